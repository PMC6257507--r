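# Sensitivity estimators robust to invalid instruments: MR-Egger regression
# (directional pleiotropy via an unconstrained intercept) and the weighted
# median of per-variant ratios (consistent when >= 50% of weight is valid).

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome associations on the exposure
#' associations with an unconstrained intercept, weights `1/se_outcome^2`.
#' All instruments are first re-oriented so `beta_exposure > 0` (flipping
#' the signs of both betas where needed); the fit is invariant to the
#' original orientation. The intercept estimates average directional
#' pleiotropy; its test is the directional-pleiotropy test. Standard errors
#' use a multiplicative random-effects scale: the residual standard error
#' `sigma`, clipped below at 1 so under-dispersion never shrinks the
#' weighted-least-squares SEs. With only 3-6 instruments, p-values come
#' from the t distribution with `k - 2` degrees of freedom.
#'
#' @param instruments Data frame with columns `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome` (one row per instrument),
#'   as produced by [harmonize()].
#' @return An object of class `egger_result`: `slope`, `slope_se`,
#'   `slope_ci_low/high`, `slope_p`, `intercept`, `intercept_se`,
#'   `intercept_ci_low/high`, `intercept_p`, `sigma`, `n_snps`.
#' @examples
#' ins <- data.frame(beta_exposure = c(0.2, 0.3, 0.4, 0.5),
#'                   se_exposure = 0.01,
#'                   beta_outcome = c(0.025, 0.031, 0.044, 0.048),
#'                   se_outcome = c(0.01, 0.012, 0.009, 0.011))
#' egger_regression(ins)
#' @export
egger_regression <- function(instruments) {
  k <- nrow(instruments)
  if (is.null(k) || k < 3) {
    ironmr_error(
      "MR-Egger needs at least 3 instruments (2 points fit a line exactly)",
      "insufficient_instruments_error")
  }
  stopifnot(all(instruments$se_outcome > 0))
  flip <- sign(instruments$beta_exposure)
  flip[flip == 0] <- 1
  bx <- instruments$beta_exposure * flip
  by <- instruments$beta_outcome * flip
  w <- 1 / instruments$se_outcome^2

  fit <- stats::lm(by ~ bx, weights = w)
  smry <- suppressWarnings(summary(fit))
  sigma <- max(1, smry$sigma)
  # cov.unscaled is (X'WX)^-1, independent of the residual scale, so the
  # clipped sigma can be applied even for an exact (zero-residual) fit
  unscaled_se <- sqrt(diag(smry$cov.unscaled))
  names(unscaled_se) <- rownames(smry$coefficients)
  df <- k - 2
  tcrit <- stats::qt(0.975, df)

  est <- function(idx) {
    b <- smry$coefficients[idx, "Estimate"]
    se <- unscaled_se[[idx]] * sigma
    p <- 2 * stats::pt(-abs(b / se), df)
    list(b = b, se = se, ci_low = b - tcrit * se, ci_high = b + tcrit * se,
         p = p)
  }
  s <- est("bx"); i <- est("(Intercept)")
  structure(list(
    slope = s$b, slope_se = s$se,
    slope_ci_low = s$ci_low, slope_ci_high = s$ci_high, slope_p = s$p,
    intercept = i$b, intercept_se = i$se,
    intercept_ci_low = i$ci_low, intercept_ci_high = i$ci_high,
    intercept_p = i$p,
    sigma = sigma, n_snps = as.integer(k)
  ), class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf(
    "MR-Egger [%d SNPs, sigma = %.3f]\n  slope     = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n  intercept = %.4f (SE %.4f), p = %.3g  (directional-pleiotropy test)\n",
    x$n_snps, x$sigma, x$slope, x$slope_se, x$slope_ci_low, x$slope_ci_high,
    x$slope_p, x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Weighted median of a set of values
#'
#' The interpolated weighted median used by the weighted-median MR
#' estimator: values are sorted, each assigned the standardized
#' mid-cumulative weight `s_j = (cumsum(w)_j - w_j/2) / sum(w)`, and the
#' estimate is the piecewise-linear interpolation of value against `s`
#' evaluated at `s = 0.5`, clamped at the extreme values. With equal
#' weights this reduces to the ordinary (interpolated) median.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @return The weighted median (scalar).
#' @examples
#' weighted_median_value(c(0.1, 0.2, 0.3), c(1, 1, 1))  # 0.2
#' @export
weighted_median_value <- function(values, weights) {
  stopifnot(length(values) == length(weights), length(values) >= 1)
  if (sum(weights) <= 0) {
    ironmr_error("total weight is zero", "zero_weight_error")
  }
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (length(v) == 1) return(v)
  if (0.5 <= s[1]) return(v[1])
  if (0.5 >= s[length(s)]) return(v[length(v)])
  stats::approx(s, v, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimator with parametric-bootstrap SE
#'
#' Computes per-variant Wald ratios and pools them as the weighted median
#' with inverse-variance weights `1/se_j^2`, where `se_j` is each ratio's
#' delta-method SE. The estimate is consistent when at least half of the
#' total weight comes from valid instruments. The standard error is the
#' standard deviation of the estimate over parametric-bootstrap replicates
#' in which each `(beta_exposure, beta_outcome)` pair is re-drawn from its
#' normal sampling distribution.
#'
#' @param instruments Data frame with columns `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param n_boot Bootstrap replicates (default 10000, minimum 1000).
#' @param seed RNG seed (mandatory: the SE is stochastic).
#' @param order Delta-method order for the per-ratio SEs feeding the
#'   weights; kept equal to the main analysis' order.
#' @return An object of class `weighted_median_result` with `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `odds_ratio` scale, `n_snps`, `n_boot`,
#'   `seed`.
#' @examples
#' ins <- data.frame(beta_exposure = c(0.2, 0.3, 0.4),
#'                   se_exposure = 0.01,
#'                   beta_outcome = c(0.02, 0.03, 0.04),
#'                   se_outcome = 0.01)
#' weighted_median(ins, n_boot = 1000, seed = 7)
#' @export
weighted_median <- function(instruments, n_boot = 10000, seed,
                            order = c("second", "first")) {
  order <- match.arg(order)
  if (missing(seed) || !is_scalar_number(seed)) {
    ironmr_error("weighted_median requires an explicit integer seed",
                 "configuration_error")
  }
  k <- nrow(instruments)
  if (is.null(k) || k < 1) {
    ironmr_error("no instruments supplied", "no_instruments_error")
  }
  if (k < 3) {
    warning(sprintf(
      "weighted median on %d instrument(s): estimate reported but unreliable",
      k), call. = FALSE)
  }
  if (n_boot < 1000) {
    ironmr_error("n_boot must be at least 1000", "configuration_error")
  }

  point <- function(bx, by) {
    ratios <- by / bx
    ses <- switch(order,
      first = instruments$se_outcome / abs(bx),
      second = sqrt(instruments$se_outcome^2 / bx^2 +
                      by^2 * instruments$se_exposure^2 / bx^4))
    weighted_median_value(ratios, 1 / ses^2)
  }
  beta <- point(instruments$beta_exposure, instruments$beta_outcome)

  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx_star <- stats::rnorm(k, instruments$beta_exposure,
                              instruments$se_exposure)
      by_star <- stats::rnorm(k, instruments$beta_outcome,
                              instruments$se_outcome)
      point(bx_star, by_star)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  ci_mult <- stats::qnorm(0.975)
  structure(list(
    beta = beta, se = se,
    ci_low = beta - ci_mult * se, ci_high = beta + ci_mult * se,
    pvalue = z_pvalue(beta, se),
    odds_ratio = exp(beta),
    or_ci_low = exp(beta - ci_mult * se), or_ci_high = exp(beta + ci_mult * se),
    n_snps = as.integer(k), n_boot = as.integer(n_boot),
    seed = as.integer(seed)
  ), class = "weighted_median_result")
}

#' @export
print.weighted_median_result <- function(x, ...) {
  cat(sprintf(
    "Weighted median [%d SNPs, %d bootstrap reps, seed %d]\n  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n  OR = %.3f, 95%% CI [%.3f, %.3f]\n",
    x$n_snps, x$n_boot, x$seed, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue,
    x$odds_ratio, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' Evaluate an expression under a local RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded estimators do not
#' perturb outer simulation streams.
#' @noRd
withr_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
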
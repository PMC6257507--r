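# Core two-sample MR estimators: per-variant Wald ratios with delta-method
# standard errors, fixed-effect inverse-variance weighted pooling, the
# first-stage F statistic, and odds-ratio scaling.

#' Construct an MR estimate
#'
#' Internal constructor for the causal-effect container used by all
#' estimators: log-odds of outcome per SD-unit increase of the exposure,
#' with normal-theory 95% CI, two-sided p, and the exponentiated
#' odds-ratio scale.
#' @noRd
mr_estimate <- function(method, beta, se, n_snps, pvalue = NULL,
                        ci_mult = stats::qnorm(0.975)) {
  stopifnot(is_scalar_number(beta), is_scalar_number(se), se > 0)
  ci_low <- beta - ci_mult * se
  ci_high <- beta + ci_mult * se
  structure(list(
    method = method,
    beta = beta, se = se,
    ci_low = ci_low, ci_high = ci_high,
    pvalue = pvalue %||% z_pvalue(beta, se),
    odds_ratio = exp(beta),
    or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
    n_snps = as.integer(n_snps)
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate [%s, %d SNP%s]\n  beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n  OR = %.3f, 95%% CI [%.3f, %.3f]\n",
    x$method, x$n_snps, if (x$n_snps == 1) "" else "s",
    x$beta, x$se, x$ci_low, x$ci_high, x$pvalue,
    x$odds_ratio, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
             odds_ratio = x$odds_ratio, or_ci_low = x$or_ci_low,
             or_ci_high = x$or_ci_high, stringsAsFactors = FALSE)
}

#' Per-variant Wald-ratio causal estimate
#'
#' The ratio estimate `by / bx` of the causal effect from a single
#' instrument, with a delta-method standard error. The first-order
#' approximation is `sey / |bx|`; the second-order approximation (default)
#' adds the propagation of uncertainty in the instrument-exposure
#' association: `sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)`.
#'
#' @param bx,sex Instrument-exposure association and its SE (SD units).
#' @param by,sey Instrument-outcome association and its SE (log-odds).
#' @param order `"second"` (default) or `"first"` delta-method order.
#' @return An object of class `mr_estimate` with `method = "wald"`.
#' @examples
#' wald_ratio(bx = 1, sex = 0.01, by = 0.07, sey = 0.05, order = "first")
#' @export
wald_ratio <- function(bx, sex, by, sey, order = c("second", "first")) {
  order <- match.arg(order)
  stopifnot(is_scalar_number(bx), is_scalar_number(by),
            is_scalar_number(sex), is_scalar_number(sey),
            sex > 0, sey > 0)
  if (bx == 0) {
    ironmr_error("degenerate instrument: exposure association is exactly zero",
                 "degenerate_instrument_error")
  }
  if (abs(bx) / sex < 1) {
    warning(sprintf(
      "weak denominator: |bx|/sex = %.2f < 1; ratio estimate unstable",
      abs(bx) / sex), call. = FALSE)
  }
  beta <- by / bx
  se <- switch(order,
    first = sey / abs(bx),
    second = sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)
  )
  mr_estimate("wald", beta, se, n_snps = 1L)
}

#' Fixed-effect inverse-variance weighted pooling of MR estimates
#'
#' Pools per-variant causal estimates with weights `1/se^2` under a common
#' causal-effect (fixed-effect) model: the pooled beta is the
#' weight-averaged beta and its SE is `1/sqrt(sum of weights)`.
#'
#' @param estimates List of `mr_estimate` objects, or a data.frame with
#'   columns `beta` and `se`.
#' @return An `mr_estimate` with `method = "ivw"`.
#' @examples
#' e1 <- wald_ratio(0.3, 0.01, 0.03, 0.03)
#' e2 <- wald_ratio(0.2, 0.01, 0.04, 0.04)
#' ivw_fixed(list(e1, e2))
#' @export
ivw_fixed <- function(estimates) {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    betas <- estimates$beta; ses <- estimates$se
  } else {
    betas <- vapply(estimates, `[[`, numeric(1), "beta")
    ses <- vapply(estimates, `[[`, numeric(1), "se")
  }
  if (length(betas) == 0) {
    ironmr_error("no usable instruments to pool", "no_instruments_error")
  }
  stopifnot(all(ses > 0))
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  mr_estimate("ivw", beta, se, n_snps = length(betas))
}

#' First-stage F statistic for instrument strength
#'
#' Evaluates `(r2 / k) / ((1 - r2) / (n - k - 1))`, where `r2` is the
#' proportion of exposure variance explained by the instruments, `k` the
#' number of instruments in the model and `n` the sample size. Values well
#' above 10 indicate negligible weak-instrument bias.
#'
#' @param r2 Variance explained, in (0, 1).
#' @param k Number of instruments (positive integer).
#' @param n Sample size; must exceed `k + 1`.
#' @return The F statistic (positive scalar).
#' @examples
#' f_statistic(0.02, 1, 48972)
#' @export
f_statistic <- function(r2, k, n) {
  stopifnot(is_scalar_number(r2), r2 > 0, r2 < 1,
            is_scalar_number(k), k >= 1, is_scalar_number(n))
  if (n <= k + 1) {
    ironmr_error(sprintf("sample size n = %g must exceed k + 1 = %g", n, k + 1),
                 "domain_error")
  }
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Fill the odds-ratio scale of an MR estimate
#'
#' Exponentiates the log-odds effect and its CI bounds; the beta-scale
#' fields are left untouched. Idempotent (the constructors already populate
#' the OR scale; this re-derives it).
#'
#' @param estimate An `mr_estimate`.
#' @return The estimate with `odds_ratio`, `or_ci_low`, `or_ci_high` set.
#' @export
to_or <- function(estimate) {
  stopifnot(inherits(estimate, "mr_estimate"))
  estimate$odds_ratio <- exp(estimate$beta)
  estimate$or_ci_low <- exp(estimate$ci_low)
  estimate$or_ci_high <- exp(estimate$ci_high)
  estimate
}
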
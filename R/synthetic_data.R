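# Summary-level simulator of two-sample GWAS summary statistics with known
# causal truth. Betas are drawn directly around their true values with
# analytic standard errors from standardized-genotype approximations; this
# is sufficient to exercise every estimator without individual-level data.

#' Build and validate a simulation configuration
#'
#' Generative parameters for a two-sample summary-statistic simulation.
#' Defaults mirror the scale of the source study: an exposure GWAS of
#' 48,972 subjects and a stroke case-control GWAS of 67,162 cases and
#' 454,450 controls, with six instruments whose per-SD exposure effects
#' (mean 0.2, SD 0.05) put their first-stage F statistics in the hundreds.
#'
#' @param n_snps Number of instruments (>= 1).
#' @param theta True causal effect, log-odds of outcome per SD of exposure.
#' @param bx_mean,bx_sd Normal distribution of true exposure effects
#'   (SD units per allele copy).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case-control GWAS sizes.
#' @param pleio_mean,pleio_sd Normal distribution of direct (pleiotropic)
#'   variant-outcome effects, log-odds; both zero for valid instruments.
#' @param n_pleio Number of variants receiving a pleiotropic effect
#'   (the first `n_pleio`); `NULL` (default) applies it to all.
#' @param maf_range Minor-allele-frequency interval, inside (0, 0.5].
#' @param palindrome_frac Fraction of variants assigned palindromic (A/T or
#'   C/G) allele pairs, to exercise the harmonization policies.
#' @param seed Integer RNG seed (mandatory for generation).
#' @return An object of class `simulation_config` (a validated list).
#' @examples
#' simulation_config(n_snps = 3, theta = 0.1, seed = 1)
#' @export
simulation_config <- function(n_snps = 6, theta = 0,
                              bx_mean = 0.2, bx_sd = 0.05,
                              n_exposure = 48972,
                              n_cases = 67162, n_controls = 454450,
                              pleio_mean = 0, pleio_sd = 0, n_pleio = NULL,
                              maf_range = c(0.05, 0.5),
                              palindrome_frac = 0, seed = NULL) {
  cfg <- list(n_snps = as.integer(n_snps), theta = theta,
              bx_mean = bx_mean, bx_sd = bx_sd,
              n_exposure = n_exposure, n_cases = n_cases,
              n_controls = n_controls,
              pleio_mean = pleio_mean, pleio_sd = pleio_sd,
              n_pleio = if (is.null(n_pleio)) NULL else as.integer(n_pleio),
              maf_range = maf_range, palindrome_frac = palindrome_frac,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  if (cfg$n_snps < 1) {
    ironmr_error("n_snps must be at least 1", "configuration_error")
  }
  if (cfg$n_exposure <= 0 || cfg$n_cases <= 0 || cfg$n_controls <= 0) {
    ironmr_error("sample sizes must be positive", "configuration_error")
  }
  if (cfg$pleio_sd < 0 || cfg$bx_sd < 0) {
    ironmr_error("dispersion parameters must be non-negative",
                 "configuration_error")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    ironmr_error("maf_range must lie within (0, 0.5]", "configuration_error")
  }
  if (!is.null(cfg$n_pleio) && (cfg$n_pleio < 0 || cfg$n_pleio > cfg$n_snps)) {
    ironmr_error("n_pleio must be between 0 and n_snps", "configuration_error")
  }
  if (cfg$palindrome_frac < 0 || cfg$palindrome_frac > 1) {
    ironmr_error("palindrome_frac must be in [0, 1]", "configuration_error")
  }
  structure(cfg, class = "simulation_config")
}

# standardized-genotype SE approximations: var(beta_hat) ~ 1 / (2p(1-p) N)
# for a quantitative trait, with the effective case-control size
# Nc*Nn/(Nc+Nn) for a log-odds outcome.
se_exposure_analytic <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)
se_outcome_analytic <- function(maf, n_cases, n_controls) {
  1 / sqrt(2 * maf * (1 - maf) * n_cases * n_controls /
             (n_cases + n_controls))
}

NONPALINDROMIC_PAIRS <- list(c("A", "G"), c("A", "C"), c("T", "G"),
                             c("T", "C"), c("G", "A"), c("C", "A"))
PALINDROMIC_PAIRS <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' For each variant j: draw a minor-allele frequency and a true exposure
#' effect `b_Xj ~ N(bx_mean, bx_sd^2)`; set the analytic exposure SE from
#' the standardized-genotype approximation and draw the observed
#' `beta_Xj ~ N(b_Xj, SE_Xj^2)`. Draw a direct effect
#' `alpha_j ~ N(pleio_mean, pleio_sd^2)` (zero outside the first `n_pleio`
#' variants), set the true outcome effect `b_Yj = theta * b_Xj + alpha_j`,
#' the analytic case-control outcome SE, and draw the observed
#' `beta_Yj ~ N(b_Yj, SE_Yj^2)`. Allele pairs are assigned at random
#' (palindromic with probability `palindrome_frac`) and the outcome table's
#' allele labels are randomly swapped per variant so every harmonization
#' path is exercised.
#'
#' @param config A [simulation_config()] with a non-NULL `seed`.
#' @return A list with `exposure` and `outcome` canonical association
#'   tables (the exact schema [read_gwas_summary()] produces) and `truth`,
#'   a list carrying `theta`, per-variant `b_x`, `alpha`, `maf`, and the
#'   indices of invalid (pleiotropic) variants.
#' @examples
#' sim <- simulate_summary_stats(simulation_config(theta = 0.1, seed = 42))
#' head(sim$exposure)
#' sim$truth$theta
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) {
    ironmr_error("simulation requires an explicit seed", "configuration_error")
  }
  withr_seed(config$seed, {
    k <- config$n_snps
    snp <- sprintf("rs%07d", seq_len(k))
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    b_x <- stats::rnorm(k, config$bx_mean, config$bx_sd)
    se_x <- se_exposure_analytic(maf, config$n_exposure)
    beta_x <- stats::rnorm(k, b_x, se_x)

    n_pleio <- config$n_pleio %||% k
    alpha <- numeric(k)
    if (n_pleio > 0 && (config$pleio_sd > 0 || config$pleio_mean != 0)) {
      alpha[seq_len(n_pleio)] <-
        stats::rnorm(n_pleio, config$pleio_mean, config$pleio_sd)
    }
    b_y <- config$theta * b_x + alpha
    se_y <- se_outcome_analytic(maf, config$n_cases, config$n_controls)
    beta_y <- stats::rnorm(k, b_y, se_y)

    pal <- stats::runif(k) < config$palindrome_frac
    pair_idx <- sample.int(length(NONPALINDROMIC_PAIRS), k, replace = TRUE)
    pal_idx <- sample.int(length(PALINDROMIC_PAIRS), k, replace = TRUE)
    ea <- oa <- character(k)
    for (j in seq_len(k)) {
      p <- if (pal[j]) PALINDROMIC_PAIRS[[pal_idx[j]]]
           else NONPALINDROMIC_PAIRS[[pair_idx[j]]]
      ea[j] <- p[1]; oa[j] <- p[2]
    }

    exposure <- association_table(
      snp = snp, effect_allele = ea, other_allele = oa,
      beta = beta_x, se = se_x, eaf = maf, n = config$n_exposure,
      trait = "exposure")

    # swap outcome allele labels for a random subset of non-palindromic
    # variants so the harmonization sign-flip path is exercised; palindromic
    # labels are left as-is (label swaps are unresolvable by design there)
    swap <- stats::runif(k) < 0.5 & !pal
    out_ea <- ifelse(swap, oa, ea)
    out_oa <- ifelse(swap, ea, oa)
    out_beta <- ifelse(swap, -beta_y, beta_y)
    out_eaf <- ifelse(swap, 1 - maf, maf)
    outcome <- association_table(
      snp = snp, effect_allele = out_ea, other_allele = out_oa,
      beta = out_beta, se = se_y, eaf = out_eaf,
      n = config$n_cases + config$n_controls, trait = "outcome")

    list(exposure = exposure, outcome = outcome,
         truth = list(theta = config$theta, b_x = b_x, alpha = alpha,
                      maf = maf, invalid = which(alpha != 0),
                      config = unclass(config)))
  })
}

#' Preset simulation scenarios
#'
#' Named generative settings covering the study's robustness concerns:
#' \describe{
#'   \item{null}{no causal effect, no pleiotropy (type-I error).}
#'   \item{causal}{causal effect `theta = 0.1`, valid instruments
#'     (parameter recovery, CI coverage).}
#'   \item{balanced_pleiotropy}{causal effect plus zero-mean direct effects
#'     on all variants (`pleio_sd = 0.02`).}
#'   \item{directional_pleiotropy}{causal effect plus positive-mean direct
#'     effects on all variants (`pleio_mean = 0.02`, `pleio_sd = 0.01`):
#'     biases IVW upward while the Egger intercept absorbs the mean.}
#'   \item{half_invalid}{causal effect with large direct effects
#'     (`pleio_mean = 0.05`, `pleio_sd = 0.01`) confined to
#'     `ceiling(n_snps/2) - 1` variants, so valid instruments keep a
#'     majority of the weight and the weighted median stays consistent.}
#' }
#'
#' @param name Scenario name (see above).
#' @param seed Integer RNG seed stored in the returned config.
#' @param n_snps Number of instruments (default 6).
#' @return A [simulation_config()].
#' @examples
#' scenario("half_invalid", seed = 1)$n_pleio  # 2 invalid of 6
#' @export
scenario <- function(name = c("null", "causal", "balanced_pleiotropy",
                              "directional_pleiotropy", "half_invalid"),
                     seed = NULL, n_snps = 6) {
  if (!is.character(name) || length(name) != 1 ||
      !name %in% c("null", "causal", "balanced_pleiotropy",
                   "directional_pleiotropy", "half_invalid")) {
    ironmr_error(paste(
      "unknown scenario; valid names: null, causal, balanced_pleiotropy,",
      "directional_pleiotropy, half_invalid"), "configuration_error")
  }
  base <- list(n_snps = n_snps, seed = seed)
  args <- switch(name,
    null = list(theta = 0, pleio_mean = 0, pleio_sd = 0),
    causal = list(theta = 0.1, pleio_mean = 0, pleio_sd = 0),
    balanced_pleiotropy = list(theta = 0.1, pleio_mean = 0, pleio_sd = 0.02),
    directional_pleiotropy = list(theta = 0.1, pleio_mean = 0.02,
                                  pleio_sd = 0.01),
    half_invalid = list(theta = 0.1, pleio_mean = 0.05, pleio_sd = 0.01,
                        n_pleio = ceiling(n_snps / 2) - 1)
  )
  do.call(simulation_config, c(base, args))
}

#' Simulate a full four-biomarker iron-status study
#'
#' Generates the complete input set the pipeline consumes: four biomarker
#' exposure tables sharing the same variants — serum iron, log-ferritin and
#' transferrin saturation carrying the latent iron-status effect with a
#' positive sign and transferrin with a negative sign — plus one outcome
#' table per requested label, each an independent draw at case-control GWAS
#' precision with the same causal `theta` per SD of latent iron status.
#' Biomarker betas are the latent effects plus independent measurement
#' noise at the exposure GWAS precision, so strict instrument selection on
#' the output behaves like the real concordance filter.
#'
#' @param config A [simulation_config()]; `theta` is the causal effect of
#'   the latent iron-status exposure.
#' @param outcomes Character vector of outcome labels.
#' @return List with `exposures` (named list of four canonical tables),
#'   `outcomes` (named list of canonical tables), and `truth`.
#' @examples
#' study <- simulate_study(simulation_config(theta = 0.1, seed = 3),
#'                         outcomes = "any_stroke")
#' names(study$exposures)
#' @export
simulate_study <- function(config, outcomes = c("any_stroke")) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$seed)) {
    ironmr_error("simulation requires an explicit seed", "configuration_error")
  }
  withr_seed(config$seed, {
    k <- config$n_snps
    snp <- sprintf("rs%07d", seq_len(k))
    maf <- stats::runif(k, config$maf_range[1], config$maf_range[2])
    b_x <- stats::rnorm(k, config$bx_mean, config$bx_sd)
    se_x <- se_exposure_analytic(maf, config$n_exposure)

    pair_idx <- sample.int(length(NONPALINDROMIC_PAIRS), k, replace = TRUE)
    ea <- vapply(pair_idx, function(i) NONPALINDROMIC_PAIRS[[i]][1], "")
    oa <- vapply(pair_idx, function(i) NONPALINDROMIC_PAIRS[[i]][2], "")

    signs <- IRON_BIOMARKERS
    exposures <- lapply(names(signs), function(bm) {
      association_table(
        snp = snp, effect_allele = ea, other_allele = oa,
        beta = stats::rnorm(k, signs[[bm]] * b_x, se_x),
        se = se_x, eaf = maf, n = config$n_exposure, trait = bm)
    })
    names(exposures) <- names(signs)

    n_pleio <- config$n_pleio %||% k
    alpha <- numeric(k)
    if (n_pleio > 0 && (config$pleio_sd > 0 || config$pleio_mean != 0)) {
      alpha[seq_len(n_pleio)] <-
        stats::rnorm(n_pleio, config$pleio_mean, config$pleio_sd)
    }
    b_y <- config$theta * b_x + alpha
    se_y <- se_outcome_analytic(maf, config$n_cases, config$n_controls)

    outcome_tables <- lapply(outcomes, function(lbl) {
      swap <- stats::runif(k) < 0.5
      beta_y <- stats::rnorm(k, b_y, se_y)
      association_table(
        snp = snp,
        effect_allele = ifelse(swap, oa, ea),
        other_allele = ifelse(swap, ea, oa),
        beta = ifelse(swap, -beta_y, beta_y),
        se = se_y, eaf = ifelse(swap, 1 - maf, maf),
        n = config$n_cases + config$n_controls, trait = lbl)
    })
    names(outcome_tables) <- outcomes

    list(exposures = exposures, outcomes = outcome_tables,
         truth = list(theta = config$theta, b_x = b_x, alpha = alpha,
                      maf = maf, invalid = which(alpha != 0),
                      config = unclass(config)))
  })
}

#' Write a simulated study to disk in the pipeline's input schema
#'
#' Emits one TSV per exposure biomarker and per outcome (exactly the schema
#' [read_gwas_summary()] reads) plus `truth.json`.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }
  for (bm in names(study$exposures)) emit(study$exposures[[bm]],
                                          paste0("exposure_", bm))
  for (oc in names(study$outcomes)) emit(study$outcomes[[oc]],
                                         paste0("outcome_", oc))
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(study$truth, truth_path, auto_unbox = TRUE,
                       digits = NA)
  paths[["truth"]] <- truth_path
  invisible(paths)
}
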
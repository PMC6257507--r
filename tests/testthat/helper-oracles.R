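# Independent oracles and fixture builders shared across the suite.
# Every oracle is a deliberately naive re-derivation (normal equations,
# grid search, Monte Carlo) kept separate from the package's code paths.

# Weighted least squares through the origin: closed-form normal equation.
wls_origin_oracle <- function(bx, by, w) {
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  list(beta = beta, se = se)
}

# Weighted regression with intercept: explicit 2x2 normal-equations solve.
egger_oracle <- function(bx, by, w) {
  X <- cbind(1, bx)
  co <- solve(t(X) %*% (w * X), t(X) %*% (w * by))
  list(intercept = co[1], slope = co[2])
}

# Weighted percentile by brute-force grid search over the interpolated
# mid-cumulative-weight curve.
grid_median_oracle <- function(values, weights, n_grid = 4e6) {
  ord <- order(values)
  v <- values[ord]; w <- weights[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  grid <- seq(min(v), max(v), length.out = n_grid)
  s_of_x <- approx(v, s, xout = grid, rule = 2, ties = "ordered")$y
  grid[which.min(abs(s_of_x - 0.5))]
}

# Monte-Carlo SD of the ratio by/bx under normal sampling noise.
mc_ratio_sd_oracle <- function(bx, sex, by, sey, n = 1e6, seed = 424242) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sd(rnorm(n, by, sey) / rnorm(n, bx, sex))
}

# The bundled synthetic biomarker fixture, readable both from the source
# tree (devtools) and the installed package.
fixture_biomarker_tables <- function() {
  paths <- gis_synthetic_paths()
  if (any(paths == "")) {
    base <- testthat::test_path("..", "..", "inst", "extdata")
    files <- c(iron = "gis_synthetic_serum_iron.tsv",
               ferritin = "gis_synthetic_log_ferritin.tsv",
               saturation = "gis_synthetic_transferrin_saturation.tsv",
               transferrin = "gis_synthetic_transferrin.tsv")
    paths <- vapply(files, function(f) file.path(base, f), character(1))
  }
  tabs <- lapply(names(paths), function(bm)
    read_gwas_summary(paths[[bm]], trait = bm))
  names(tabs) <- names(paths)
  tabs
}

# Small random biomarker table set with a controllable concordance pattern,
# for property tests of the selection rules.
random_biomarker_tables <- function(n_snps, seed) {
  set.seed(seed)
  snp <- sprintf("rs%06d", sample.int(999999, n_snps))
  dirs <- c(iron = 1, ferritin = 1, saturation = 1, transferrin = -1)
  lapply(dirs, function(d) {
    beta <- d * rnorm(n_snps, 0.05, 0.1)
    se <- runif(n_snps, 0.005, 0.02)
    association_table(snp = snp, effect_allele = "A", other_allele = "G",
                      beta = beta, se = se, eaf = runif(n_snps, 0.05, 0.95),
                      trait = "x")
  })
}

assoc1 <- function(snp, ea, oa, beta, se, eaf = NA_real_, trait = "t") {
  association_table(snp = snp, effect_allele = ea, other_allele = oa,
                    beta = beta, se = se, eaf = eaf, trait = trait)
}
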
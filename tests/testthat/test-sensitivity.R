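test_that("Egger regression recovers exact lines", {
  ins <- data.frame(beta_exposure = c(1, 2, 3), se_exposure = 0.01,
                    beta_outcome = c(0.2, 0.3, 0.4), se_outcome = 0.05)
  eg <- egger_regression(ins)
  expect_equal(eg$slope, 0.1)
  expect_equal(eg$intercept, 0.1)
  expect_equal(eg$sigma, 1)  # zero residuals: sigma clipped at 1

  # pure proportionality: slope is the ratio, intercept vanishes
  prop <- data.frame(beta_exposure = c(0.2, 0.3, 0.4, 0.5),
                     se_exposure = 0.01,
                     beta_outcome = 0.2 * c(0.2, 0.3, 0.4, 0.5),
                     se_outcome = 0.02)
  eg2 <- egger_regression(prop)
  expect_equal(eg2$slope, 0.2, tolerance = 1e-12)
  expect_equal(eg2$intercept, 0, tolerance = 1e-12)

  expect_error(egger_regression(ins[1:2, ]),
               class = "insufficient_instruments_error")
})

test_that("Egger coefficients equal the weighted normal-equations oracle", {
  set.seed(5)
  for (rep in 1:10) {
    bx <- runif(6, 0.1, 0.5)
    by <- 0.02 + 0.1 * bx + rnorm(6, 0, 0.01)
    sey <- runif(6, 0.005, 0.03)
    ins <- data.frame(beta_exposure = bx, se_exposure = 0.01,
                      beta_outcome = by, se_outcome = sey)
    eg <- egger_regression(ins)
    oracle <- egger_oracle(bx, by, 1 / sey^2)
    expect_equal(eg$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(eg$intercept, oracle$intercept, tolerance = 1e-10)
    expect_gte(eg$sigma, 1)
  }
})

test_that("Egger fit is invariant to instrument orientation flips", {
  set.seed(8)
  bx <- runif(5, 0.1, 0.4)
  by <- 0.01 + 0.15 * bx + rnorm(5, 0, 0.01)
  ins <- data.frame(beta_exposure = bx, se_exposure = 0.01,
                    beta_outcome = by, se_outcome = 0.02)
  base <- egger_regression(ins)
  flip <- sample(c(-1, 1), 5, replace = TRUE)
  flipped <- data.frame(beta_exposure = flip * bx, se_exposure = 0.01,
                        beta_outcome = flip * by, se_outcome = 0.02)
  eg <- egger_regression(flipped)
  expect_equal(eg$slope, base$slope, tolerance = 1e-12)
  expect_equal(eg$intercept, base$intercept, tolerance = 1e-12)
  expect_equal(eg$slope_se, base$slope_se, tolerance = 1e-12)
})

test_that("the weighted median interpolates mid-cumulative weights", {
  # equal weights, s = (1/6, 1/2, 5/6): exact hit at the middle value
  expect_equal(weighted_median_value(c(0.1, 0.2, 0.3), rep(1, 3)), 0.2)
  # single value: degenerate median
  expect_equal(weighted_median_value(0.42, 2), 0.42)
  # order of the inputs is irrelevant
  expect_equal(weighted_median_value(c(0.3, 0.1, 0.2), rep(1, 3)), 0.2)
  expect_error(weighted_median_value(c(1, 2), c(0, 0)),
               class = "zero_weight_error")
})

test_that("weighted median agrees with the grid-percentile oracle", {
  cases <- list(
    list(v = c(0.1, 0.2, 0.4), w = c(1, 1, 2)),
    list(v = c(-0.3, 0.05, 0.1, 0.2, 0.8), w = c(0.2, 1, 3, 1, 0.5)),
    list(v = c(0.01, 0.02, 0.03, 0.5), w = c(5, 1, 1, 5))
  )
  for (cs in cases) {
    expect_equal(weighted_median_value(cs$v, cs$w),
                 grid_median_oracle(cs$v, cs$w), tolerance = 1e-6)
  }
  set.seed(12)
  for (rep in 1:5) {
    v <- rnorm(7); w <- runif(7, 0.1, 3)
    expect_equal(weighted_median_value(v, w), grid_median_oracle(v, w),
                 tolerance = 1e-6)
  }
})

test_that("equal weights reduce the weighted median to the interpolated median", {
  set.seed(3)
  for (k in c(3, 5, 8)) {
    v <- rnorm(k)
    wm <- weighted_median_value(v, rep(1, k))
    # the interpolated ordinary median at equal weights
    s <- (seq_len(k) - 0.5) / k
    expect_equal(wm, approx(s, sort(v), xout = 0.5)$y)
  }
})

test_that("weighted median stays inside the ratio range and ignores minority invalids", {
  set.seed(21)
  for (rep in 1:10) {
    k <- sample(3:8, 1)
    ins <- data.frame(beta_exposure = runif(k, 0.1, 0.5), se_exposure = 0.01,
                      beta_outcome = rnorm(k, 0.02, 0.05), se_outcome = 0.02)
    wm <- suppressWarnings(weighted_median(ins, n_boot = 1000, seed = rep))
    ratios <- ins$beta_outcome / ins$beta_exposure
    expect_gte(wm$beta, min(ratios))
    expect_lte(wm$beta, max(ratios))
  }

  # 3 valid instruments sharing theta, 2 invalid: as SEs shrink the
  # estimate converges to theta
  theta <- 0.1
  bx <- c(0.3, 0.35, 0.4, 0.3, 0.35)
  alpha <- c(0, 0, 0, 0.08, 0.1)
  for (se in c(1e-3, 1e-5)) {
    ins <- data.frame(beta_exposure = bx, se_exposure = se,
                      beta_outcome = theta * bx + alpha, se_outcome = se)
    wm <- weighted_median(ins, n_boot = 1000, seed = 1)
    expect_equal(wm$beta, theta, tolerance = 50 * se)
  }
})

test_that("the bootstrap SE is reproducible for a fixed seed", {
  ins <- data.frame(beta_exposure = c(0.2, 0.3, 0.4, 0.25),
                    se_exposure = 0.02,
                    beta_outcome = c(0.02, 0.04, 0.03, 0.02),
                    se_outcome = 0.015)
  a <- weighted_median(ins, n_boot = 2000, seed = 77)
  b <- weighted_median(ins, n_boot = 2000, seed = 77)
  expect_identical(a$se, b$se)
  c <- weighted_median(ins, n_boot = 2000, seed = 78)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
  # a single instrument degenerates to its Wald ratio, with a warning
  expect_warning(one <- weighted_median(ins[1, ], n_boot = 1000, seed = 1),
                 "unreliable")
  expect_equal(one$beta, 0.02 / 0.2)
})

test_that("weighted median requires a seed and enough bootstrap replicates", {
  ins <- data.frame(beta_exposure = c(0.2, 0.3, 0.4), se_exposure = 0.01,
                    beta_outcome = c(0.02, 0.03, 0.04), se_outcome = 0.01)
  expect_error(weighted_median(ins, n_boot = 1000),
               class = "configuration_error")
  expect_error(weighted_median(ins, n_boot = 10, seed = 1),
               class = "configuration_error")
})
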
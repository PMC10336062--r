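make_recovery_records <- function(s_inf, delta, lam, intervals, n_rep = 3,
                                  cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sf <- exp(log(s_inf) - delta * exp(-lam * intervals))
  sf <- rep(sf, each = n_rep)
  if (cv > 0) sf <- pmin(sf * exp(rnorm(length(sf), 0,
                                        sqrt(log(1 + cv^2)))), 1)
  tibble::tibble(cell_line = "x", modality_1 = "xray", dose_1_Gy = 3,
                 modality_2 = "xray", dose_2_Gy = 3,
                 interval_min = rep(intervals, each = n_rep),
                 delivery_min_1 = 5, delivery_min_2 = 5,
                 replicate = rep(seq_len(n_rep), length(intervals)),
                 surviving_fraction = sf)
}

test_that("recovery fit inverts noiseless data exactly", {
  Tset <- c(15, 30, 60, 120, 240, 360)
  rec <- make_recovery_records(0.12, 1.5, log(2) / 44, Tset)
  fit <- fit_recovery_curve(rec)
  expect_equal(fit$s_infinity, 0.12, tolerance = 1e-6)
  expect_equal(fit$interaction_magnitude, 1.5, tolerance = 1e-6)
  expect_equal(fit$half_life_min, 44, tolerance = 1e-6)
  expect_false(fit$no_recovery)
})

test_that("flat split-dose data is flagged as no recovery", {
  rec <- make_recovery_records(0.1, 0, log(2) / 44, c(15, 60, 120, 360))
  fit <- fit_recovery_curve(rec)
  expect_true(fit$no_recovery)
  expect_true(is.na(fit$half_life_min))
  expect_error(fit_recovery_curve(rec[rec$interval_min == 15, ]),
               "interval")
})

test_that("recovery fit is within 3 SE of truth on noisy data", {
  Tset <- c(0, 15, 30, 60, 120, 240, 360)
  lam <- log(2) / 44
  rec <- make_recovery_records(0.1, 1.33, lam, Tset, cv = 0.15, seed = 99)
  fit <- fit_recovery_curve(rec)
  se_lam <- sqrt(fit$covariance[3, 3])
  expect_lt(abs(fit$repair_rate_per_min - lam), 3 * se_lam)
})

test_that("shared-half-life F-test is exact on a noiseless shared truth", {
  tr <- ground_truth_preset("pc3")
  by <- gen_conditions(tr, seed = 1, noise = FALSE)
  res <- shared_halflife_ftest(by[c("xx", "xa", "ax")])
  expect_lt(res$f_statistic, 1e-4)
  expect_gt(res$p_value, 0.999)
  expect_equal(res$shared_half_life_min, 44, tolerance = 1e-4)
})

test_that("shared-half-life F-test holds its size and has power", {
  tr <- ground_truth_preset("pc3")
  # size under the shared-lambda truth
  rej <- 0
  n_sim <- 120
  for (s in seq_len(n_sim)) {
    by <- suppressWarnings(gen_conditions(tr, seed = 5000 + s))
    p <- suppressWarnings(
      shared_halflife_ftest(by[c("xx", "xa", "ax")])$p_value)
    if (p < 0.05) rej <- rej + 1
  }
  # nominal band 0.05 +/- 0.02 plus 3 binomial SE of the simulation itself
  expect_lt(abs(rej / n_sim - 0.05), 0.02 + 3 * sqrt(0.05 * 0.95 / n_sim))
  # power against a 3-fold rate difference at the study noise level
  tr3 <- tr
  tr3$repair_rate_per_min <- 3 * tr$repair_rate_per_min
  hit <- 0
  n_pow <- 50
  for (s in seq_len(n_pow)) {
    by1 <- suppressWarnings(gen_conditions(tr, seed = 6000 + s))
    by2 <- suppressWarnings(gen_conditions(tr3, seed = 6500 + s))
    p <- suppressWarnings(
      shared_halflife_ftest(list(xx = by1$xx, xa = by2$xa))$p_value)
    if (p < 0.05) hit <- hit + 1
  }
  expect_gte(hit / n_pow, 0.8)
})

test_that("RBE_SLD estimator is the scaled recovery-magnitude ratio", {
  expect_equal(estimate_rbe_sld(1.2, 1.2, 3, 3)$value, 1)
  expect_equal(estimate_rbe_sld(0.7 * 1.5, 1.5, 3, 0.75)$value, 2.8)
  expect_error(estimate_rbe_sld(1, 0, 3, 0.75), "no reference")
  expect_warning(out <- estimate_rbe_sld(-0.2, 1, 3, 0.75), "truncated")
  expect_equal(out$value, 0)
  # exact linearity in Delta_XA and in the dose ratio
  set.seed(4)
  for (i in 1:20) {
    dxx <- runif(1, 0.5, 2); dxa <- runif(1, 0.1, 2)
    dx <- runif(1, 1, 6); da <- runif(1, 0.2, 2); c1 <- runif(1, 0.5, 3)
    expect_equal(estimate_rbe_sld(c1 * dxa, dxx, dx, da)$value,
                 c1 * estimate_rbe_sld(dxa, dxx, dx, da)$value)
    expect_equal(estimate_rbe_sld(dxa, dxx, c1 * dx, da)$value,
                 c1 * estimate_rbe_sld(dxa, dxx, dx, da)$value)
  }
})

test_that("zero-noise generation recovers the preset RBE_SLD exactly", {
  for (preset in c("pc3", "u2os")) {
    tr <- ground_truth_preset(preset)
    by <- gen_conditions(tr, seed = 1, noise = FALSE)
    fxx <- fit_recovery_curve(by$xx)
    fxa <- fit_recovery_curve(by$xa)
    est <- estimate_rbe_sld(fxa$interaction_magnitude,
                            fxx$interaction_magnitude, 3, 0.75)
    expect_equal(est$value, tr$rbe_sld, tolerance = 1e-6)
  }
})

test_that("D10 satisfies the defining equation on random LQ parameters", {
  expect_equal(d10_dose(lq_params(0.5, 0)), log(10) / 0.5)
  set.seed(8)
  for (i in 1:40) {
    a <- runif(1, 0, 2) * rbinom(1, 1, 0.8)
    b <- runif(1, 0, 0.3)
    if (a + b == 0) b <- 0.1
    D <- d10_dose(lq_params(a, b))
    expect_lt(abs(a * D + b * D^2 - log(10)), 1e-10)
  }
  expect_error(d10_dose(lq_params(0, 0)), "positive")
})

test_that("RBE_D10 is a D10 ratio with a sane parametric bootstrap CI", {
  p <- lq_params(0.3, 0.06)
  expect_equal(rbe_d10(p, p, n_boot = 0)$value, 1)
  ref <- lq_params(0.2, 0.05); tst <- lq_params(1.5, 0)
  expect_equal(rbe_d10(ref, tst, n_boot = 0)$value,
               d10_dose(ref) / d10_dose(tst))
  ref$covariance <- diag(c(0.01, 0.001)^2)
  tst$covariance <- diag(c(0.05, 1e-8)^2)
  est <- rbe_d10(ref, tst, n_boot = 500, seed = 3)
  expect_true(est$ci_low <= est$value && est$value <= est$ci_high)
})

test_that("order-independence test accepts symmetric noiseless orderings", {
  tr <- ground_truth_preset("pc3")
  by <- suppressWarnings(gen_conditions(tr, seed = 77))
  res <- suppressWarnings(order_independence_ftest(by$xa, by$ax))
  expect_gt(res$p_value, 0.05)
})
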
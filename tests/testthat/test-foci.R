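cfg <- default_config()

make_exp_records <- function(n0, p, k, times = c(0.5, 1, 2, 4, 6, 24)) {
  mu <- (n0 - p) * exp(-k * times) + p
  tibble::tibble(cell_line = "x", modality = "xray", dose_Gy = 2,
                 time_h = times, mean_foci = mu,
                 sd_foci = sqrt(pmax(mu, 0.5)), n_cells = 50L)
}

test_that("exponential foci fit inverts noiseless data", {
  rec <- make_exp_records(50, 5, 0.5)
  fit <- fit_foci_exponential(rec)
  expect_equal(fit$n0, 50, tolerance = 1e-6)
  expect_equal(fit$p, 5, tolerance = 1e-6)
  expect_equal(fit$k_per_h, 0.5, tolerance = 1e-6)
  # model limits and the half-decay point
  expect_equal((fit$n0 - fit$p) * exp(-fit$k_per_h * 0) + fit$p, 50,
               tolerance = 1e-6)
  t_half <- log(2) / 0.5
  expect_equal((50 - 5) * exp(-0.5 * t_half) + 5, 27.5)
  expect_error(fit_foci_exponential(rec[1:3, ]), "4 distinct time points")
})

test_that("per-DSB unrepaired probability has the right limits and value", {
  expect_equal(per_dsb_survival_prob(0, 0.04, cfg), 1)
  expect_equal(per_dsb_survival_prob(1e6, 0.04, cfg), 0.04)
  # direct scalar evaluation at t = 1 h
  k_fast <- log(2) / (25 / 60)
  k_slow <- log(2) / 8
  manual <- 0.04 + 0.96 * (0.57 * exp(-k_fast) + 0.43 * exp(-k_slow))
  expect_equal(per_dsb_survival_prob(1, 0.04, cfg), manual, tolerance = 1e-12)
  expect_error(per_dsb_survival_prob(-1, 0.04, cfg), "non-negative")
  expect_error(per_dsb_survival_prob(1, 1, cfg), "persistent_rate")
  # monotone non-increasing in time
  q <- per_dsb_survival_prob(seq(0, 30, by = 0.5), 0.04, cfg)
  expect_true(all(diff(q) <= 0))
})

test_that("expected visible foci follows the Poisson void closed form", {
  p <- cluster_model_params(10, 1, 0, 62, cfg)
  # q = 1 at t = 0: 10 (1 - e^-1)
  expect_equal(expected_visible_foci(0, p, "alpha"), 10 * (1 - exp(-1)))
  # q -> 0 (no persistence, long time): no foci
  expect_lt(expected_visible_foci(1e6, p, "alpha"), 1e-8)
  # mu -> infinity saturates at N
  psat <- cluster_model_params(10, 500, 0, 62, cfg)
  expect_equal(expected_visible_foci(0, psat, "alpha"), 10, tolerance = 1e-12)
  # X-ray: one DSB per focus
  expect_equal(expected_visible_foci(2, p, "xray"),
               62 * per_dsb_survival_prob(2, 0, cfg))
  # monotone non-increasing in t for both modalities
  tt <- seq(0, 24, by = 0.5)
  expect_true(all(diff(expected_visible_foci(tt, p, "alpha")) <= 0))
  expect_true(all(diff(expected_visible_foci(tt, p, "xray")) <= 0))
})

test_that("small clusters reduce to per-DSB counting", {
  p <- cluster_model_params(10, 1e-6, 0.04, 62, cfg)
  tt <- c(0.5, 2, 8)
  q <- per_dsb_survival_prob(tt, 0.04, cfg)
  expect_equal(expected_visible_foci(tt, p, "alpha"), 10 * 1e-6 * q,
               tolerance = 1e-4)
})

test_that("foci Monte Carlo agrees with the closed form", {
  tt <- c(0.5, 1, 2, 6, 24)
  set.seed(61)
  for (i in 1:6) {
    p <- cluster_model_params(runif(1, 5, 15), runif(1, 0.5, 30),
                              runif(1, 0, 0.1), runif(1, 30, 80), cfg)
    mc <- simulate_foci_mc(p, 3000, tt, "alpha")
    closed <- expected_visible_foci(tt, p, "alpha")
    se <- apply(mc, 2, sd) / sqrt(nrow(mc))
    expect_true(all(abs(colMeans(mc) - closed) < 3 * se + 1e-9))
  }
  # fully persistent damage never clears
  pp <- cluster_model_params(8, 3, 0.999999, 40, cfg)
  mc <- simulate_foci_mc(pp, 400, c(0.1, 24, 100), "alpha", seed = 5)
  expect_true(all(mc[, 1] == mc[, 2] & mc[, 2] == mc[, 3]))
  # determinism under a fixed seed
  a <- simulate_foci_mc(p, 50, tt, "alpha", seed = 9)
  b <- simulate_foci_mc(p, 50, tt, "alpha", seed = 9)
  expect_identical(a, b)
})

test_that("joint cluster fit inverts noiseless data at the preset truth", {
  tr <- ground_truth_preset("pc3")
  f <- gen_foci_dataset(tr, seed = 1, noise = FALSE)
  fit <- fit_foci_cluster(f[f$modality == "xray", ],
                          f[f$modality == "alpha", ], cfg, rbe_dsb = 3.67)
  expect_equal(fit$n0_xray, 62, tolerance = 1e-4)
  expect_equal(fit$persistent_rate, 0.040, tolerance = 1e-4)
  expect_equal(fit$n_clusters_mean, 9.9, tolerance = 1e-4)
  expect_false(attr(fit, "boundary"))
})

test_that("joint cluster fit recovers truth within 3 SE under noise", {
  tr <- ground_truth_preset("u2os")
  f <- gen_foci_dataset(tr, seed = 8, noise = TRUE)
  fit <- fit_foci_cluster(f[f$modality == "xray", ],
                          f[f$modality == "alpha", ], cfg, rbe_dsb = 3.67)
  se <- sqrt(diag(attr(fit, "covariance")))
  expect_lt(abs(fit$n0_xray - 42), 3 * se[1])
  expect_lt(abs(fit$persistent_rate - 0.044), 3 * se[2])
  expect_lt(abs(fit$n_clusters_mean - 10.2), 3 * se[3])
})

test_that("clustered alpha foci decay more slowly than X-ray foci", {
  # relative decay rate of the alpha curve is below the X-ray curve
  # whenever clusters hold several DSBs
  for (mu in c(3, 10, 26)) {
    p <- cluster_model_params(10, mu, 0.04, 62, cfg)
    tt <- seq(0.5, 8, by = 0.5)
    fx <- expected_visible_foci(tt, p, "xray")
    fa <- expected_visible_foci(tt, p, "alpha")
    # normalised to the first time point, alpha stays above X-ray
    expect_true(all(fa / fa[1] >= fx / fx[1] - 1e-12))
  }
})
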
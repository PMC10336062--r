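cfg <- default_config()

test_that("DSB position sampling matches the prescribed yields", {
  set.seed(41)
  nx <- replicate(400, nrow(sample_dsb_positions(
    beam_preset("photon_ref"), 1, 35, cfg)$positions))
  expect_lt(abs(mean(nx) - 35), 3 * sd(nx) / sqrt(length(nx)))
  na <- replicate(400, nrow(sample_dsb_positions(
    beam_preset("alpha"), 1, 128.5, cfg)$positions))
  expect_lt(abs(mean(na) - 128.5), 3 * sd(na) / sqrt(length(na)))
  expect_equal(nrow(sample_dsb_positions(beam_preset("alpha"), 0, 128.5,
                                         cfg)$positions), 0)
  # X-ray breaks fill the nucleus; all within the 4.32 um radius
  b <- sample_dsb_positions(beam_preset("photon_ref"), 6, 35, cfg, seed = 2)
  expect_true(all(sqrt(rowSums(b$positions^2)) <= 4.32))
  # complexity drawn at the configured rate
  set.seed(43)
  cx <- unlist(replicate(60, sample_dsb_positions(
    beam_preset("photon_ref"), 3, 35, cfg)$complex))
  expect_lt(abs(mean(cx) - 0.43), 3 * sqrt(0.43 * 0.57 / length(cx)))
})

test_that("a single isolated break always self-repairs at its class rate", {
  b <- list(positions = matrix(c(1, 0, 0), 1, 3), complex = 0L)
  res <- simulate_repair(b, cfg, seed = 1)
  expect_identical(res$status, 0L)
  expect_equal(res$misrepair_fraction, 0)
  # completion times are exponential with the fast class rate
  set.seed(2)
  tt <- replicate(4000,
    simulate_repair(b, cfg)$completion_min)
  ks <- suppressWarnings(
    stats::ks.test(tt, "pexp", cfg$rate_fast_per_min))
  expect_gt(ks$p.value, 0.01)
  # complex class: slower rate; the median of the exponential completion
  # time is the 8 h half-life itself and is robust to the few runs that
  # outlast t_max (reported NA)
  bc <- list(positions = matrix(0, 1, 3), complex = 1L)
  set.seed(3)
  tc <- suppressWarnings(
    replicate(800, simulate_repair(bc, cfg)$completion_min))
  expect_equal(median(tc, na.rm = TRUE), log(2) / cfg$rate_slow_per_min,
               tolerance = 0.15)
})

test_that("coincident-break misrepair matches exhaustive enumeration", {
  set.seed(44)
  for (k in 2:3) {
    b <- list(positions = matrix(0, k, 3), complex = rep(0L, k))
    fr <- replicate(4000, simulate_repair(b, cfg)$misrepair_fraction)
    expected <- 1 - expected_correct_coincident(k) / k
    expect_lt(abs(mean(fr) - expected), 3 * sd(fr) / sqrt(length(fr)))
  }
})

test_that("well-separated breaks almost never misrepair", {
  r <- 20 * cfg$sigma_um
  b <- list(positions = rbind(c(0, 0, 0), c(r, 0, 0)), complex = c(0L, 0L))
  set.seed(45)
  mis <- replicate(3000, simulate_repair(b, cfg)$n_misrepaired > 0)
  expect_lt(mean(mis), 0.001)
})

test_that("every break ends joined: joins form a perfect matching", {
  set.seed(46)
  b <- sample_dsb_positions(beam_preset("photon_ref"), 3, 35, cfg)
  res <- simulate_repair(b, cfg)
  expect_true(all(res$status %in% c(0L, 1L)))
  expect_equal(res$n_misrepaired + sum(res$status == 0L), res$n_breaks)
  expect_true(all(is.finite(res$completion_min)))
})

test_that("X-ray misrepair increases with dose", {
  set.seed(47)
  m <- vapply(c(1, 3, 6), function(D) {
    mean(replicate(60, {
      b <- sample_dsb_positions(beam_preset("photon_ref"), D, 35, cfg)
      simulate_repair(b, cfg)$misrepair_fraction
    }), na.rm = TRUE)
  }, 0)
  expect_true(all(diff(m) > 0))
})

test_that("misrepair is non-increasing with interval for X+X", {
  ex <- list(beam = beam_preset("photon_ref"), dose_Gy = 3,
             yield_per_gy = 35)
  mis <- misrepair_vs_interval(ex, ex, c(0, 60, 360), cfg,
                               n_distributions = 40, n_repeats = 2,
                               seed = 48)
  expect_true(all(diff(mis$misrepair_fraction) < 0))
  # and the drop is well beyond Monte Carlo error
  expect_gt(mis$misrepair_fraction[1] - mis$misrepair_fraction[3],
            3 * sqrt(mis$se[1]^2 + mis$se[3]^2))
})

test_that("a long interval gives independent-fraction misrepair", {
  ex <- list(beam = beam_preset("photon_ref"), dose_Gy = 3,
             yield_per_gy = 35)
  far <- misrepair_vs_interval(ex, ex, 1440, cfg, n_distributions = 60,
                               n_repeats = 2, seed = 49)
  single <- misrepair_vs_interval(ex, NULL, 0, cfg, n_distributions = 60,
                                  n_repeats = 2, seed = 50)
  expect_lt(abs(far$misrepair_fraction - single$misrepair_fraction),
            3 * sqrt(far$se^2 + single$se^2))
})

test_that("alpha pairs recover less than half as much as X-ray pairs", {
  ex <- list(beam = beam_preset("photon_ref"), dose_Gy = 3,
             yield_per_gy = 35)
  ea <- list(beam = beam_preset("alpha"), dose_Gy = 0.75,
             yield_per_gy = 128.5)
  mx <- misrepair_vs_interval(ex, ex, c(0, 360), cfg,
                              n_distributions = 40, n_repeats = 2,
                              seed = 51)
  ma <- misrepair_vs_interval(ea, ea, c(0, 360), cfg,
                              n_distributions = 40, n_repeats = 2,
                              seed = 52)
  rel <- function(m) (m$misrepair_fraction[1] - m$misrepair_fraction[2]) /
    m$misrepair_fraction[2]
  expect_lt(rel(ma), rel(mx) / 2)
})

test_that("the misrepair-to-survival map inverts noiseless data", {
  mis <- tibble::tibble(interval_min = c(0, 30, 60, 120, 360),
                        misrepair_fraction = c(0.08, 0.065, 0.055, 0.047,
                                               0.042))
  m_inf <- 0.042
  obs <- data.frame(interval_min = mis$interval_min,
                    surviving_fraction =
                      0.1 * exp(-0.3 * (mis$misrepair_fraction - m_inf)))
  fit <- fit_survival_map(mis, obs)
  expect_equal(fit$s_infinity, 0.1, tolerance = 1e-8)
  expect_equal(fit$k_lethality, 0.3, tolerance = 1e-8)
  expect_false(fit$unidentifiable)
  # k = 0 truth: constant survival
  obs0 <- obs; obs0$surviving_fraction <- 0.2
  fit0 <- fit_survival_map(mis, obs0)
  expect_equal(fit0$k_lethality, 0, tolerance = 1e-10)
  expect_equal(fit0$s_infinity, 0.2, tolerance = 1e-8)
  # flat misrepair: unidentifiable
  flat <- mis; flat$misrepair_fraction <- 0.05
  ffit <- fit_survival_map(flat, obs0)
  expect_true(ffit$unidentifiable)
})
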
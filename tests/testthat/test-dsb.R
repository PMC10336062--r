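test_that("nucleus energy bookkeeping matches the closed form", {
  # 2.5 um water sphere: mass * 1 J/kg in keV
  expect_equal(nucleus_energy_per_gy_keV(2.5), 408.5, tolerance = 2e-4)
  # energy accounting identity: sum of track energies / E_Gy = realized dose
  tr <- sample_tracks(2.5, beam_quality("alpha", 129.3), 2, seed = 3)
  expect_equal(sum(tr$energy_keV) / nucleus_energy_per_gy_keV(2.5),
               attr(tr, "realized_dose_gy"), tolerance = 1e-12)
})

test_that("uniform chords have the 4R/3 mean and respect geometry", {
  set.seed(21)
  tr <- sample_tracks(2.5, beam_quality("electron_segment", 0.2), 25)
  expect_gt(nrow(tr), 1.2e4)
  expect_equal(mean(tr$length_um), 4 * 2.5 / 3, tolerance = 0.01)
  expect_true(all(tr$length_um <= 5 + 1e-12))
  # entry points on the sphere surface
  r_entry <- sqrt(tr$ex^2 + tr$ey^2 + tr$ez^2)
  expect_true(all(abs(r_entry - 2.5) < 1e-9))
})

test_that("alpha track count follows the energy balance", {
  # 408.5 keV per Gy / (129.3 keV/um * 3.333 um per track) ~ 0.948
  set.seed(22)
  n <- replicate(4000, nrow(sample_tracks(2.5, beam_quality("alpha", 129.3),
                                          1)))
  expected <- nucleus_energy_per_gy_keV(2.5) / (129.3 * 4 * 2.5 / 3)
  expect_equal(mean(n), expected,
               tolerance = 3 * sqrt(expected / 4000) / expected)
  expect_equal(nrow(sample_tracks(2.5, beam_quality("alpha", 129.3), 0)), 0)
  expect_error(sample_tracks(2.5, beam_quality("alpha", 129.3), -1),
               "non-negative")
})

test_that("SSB placement hits the 1000/Gy budget at any LET", {
  cfg <- default_config()
  budget <- nucleus_energy_per_gy_keV(2.5) / cfg$energy_per_ssb_keV
  set.seed(23)
  for (let in c(2, 129.3)) {
    tot_ssb <- 0; tot_dose <- 0
    for (k in 1:60) {
      tr <- sample_tracks(2.5, beam_quality("electron_segment", let), 1)
      tot_dose <- tot_dose + attr(tr, "realized_dose_gy")
      tot_ssb <- tot_ssb + nrow(place_ssbs(tr, cfg))
    }
    expect_equal(tot_ssb / tot_dose, budget, tolerance = 0.05)
  }
  # single chord: mean count = LET * L / 0.41
  one <- tibble::tibble(track_id = 1L, ex = 0, ey = 0, ez = 0, ux = 1,
                        uy = 0, uz = 0, length_um = 3, energy_keV = 50 * 3)
  n <- replicate(300, nrow(place_ssbs(one, cfg)))
  expect_equal(mean(n), 50 * 3 / 0.41, tolerance = 0.05)
  # fair strand assignment
  tr <- sample_tracks(2.5, beam_quality("electron_segment", 26), 1,
                      seed = 11)
  s <- place_ssbs(tr, cfg)$strand
  expect_lt(abs(mean(s) - 0.5), 3 * sqrt(0.25 / length(s)))
})

test_that("DSB pairing follows the opposite-strand 3.2 nm rule", {
  mk <- function(xs_nm, strands) tibble::tibble(
    x = xs_nm * 1e-3, y = 0, z = 0, strand = strands,
    track_id = 1L)
  # two SSBs 2 nm apart: strands are re-assigned per resample, so over many
  # resamples the mean DSB count is P(opposite strands) = 1/2
  cnt <- pair_dsbs(mk(c(0, 2), c(0L, 1L)), n_strand_resamples = 4000,
                   seed = 1)
  expect_equal(cnt$mean_count, 0.5, tolerance = 0.05)
  # two SSBs 4 nm apart can never pair
  expect_equal(pair_dsbs(mk(c(0, 4), c(0L, 1L)),
                         n_strand_resamples = 200, seed = 1)$mean_count, 0)
})

test_that("greedy pairing matches exhaustive matching on small instances", {
  # instances drawn at the calibrated alpha-track densities: exponential
  # along-track spacing at 315 SSB/um and Gaussian radial jitter
  set.seed(31)
  n_match <- 0; n_inst <- 200
  for (i in seq_len(n_inst)) {
    n <- sample(3:8, 1)
    pos <- cbind(cumsum(rexp(n, 315)), rnorm(n, 0, 1.87e-3),
                 rnorm(n, 0, 1.87e-3))
    strands <- rbinom(n, 1, 0.5)
    oracle <- max_matching_count(pos, strands, 3.2e-3)
    ssb <- tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                          strand = strands, track_id = 1L)
    # force the oracle's strand assignment by averaging over resamples is
    # not possible; instead call the internal greedy path directly
    ord <- order(ssb$x)
    cand <- radmix:::.close_pairs_cpp(cbind(ssb$x[ord], ssb$y[ord],
                                            ssb$z[ord]), 3.2e-3)
    greedy <- 0
    if (length(cand$i) > 0) {
      o <- order(cand$dist, cand$i, cand$j)
      used <- rep(FALSE, n)
      st <- strands[ord]
      for (p in o) {
        a <- cand$i[p]; b <- cand$j[p]
        if (!used[a] && !used[b] && st[a] != st[b]) {
          used[a] <- used[b] <- TRUE
          greedy <- greedy + 1
        }
      }
    }
    if (greedy == oracle) n_match <- n_match + 1
    expect_lte(greedy, oracle)
  }
  expect_gte(n_match / n_inst, 0.99)
})

test_that("pairing resolves the A-B-C triplet to a single nearest pair", {
  # A(0, strand 1), B(1 nm, strand 2), C(2.5 nm, strand 2): A-B pairs, C is
  # left unpaired under greedy and under exhaustive matching
  pos <- cbind(c(0, 1e-3, 2.5e-3), 0, 0)
  strands <- c(1L, 0L, 0L)
  expect_identical(max_matching_count(pos, strands, 3.2e-3), 1L)
})

test_that("calibrated yields are monotone in LET and close to linear", {
  cfg <- default_config()
  beams <- list(beam_quality("proton", 25), beam_quality("proton", 50),
                beam_quality("proton", 100))
  yc <- dsb_yield_curve(beams, cfg, n_runs = 20, seed = 5)
  expect_true(all(diff(yc$mean_dsb_per_gy) > 0))
  fit <- lm(mean_dsb_per_gy ~ let_keV_per_um, data = yc)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_error(dsb_yield_curve(beams, cfg, n_runs = 1), "at least 2")
})

test_that("doubling the radial jitter strictly reduces the alpha yield", {
  cfg <- default_config()
  y1 <- dsb_yield(beam_preset("alpha"), cfg, n_runs = 20, seed = 9)
  cfg2 <- cfg
  cfg2$sigma_r_nm <- 2 * cfg$sigma_r_nm
  y2 <- dsb_yield(beam_preset("alpha"), cfg2, n_runs = 20, seed = 9)
  expect_lt(y2$yield_per_gy, y1$yield_per_gy)
})
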
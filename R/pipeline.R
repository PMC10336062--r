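#' Run the full analysis pipeline
#'
#' Composes the package end to end on synthetic or supplied data:
#' (1) generate (or read) survival and foci tables; (2) fit single-fraction
#' LQ parameters per modality and compute RBE_D10; (3) fit split-dose
#' recovery curves per condition, run the shared-half-life and
#' order-independence F-tests, and estimate RBE_SLD with a bootstrap CI;
#' (4) simulate the calibrated DSB-induction surrogate for a small yield
#' curve and RBE_DSB; (5) simulate misrepair versus interval for the X+X
#' schedule and fit the misrepair-to-survival map against the generated
#' survival; (6) fit the exponential and cluster foci models. Writes
#' `report.json` plus per-stage CSVs under `out_dir` and returns the report.
#'
#' @param preset ground-truth preset name (`"pc3"` or `"u2os"`) for
#'   synthetic input, or `NULL` when both paths are given
#' @param survival_path,foci_path optional CSV inputs replacing the generator
#' @param out_dir output directory (created if needed); `NULL` writes nothing
#' @param seed integer seed governing every stochastic stage
#' @param config run configuration
#' @param n_boot bootstrap resamples for the RBE CIs
#' @param induction_runs runs per beam for the DSB yield stage
#' @param repair_distributions damage geometries per interval in the
#'   misrepair stage
#' @return the report as a nested list (class `radmix_report`)
#' @export
run_pipeline <- function(preset = "pc3", survival_path = NULL,
                         foci_path = NULL, out_dir = NULL, seed = 1,
                         config = default_config(), n_boot = 1000,
                         induction_runs = 8, repair_distributions = 20) {
  set.seed(seed)
  truth <- NULL
  if (is.null(survival_path)) {
    truth <- ground_truth_preset(preset, config)
    surv <- gen_survival_dataset(truth, seed = seed)
    foci <- gen_foci_dataset(truth, seed = seed + 1)
  } else {
    surv <- read_survival_table(survival_path)
    foci <- read_foci_table(foci_path)
  }

  # single-fraction LQ fits and RBE_D10
  single <- surv[surv$dose_2_Gy == 0 & surv$dose_1_Gy > 0 |
                   (surv$dose_2_Gy == 0 & surv$dose_1_Gy == 0), ]
  lq_x <- fit_lq(single[single$modality_1 == "xray", ])
  lq_a <- fit_lq(single[single$modality_1 == "alpha", ])
  rbe10 <- rbe_d10(lq_x, lq_a, n_boot = n_boot, seed = seed + 2)

  # split-dose recovery and RBE_SLD
  two <- surv[surv$dose_2_Gy > 0, ]
  cond <- paste0(substr(two$modality_1, 1, 1), substr(two$modality_2, 1, 1))
  by_cond <- split(two, cond)
  fits <- lapply(by_cond, function(r)
    tryCatch(fit_recovery_curve(r), error = function(e) NULL))
  with_recovery <- names(fits)[vapply(fits, function(f)
    !is.null(f) && !f$no_recovery, TRUE)]
  shared <- if (length(with_recovery) >= 2)
    shared_halflife_ftest(by_cond[with_recovery]) else NULL
  order_test <- if (all(c("xa", "ax") %in% names(by_cond)))
    order_independence_ftest(by_cond$xa, by_cond$ax) else NULL
  rbe_sld <- NULL
  if (all(c("xx", "xa") %in% names(by_cond))) {
    dxx <- recovery_magnitude(by_cond$xx)
    dxa <- recovery_magnitude(by_cond$xa)
    rbe_sld <- estimate_rbe_sld(
      dxa, dxx, dose_x_Gy = 3, dose_a_Gy = 0.75,
      bootstrap_inputs = list(xx = by_cond$xx, xa = by_cond$xa),
      n_boot = n_boot, seed = seed + 3)
  }

  # DSB induction surrogate (shipped calibrated config)
  yields <- dsb_yield_curve(list(beam_preset("alpha")), config,
                            n_runs = induction_runs, seed = seed + 4)

  # misrepair vs interval for X+X, mapped to the generated survival
  intervals <- sort(unique(two$interval_min))
  exp_x <- list(beam = beam_preset("photon_ref", config), dose_Gy = 3,
                yield_per_gy = config$dsb_per_gy_ref)
  mis <- misrepair_vs_interval(exp_x, exp_x, intervals, config,
                               n_distributions = repair_distributions,
                               n_repeats = 2, seed = seed + 5)
  smap <- if ("xx" %in% names(by_cond))
    fit_survival_map(mis, data.frame(
      interval_min = by_cond$xx$interval_min,
      surviving_fraction = by_cond$xx$surviving_fraction)) else NULL

  # foci models
  fx <- foci[foci$modality == "xray", ]
  fa <- foci[foci$modality == "alpha", ]
  foci_exp_x <- fit_foci_exponential(fx)
  foci_exp_a <- fit_foci_exponential(fa)
  foci_cluster <- fit_foci_cluster(fx, fa, config,
                                   rbe_dsb = yields$rbe_dsb[1])

  report <- list(
    seed = seed,
    config_hash = .config_hash(config),
    cell_line = surv$cell_line[1],
    lq = list(
      xray = list(alpha = lq_x$alpha_per_Gy, beta = lq_x$beta_per_Gy2),
      alpha = list(alpha = lq_a$alpha_per_Gy, beta = lq_a$beta_per_Gy2)),
    rbe_d10 = list(value = rbe10$value, ci_low = rbe10$ci_low,
                   ci_high = rbe10$ci_high),
    recovery = lapply(fits, function(f) if (is.null(f)) NULL else
      list(half_life_min = f$half_life_min,
           delta = f$interaction_magnitude,
           s_infinity = f$s_infinity, no_recovery = f$no_recovery)),
    shared_halflife = if (is.null(shared)) NULL else
      list(f_statistic = shared$f_statistic, p_value = shared$p_value,
           shared_half_life_min = shared$shared_half_life_min),
    order_independence = if (is.null(order_test)) NULL else
      list(f_statistic = order_test$f_statistic,
           p_value = order_test$p_value),
    rbe_sld = if (is.null(rbe_sld)) NULL else
      list(value = rbe_sld$value, ci_low = rbe_sld$ci_low,
           ci_high = rbe_sld$ci_high),
    dsb_induction = list(
      reference_yield_per_gy = attr(yields, "reference_yield_per_gy"),
      alpha_yield_per_gy = yields$mean_dsb_per_gy[1],
      rbe_dsb = yields$rbe_dsb[1]),
    misrepair = list(interval_min = mis$interval_min,
                     misrepair_fraction = mis$misrepair_fraction),
    survival_map = if (is.null(smap)) NULL else
      list(s_infinity = smap$s_infinity, k_lethality = smap$k_lethality,
           m_infinity = smap$m_infinity),
    foci = list(
      exponential_xray = list(n0 = foci_exp_x$n0, p = foci_exp_x$p,
                              k_per_h = foci_exp_x$k_per_h),
      exponential_alpha = list(n0 = foci_exp_a$n0, p = foci_exp_a$p,
                               k_per_h = foci_exp_a$k_per_h),
      cluster = list(n0_xray = foci_cluster$n0_xray,
                     n_clusters = foci_cluster$n_clusters_mean,
                     persistent_rate = foci_cluster$persistent_rate)),
    truth = if (is.null(truth)) NULL else
      list(rbe_sld = truth$rbe_sld, rbe_d10 = truth$rbe_d10,
           half_life_min = truth$half_life_min)
  )
  class(report) <- "radmix_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_survival_table(surv, file.path(out_dir, "survival.csv"))
    write_foci_table(foci, file.path(out_dir, "foci.csv"))
    utils::write.csv(mis, file.path(out_dir, "misrepair.csv"),
                     row.names = FALSE)
    utils::write.csv(yields, file.path(out_dir, "dsb_yields.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

.config_hash <- function(config) {
  s <- paste(names(config), vapply(config, function(x)
    paste(format(x, digits = 15), collapse = ","), ""), collapse = ";")
  # small deterministic string hash (djb2)
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", h)
}
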
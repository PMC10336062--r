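#' Fit an exponential decay to foci time-course data
#'
#' N(t) = (N0 - P) exp(-k t) + P: initial foci N0, residual (persistent)
#' foci P, repair rate k (1/h). Weighted least squares with weights
#' 1/(sd/sqrt(n))^2 per point (uniform if SDs are absent or degenerate);
#' constraints N0 >= P >= 0, k > 0.
#'
#' @param records foci tibble (see [read_foci_table()]) for one condition,
#'   with at least 4 distinct time points
#' @return list of class `foci_exp_fit`: `n0`, `p`, `k_per_h`, `covariance`,
#'   `residual_ss`, `dof`
#' @export
fit_foci_exponential <- function(records) {
  if (length(unique(records$time_h)) < 4)
    stop("need at least 4 distinct time points")
  dat <- data.frame(t = records$time_h, y = records$mean_foci)
  se <- records$sd_foci / sqrt(records$n_cells)
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, nrow(dat))
  n0_0 <- max(dat$y)
  p_0 <- max(min(dat$y), 1e-3)
  fit <- nls(y ~ (n0 - p) * exp(-k * t) + p, data = dat,
             start = list(n0 = n0_0, p = p_0, k = 0.3),
             lower = c(0, 0, 1e-6), upper = c(Inf, Inf, Inf),
             weights = w, algorithm = "port",
             control = list(maxiter = 500, warnOnly = TRUE))
  cf <- coef(fit)
  if (cf[["p"]] > cf[["n0"]]) warning("fitted P exceeds N0")
  structure(list(n0 = cf[["n0"]], p = cf[["p"]], k_per_h = cf[["k"]],
                 covariance = tryCatch(vcov(fit),
                                       error = function(e) NULL),
                 residual_ss = sum(w * residuals(fit)^2),
                 dof = nrow(dat) - 3L),
            class = "foci_exp_fit")
}

#' Per-DSB survival (unrepaired) probability
#'
#' Probability that an individual DSB is still unrepaired at time t:
#' q(t) = p_per + (1 - p_per) \[(1 - c) e^(-k_fast t) + c e^(-k_slow t)\],
#' with c the complex-break fraction (0.43), class rates shared with the
#' misrepair simulator (converted to 1/h), and `p_per` the probability the
#' break never repairs.
#'
#' @param t_h time in hours (vectorised), >= 0
#' @param persistent_rate p_per in \[0, 1)
#' @param config run configuration (class rates, complex fraction)
#' @return q(t) in \[0, 1\]
#' @export
per_dsb_survival_prob <- function(t_h, persistent_rate = 0,
                                  config = default_config()) {
  if (any(t_h < 0)) stop("time must be non-negative")
  if (persistent_rate < 0 || persistent_rate >= 1)
    stop("persistent_rate must lie in [0, 1)")
  cfrac <- config$complex_fraction
  k_fast <- config$rate_fast_per_min * 60
  k_slow <- config$rate_slow_per_min * 60
  persistent_rate + (1 - persistent_rate) *
    ((1 - cfrac) * exp(-k_fast * t_h) + cfrac * exp(-k_slow * t_h))
}

#' Cluster foci model parameters
#'
#' @param n_clusters_mean mean number of damage clusters per cell (each
#'   cluster is one visible focus until all its DSBs are repaired)
#' @param dsb_per_cluster_mean Poisson mean DSBs per cluster (1 DSB per
#'   cluster for sparse X-ray damage)
#' @param persistent_rate per-DSB probability of never repairing
#' @param n0_xray initial X-ray foci at the fitted dose (equals the X-ray
#'   cluster count since X-ray clusters hold exactly one DSB)
#' @param config run configuration (class rates, complex fraction)
#' @return list of class `cluster_model_params`
#' @export
cluster_model_params <- function(n_clusters_mean, dsb_per_cluster_mean,
                                 persistent_rate, n0_xray,
                                 config = default_config()) {
  stopifnot(n_clusters_mean > 0, dsb_per_cluster_mean > 0,
            persistent_rate >= 0, persistent_rate < 1, n0_xray >= 0)
  structure(list(n_clusters_mean = n_clusters_mean,
                 dsb_per_cluster_mean = dsb_per_cluster_mean,
                 persistent_rate = persistent_rate,
                 n0_xray = n0_xray, config = config),
            class = "cluster_model_params")
}

#' Expected visible foci per cell
#'
#' A cluster stays visible as one focus until all of its DSBs are repaired.
#' For sparse X-ray damage (one DSB per focus) the expectation is
#' `n0_xray * q(t)`. For alpha-particle damage with Poisson(mu) DSBs per
#' cluster, the probability a cluster still holds at least one unrepaired
#' DSB is `1 - exp(-mu q(t))` (Poisson void probability), so the expectation
#' is `N (1 - exp(-mu q(t)))`. Note the initial visible count is
#' `N (1 - exp(-mu))`, not N: empty clusters are never visible.
#'
#' @param t_h time in hours (vectorised)
#' @param params [cluster_model_params()]
#' @param modality `"alpha"` (clustered) or `"xray"` (one DSB per focus)
#' @return mean visible foci per cell
#' @export
expected_visible_foci <- function(t_h, params, modality = c("alpha", "xray")) {
  modality <- match.arg(modality)
  q <- per_dsb_survival_prob(t_h, params$persistent_rate, params$config)
  if (modality == "xray") params$n0_xray * q
  else params$n_clusters_mean * (1 - exp(-params$dsb_per_cluster_mean * q))
}

#' Monte Carlo twin of the cluster foci model
#'
#' Per cell: Poisson cluster count, Poisson DSBs per cluster (exactly 1 for
#' X-rays), each DSB persistent with probability `persistent_rate` or
#' repaired after an exponential time of its complexity class. A cluster is
#' visible at t while any DSB is unrepaired. The per-time mean over cells
#' converges to [expected_visible_foci()].
#'
#' @param params [cluster_model_params()]
#' @param n_cells number of simulated cells
#' @param t_h vector of observation times (hours)
#' @param modality `"alpha"` or `"xray"`
#' @param seed optional RNG seed
#' @return matrix `n_cells x length(t_h)` of visible foci counts
#' @export
simulate_foci_mc <- function(params, n_cells, t_h,
                             modality = c("alpha", "xray"), seed = NULL) {
  modality <- match.arg(modality)
  if (n_cells < 1) stop("n_cells must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  cfg <- params$config
  k_fast <- cfg$rate_fast_per_min * 60
  k_slow <- cfg$rate_slow_per_min * 60
  n_mean <- if (modality == "xray") params$n0_xray else params$n_clusters_mean
  out <- matrix(0L, n_cells, length(t_h))
  for (cell in seq_len(n_cells)) {
    ncl <- rpois(1, n_mean)
    if (ncl == 0) next
    sizes <- if (modality == "xray") rep(1L, ncl)
             else rpois(ncl, params$dsb_per_cluster_mean)
    for (cl in seq_len(ncl)) {
      f <- sizes[cl]
      if (f == 0) next
      persistent <- runif(f) < params$persistent_rate
      cplx <- runif(f) < cfg$complex_fraction
      t_rep <- ifelse(persistent, Inf,
                      rexp(f, ifelse(cplx, k_slow, k_fast)))
      clear_t <- max(t_rep)
      out[cell, ] <- out[cell, ] + as.integer(t_h < clear_t)
    }
  }
  out
}

#' Joint cluster-model fit to X-ray and alpha foci kinetics
#'
#' Simultaneous weighted least squares to both modalities' foci time courses
#' with exactly three free parameters: the initial X-ray foci yield
#' `n0_xray`, the persistent DSB rate `persistent_rate`, and the alpha
#' cluster count `n_clusters_mean`. The total alpha DSB budget is held fixed
#' at `rbe_dsb * dsb_per_gy_ref * dose` (128.5 DSB/Gy at this source's LET),
#' so the per-cluster mean is `budget / n_clusters_mean`; repair class rates
#' come from the configuration and are not fitted.
#'
#' @param xray_records,alpha_records foci tibbles for the two modalities
#'   (same cell line and dose)
#' @param config run configuration
#' @param rbe_dsb DSB-yield RBE of the alpha source (default 3.67)
#' @param dose_Gy exposure dose (default taken from the records)
#' @return [cluster_model_params()] with attributes `covariance`,
#'   `residual_ss`, `dof`, `boundary` (TRUE if a parameter sits on a bound)
#' @export
fit_foci_cluster <- function(xray_records, alpha_records,
                             config = default_config(), rbe_dsb = 3.67,
                             dose_Gy = NULL) {
  if (is.null(dose_Gy)) dose_Gy <- alpha_records$dose_Gy[1]
  budget <- rbe_dsb * config$dsb_per_gy_ref * dose_Gy
  dat <- data.frame(
    t = c(xray_records$time_h, alpha_records$time_h),
    y = c(xray_records$mean_foci, alpha_records$mean_foci),
    is_x = rep(c(1, 0), c(nrow(xray_records), nrow(alpha_records))))
  se <- c(xray_records$sd_foci / sqrt(xray_records$n_cells),
          alpha_records$sd_foci / sqrt(alpha_records$n_cells))
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, nrow(dat))
  model <- function(t, is_x, n0, pper, N) {
    q <- per_dsb_survival_prob(t, pper, config)
    is_x * n0 * q + (1 - is_x) * N * (1 - exp(-(budget / N) * q))
  }
  fit <- nls(y ~ model(t, is_x, n0, pper, N), data = dat,
             start = list(n0 = max(dat$y[dat$is_x == 1]), pper = 0.05,
                          N = max(1, max(dat$y[dat$is_x == 0]))),
             lower = c(1e-3, 0, 1e-3), upper = c(Inf, 0.999, Inf),
             weights = w, algorithm = "port",
             control = list(maxiter = 1000, warnOnly = TRUE))
  cf <- coef(fit)
  boundary <- cf[["pper"]] <= 0 || cf[["pper"]] >= 0.999 ||
    cf[["n0"]] <= 1e-3 || cf[["N"]] <= 1e-3
  out <- cluster_model_params(cf[["N"]], budget / cf[["N"]], cf[["pper"]],
                              cf[["n0"]], config)
  attr(out, "covariance") <- tryCatch(vcov(fit), error = function(e) NULL)
  attr(out, "residual_ss") <- sum(w * residuals(fit)^2)
  attr(out, "dof") <- nrow(dat) - 3L
  attr(out, "boundary") <- boundary
  attr(out, "dsb_budget") <- budget
  out
}
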
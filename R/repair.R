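#' Sample DSB positions for the misrepair model
#'
#' X-ray exposures place breaks uniformly in the (4.32 um radius) nucleus
#' with count Poisson(`yield_per_gy * dose`). Alpha-particle exposures first
#' sample track chords (Poisson count from the nucleus energy balance), then
#' draw the break count as Poisson(`yield_per_gy * realized dose`), allocate
#' breaks to tracks proportional to chord length, and scatter them about the
#' track with an isotropic perpendicular Gaussian of scale `sigma_track_nm`.
#' Each break is independently complex with probability `complex_fraction`
#' (0.43).
#'
#' @param beam [beam_quality()]; `photon_ref`/`electron_segment` are treated
#'   as uniform low-LET exposures, `alpha`/`proton` as track-correlated
#' @param dose_Gy dose (Gy)
#' @param yield_per_gy DSB yield per Gray (35 for the X-ray reference; the
#'   reference yield scaled by RBE_DSB for ions, e.g. 128.5 for this alpha
#'   source)
#' @param config run configuration
#' @param seed optional RNG seed
#' @return list: `positions` (n x 3 matrix, um), `complex` (0/1 vector)
#' @export
sample_dsb_positions <- function(beam, dose_Gy, yield_per_gy,
                                 config = default_config(), seed = NULL) {
  if (dose_Gy < 0) stop("dose must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  R <- config$repair_nucleus_radius_um
  uniform <- beam$particle %in% c("photon_ref", "electron_segment")
  if (uniform) {
    n <- rpois(1, yield_per_gy * dose_Gy)
    pos <- .runif_sphere(n, R)
  } else {
    tr <- sample_tracks(R, beam, dose_Gy)
    dose <- attr(tr, "realized_dose_gy")
    n <- if (dose > 0) rpois(1, yield_per_gy * dose) else 0L
    if (n > 0) {
      probs <- tr$length_um / sum(tr$length_um)
      alloc <- as.integer(sample(nrow(tr), n, replace = TRUE, prob = probs))
      sig <- config$sigma_track_nm * 1e-3
      pos <- matrix(0, n, 3)
      for (k in seq_len(n)) {
        i <- alloc[k]
        u <- c(tr$ux[i], tr$uy[i], tr$uz[i])
        a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        v1 <- a - sum(a * u) * u
        v1 <- v1 / sqrt(sum(v1^2))
        v2 <- c(u[2] * v1[3] - u[3] * v1[2],
                u[3] * v1[1] - u[1] * v1[3],
                u[1] * v1[2] - u[2] * v1[1])
        s <- runif(1, 0, tr$length_um[i])
        g <- rnorm(2, 0, sig)
        pos[k, ] <- c(tr$ex[i], tr$ey[i], tr$ez[i]) + s * u +
          g[1] * v1 + g[2] * v2
      }
    } else pos <- matrix(0, 0, 3)
  }
  list(positions = pos,
       complex = if (nrow(pos) > 0)
         rbinom(nrow(pos), 1, config$complex_fraction) else integer())
}

.runif_sphere <- function(n, R) {
  if (n == 0) return(matrix(0, 0, 3))
  m <- matrix(rnorm(3 * n), n, 3)
  m <- m / sqrt(rowSums(m^2))
  m * (R * runif(n)^(1 / 3))
}

#' Simulate stochastic DSB end joining
#'
#' Exact Gillespie kinetic Monte Carlo over all free break-end pairs. Each
#' end may join any other free end with rate
#' `k_pair * exp(-r^2 / (2 sigma^2))`, where `r` is the distance between the
#' parent breaks and `k_pair` the rate constant of the slower complexity
#' class of the two parents (simple: `rate_fast_per_min`, t1/2 = 25 min;
#' complex: `rate_slow_per_min`, t1/2 = 8 h by default). The simulation runs
#' until no free ends remain or `t_max_min` is reached. A break is correctly
#' repaired when its two ends rejoin each other and misrepaired when either
#' end joins an end of a different break; ends still free at `t_max_min` are
#' counted as unrepaired and excluded from the misrepair denominator.
#'
#' @param breaks list with `positions` and `complex`
#'   (see [sample_dsb_positions()])
#' @param config run configuration
#' @param seed optional RNG seed
#' @param second_fraction optional second break set injected at
#'   `interval_min`
#' @param interval_min injection time of the second fraction (minutes)
#' @return list: `n_breaks`, `n_misrepaired`, `n_unrepaired`,
#'   `misrepair_fraction`, `status` (0 correct / 1 misrepaired /
#'   2 unrepaired), `fraction` (1 or 2), `completion_min`
#' @export
simulate_repair <- function(breaks, config = default_config(), seed = NULL,
                            second_fraction = NULL, interval_min = 0) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- breaks$positions
  c1 <- as.integer(breaks$complex)
  if (is.null(second_fraction)) {
    p2 <- matrix(0, 0, 3); c2 <- integer()
  } else {
    p2 <- second_fraction$positions
    c2 <- as.integer(second_fraction$complex)
  }
  if (nrow(p1) + nrow(p2) == 0) stop("at least one break is required")
  res <- .simulate_repair_cpp(p1, c1, p2, c2, interval_min,
                              config$sigma_um, config$rate_fast_per_min,
                              config$rate_slow_per_min, config$t_max_min)
  status <- res$status
  n_un <- sum(status == 2L)
  if (n_un > 0)
    warning(n_un, " break(s) unrepaired at t_max; excluded from the ",
            "misrepair denominator")
  n_rep <- sum(status != 2L)
  list(n_breaks = length(status),
       n_misrepaired = sum(status == 1L),
       n_unrepaired = n_un,
       misrepair_fraction = if (n_rep > 0) sum(status == 1L) / n_rep else
         NA_real_,
       status = status, fraction = res$fraction,
       completion_min = res$completion_min)
}

#' Misrepair versus inter-fraction interval
#'
#' For each interval T, damage distributions are generated for both
#' exposures, repair is simulated with the second exposure injected at T,
#' and the misrepaired-break fraction is averaged over
#' `n_distributions * n_repeats` simulations (fresh geometry per
#' distribution, repeated repair realisations per geometry).
#'
#' @param exposure_1,exposure_2 lists `list(beam=, dose_Gy=, yield_per_gy=)`;
#'   `exposure_2 = NULL` simulates a single fraction
#' @param intervals_min numeric vector of intervals (minutes)
#' @param config run configuration
#' @param n_distributions independent damage geometries per interval
#' @param n_repeats repair realisations per geometry
#' @param seed RNG seed
#' @return tibble: `interval_min`, `misrepair_fraction` (mean), `se`,
#'   `mean_breaks`, `n_sims`
#' @export
misrepair_vs_interval <- function(exposure_1, exposure_2, intervals_min,
                                  config = default_config(),
                                  n_distributions = 50, n_repeats = 3,
                                  seed = NULL) {
  if (is.null(exposure_1)) stop("exposure_1 is required")
  if (any(intervals_min < 0)) stop("intervals must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(intervals_min, function(Tint) {
    fr <- numeric(0)
    nb <- numeric(0)
    for (d in seq_len(n_distributions)) {
      b1 <- sample_dsb_positions(exposure_1$beam, exposure_1$dose_Gy,
                                 exposure_1$yield_per_gy, config)
      b2 <- if (!is.null(exposure_2))
        sample_dsb_positions(exposure_2$beam, exposure_2$dose_Gy,
                             exposure_2$yield_per_gy, config) else NULL
      n1 <- nrow(b1$positions)
      n2 <- if (is.null(b2)) 0L else nrow(b2$positions)
      if (n1 + n2 == 0) next
      if (n2 == 0) b2 <- NULL
      for (r in seq_len(n_repeats)) {
        sim <- suppressWarnings(
          simulate_repair(if (n1 > 0) b1 else b2, config,
                          second_fraction = if (n1 > 0) b2 else NULL,
                          interval_min = Tint))
        fr <- c(fr, sim$misrepair_fraction)
        nb <- c(nb, sim$n_breaks)
      }
    }
    fr <- fr[is.finite(fr)]
    tibble::tibble(interval_min = Tint,
                   misrepair_fraction = mean(fr),
                   se = sd(fr) / sqrt(length(fr)),
                   mean_breaks = mean(nb), n_sims = length(fr))
  })
  do.call(rbind, rows)
}

#' Map simulated misrepair to observed split-dose survival
#'
#' Fits S(T) = S_inf * exp(-k (M(T) - M_inf)) on the log scale by least
#' squares, where M(T) is the simulated misrepair fraction at interval T and
#' M_inf the misrepair at the longest interval (independent fractions). `k`
#' is the probability that a misrepair event is lethal and is constrained
#' non-negative. If the misrepair values carry no interval contrast the map
#' is unidentifiable and flagged.
#'
#' @param misrepair_by_interval tibble from [misrepair_vs_interval()] (needs
#'   `interval_min`, `misrepair_fraction`)
#' @param observed_survival data frame with `interval_min` and
#'   `surviving_fraction` at matching intervals (replicates allowed)
#' @return list: `s_infinity`, `k_lethality`, `m_infinity`, `covariance`,
#'   `unidentifiable`
#' @export
fit_survival_map <- function(misrepair_by_interval, observed_survival) {
  m <- misrepair_by_interval
  if (nrow(m) < 3) stop("need at least 3 intervals")
  m_inf <- m$misrepair_fraction[which.max(m$interval_min)]
  obs <- observed_survival
  mm <- m$misrepair_fraction[match(obs$interval_min, m$interval_min)]
  if (anyNA(mm))
    stop("observed intervals missing from the misrepair table")
  x <- mm - m_inf
  y <- log(obs$surviving_fraction)
  if (max(x) - min(x) < 1e-12) {
    return(list(s_infinity = exp(mean(y)), k_lethality = NA_real_,
                m_infinity = m_inf, covariance = NULL,
                unidentifiable = TRUE))
  }
  fit <- lm(y ~ x)
  k <- max(0, -coef(fit)[[2]])
  if (-coef(fit)[[2]] < 0) {  # refit with k pinned at zero
    s_inf <- exp(mean(y))
    return(list(s_infinity = s_inf, k_lethality = 0, m_infinity = m_inf,
                covariance = NULL, unidentifiable = FALSE))
  }
  list(s_infinity = exp(coef(fit)[[1]]), k_lethality = k,
       m_infinity = m_inf, covariance = vcov(fit), unidentifiable = FALSE)
}
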
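#' Linear-quadratic parameter set
#'
#' @param alpha_per_Gy linear coefficient (1/Gy), non-negative
#' @param beta_per_Gy2 quadratic coefficient (1/Gy^2), non-negative
#' @param covariance optional 2x2 covariance matrix of (alpha, beta)
#' @return an object of class `lq_params`
#' @export
lq_params <- function(alpha_per_Gy, beta_per_Gy2, covariance = NULL) {
  if (alpha_per_Gy < 0 || beta_per_Gy2 < 0)
    stop("alpha and beta must be non-negative")
  if (!is.null(covariance))
    stopifnot(is.matrix(covariance), all(dim(covariance) == c(2L, 2L)))
  structure(list(alpha_per_Gy = alpha_per_Gy, beta_per_Gy2 = beta_per_Gy2,
                 covariance = covariance),
            class = "lq_params")
}

#' Linear-quadratic surviving fraction
#'
#' S = exp(-alpha D - beta D^2).
#'
#' @param params an [lq_params()] object
#' @param dose_Gy dose in Gy (vectorised), non-negative
#' @return surviving fraction(s) in (0, 1]
#' @export
#' @examples
#' lq_survival(lq_params(0.5, 0), 2)  # exp(-1)
lq_survival <- function(params, dose_Gy) {
  if (any(dose_Gy < 0)) stop("dose must be non-negative")
  exp(-params$alpha_per_Gy * dose_Gy - params$beta_per_Gy2 * dose_Gy^2)
}

#' Additive mixed-field surviving fraction
#'
#' For a combined alpha-particle dose `dose_alpha_Gy` and X-ray dose
#' `dose_x_Gy`, the purely additive model is
#' S = exp(-a_A D_A - a_x D_x - (D_A sqrt(b_A) + D_x sqrt(b_x))^2):
#' linear terms add independently while sublethal damage from the two
#' modalities pools into a single quadratic interaction. With one dose zero
#' it reduces exactly to the single-modality LQ model.
#'
#' @param lqset named list of [lq_params()] with entries `alpha` and `xray`
#' @param dose_alpha_Gy alpha-particle dose (Gy)
#' @param dose_x_Gy X-ray dose (Gy)
#' @return surviving fraction
#' @export
additive_mixed_survival <- function(lqset, dose_alpha_Gy, dose_x_Gy) {
  if (any(dose_alpha_Gy < 0) || any(dose_x_Gy < 0))
    stop("doses must be non-negative")
  for (m in c("alpha", "xray"))
    if (is.null(lqset[[m]])) stop("modality '", m, "' missing from LQ set")
  a <- lqset$alpha; x <- lqset$xray
  exp(-a$alpha_per_Gy * dose_alpha_Gy - x$alpha_per_Gy * dose_x_Gy -
        (dose_alpha_Gy * sqrt(a$beta_per_Gy2) +
           dose_x_Gy * sqrt(x$beta_per_Gy2))^2)
}

#' Two-fraction Lea-Catcheside dose-protraction factor
#'
#' G = (1/(lambda t)) \[1 - (1/(lambda t))(1 - e^(-lambda t)) +
#' (e^(-lambda T)/(2 lambda t))(1 - e^(-lambda t))^2\] for two equal
#' fractions each delivered over `t` minutes, separated by `T` minutes, with
#' repair constant `lambda` (1/min). G multiplies the quadratic (sublethal
#' damage interaction) term of the LQ model: G = 1 for a single acute dose
#' and G -> 1/2 for two acute, fully separated fractions. For
#' lambda * t < 1e-8 the analytic acute-fraction limit
#' (1 + e^(-lambda T))/2 is used, since the printed form is 0/0 at t = 0.
#'
#' @param repair_rate_per_min lambda, > 0
#' @param delivery_min fraction delivery time t (minutes), >= 0
#' @param interval_min inter-fraction interval T (minutes), >= 0 (vectorised)
#' @return G in (0, 1]
#' @export
#' @examples
#' g_factor(log(2) / 44, 5.08, 60)
g_factor <- function(repair_rate_per_min, delivery_min, interval_min) {
  if (repair_rate_per_min <= 0) stop("repair rate must be > 0")
  if (delivery_min < 0) stop("delivery time must be >= 0")
  if (any(interval_min < 0)) stop("interval must be >= 0")
  lt <- repair_rate_per_min * delivery_min
  eT <- exp(-repair_rate_per_min * interval_min)
  if (lt < 1e-8) return((1 + eT) / 2)
  f <- (1 - exp(-lt)) / lt
  (1 / lt) * (1 - f + eT * lt * f^2 / 2)
}

#' Split-dose surviving fraction
#'
#' S = exp(-alpha D - beta G D^2) for a total dose D split into two equal
#' fractions, with G from [g_factor()]. Recovery during the interval reduces
#' the quadratic term only, so with beta = 0 survival is independent of the
#' interval, and as T grows survival rises towards the product of two
#' independent half-dose exposures.
#'
#' @param params [lq_params()]
#' @param total_dose_Gy total dose D over both fractions (Gy)
#' @param repair_rate_per_min lambda (1/min)
#' @param delivery_min per-fraction delivery time (minutes)
#' @param interval_min inter-fraction interval (minutes, vectorised)
#' @return surviving fraction(s)
#' @export
split_dose_survival <- function(params, total_dose_Gy, repair_rate_per_min,
                                delivery_min, interval_min) {
  if (total_dose_Gy < 0) stop("dose must be non-negative")
  G <- g_factor(repair_rate_per_min, delivery_min, interval_min)
  exp(-params$alpha_per_Gy * total_dose_Gy -
        params$beta_per_Gy2 * G * total_dose_Gy^2)
}

#' Fit the linear-quadratic model to single-fraction survival data
#'
#' Least squares of ln(SF) on dose with model -alpha D - beta D^2, both
#' coefficients constrained non-negative (bounded Gauss-Newton via
#' `nls(algorithm = "port")`). When replicate structure is present the fit is
#' weighted by the inverse delta-method variance of ln(SF) per dose
#' (replicate SD of SF mapped through the log). Zero-dose rows (SF already
#' normalised to plating efficiency) are retained and constrain the intercept
#' at 0 implicitly since ln(1) = 0.
#'
#' @param records survival tibble (single-fraction rows; see
#'   [read_survival_table()]) for one cell line and one modality
#' @return an `lq_params` object with covariance, plus attributes
#'   `residual_ss` and `dof`
#' @export
fit_lq <- function(records) {
  df <- records[records$dose_2_Gy == 0, ]
  if (length(unique(df$dose_1_Gy)) < 3)
    stop("need at least 3 distinct doses to fit the LQ model")
  dat <- data.frame(D = df$dose_1_Gy, y = log(df$surviving_fraction))
  w <- .log_sf_weights(dat$D, df$surviving_fraction)
  fit <- nls(y ~ -a * D - b * D^2, data = dat,
             start = list(a = 0.2, b = 0.05),
             lower = c(0, 0), upper = c(Inf, Inf),
             algorithm = "port", weights = w,
             control = list(maxiter = 200, warnOnly = FALSE))
  cf <- coef(fit)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  out <- lq_params(max(cf[["a"]], 0), max(cf[["b"]], 0), covariance = vc)
  attr(out, "residual_ss") <- sum(w * residuals(fit)^2)
  attr(out, "dof") <- nrow(dat) - 2L
  out
}

# inverse-variance weights for ln(SF) from replicate scatter, pooled across
# dose/interval cells: per-cell variances from 3 replicates are far too
# noisy to use directly (they distort extra-sum-of-squares F statistics),
# and clonogenic scatter is close to homoscedastic on the log scale, so one
# pooled variance is estimated and applied to every point. Uniform weights
# when there is no replication or no scatter (noiseless synthetic data).
.log_sf_weights <- function(group, sf) {
  lsf <- log(sf)
  v <- tapply(lsf, group, function(z) if (length(z) > 1) var(z) else NA_real_)
  pooled <- mean(v, na.rm = TRUE)
  if (!is.finite(pooled) || pooled <= 1e-12) return(rep(1, length(sf)))
  rep(1 / pooled, length(sf))
}

#' @importFrom stats var residuals median
NULL
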
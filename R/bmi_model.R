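#' Equilibrium body-weight change from an energy-intake change
#'
#' Uses the equilibrium energy-balance relation: a sustained change in
#' daily energy intake of `k` kJ/day (default 94, SD 2.96 in Monte Carlo)
#' corresponds to a 1 kg change in steady-state body weight for adults.
#'
#' @param delta_e change in daily energy intake, kJ/day (negative = less).
#' @param k kJ/day per kg of equilibrium weight change; must be > 0.
#' @return weight change in kg (vectorised over `delta_e`).
#' @export
equilibrium_weight_change <- function(delta_e, k = 94) {
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  delta_e / k
}

#' Convert a weight change to a BMI change
#'
#' @param delta_w weight change, kg.
#' @param height standing height, m; must be > 0.
#' @return BMI change, kg/m^2.
#' @export
weight_to_bmi_change <- function(delta_w, height) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    stop("height must be > 0", call. = FALSE)
  }
  delta_w / height^2
}

#' Fit a log-normal distribution by the method of moments
#'
#' Inverts the log-normal moment equations:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2 / 2`.
#' Exact algebraic round-trip with [lognormal_moments()].
#'
#' @param mean,sd arithmetic mean and standard deviation (both > 0);
#'   vectorised.
#' @return list with numeric `mu` and `sigma`.
#' @export
fit_lognormal <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0) ||
      any(!is.finite(sd)) || any(sd <= 0)) {
    stop("mean and sd must be positive and finite", call. = FALSE)
  }
  sigma2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Arithmetic moments of a log-normal distribution
#'
#' @param mu,sigma log-scale parameters (`sigma > 0`); vectorised.
#' @return list with numeric `mean` and `sd`.
#' @export
lognormal_moments <- function(mu, sigma) {
  m <- exp(mu + sigma^2 / 2)
  list(mean = m, sd = m * sqrt(exp(sigma^2) - 1))
}

#' Construct a per-stratum BMI distribution
#'
#' Log-normal exposure distribution parameterised by its arithmetic mean
#' and SD (kg/m^2), with the log-scale parameters derived by
#' [fit_lognormal()].
#'
#' @param mean,sd arithmetic mean and SD, kg/m^2.
#' @param stratum optional stratum label.
#' @return an object of class `bmi_distribution`.
#' @export
bmi_distribution <- function(mean, sd, stratum = NULL) {
  ln <- fit_lognormal(mean, sd)
  structure(list(mean = mean, sd = sd, mu = ln$mu, sigma = ln$sigma,
                 stratum = stratum),
            class = "bmi_distribution")
}

#' @export
print.bmi_distribution <- function(x, ...) {
  cat(sprintf("<bmi_distribution%s> mean %.3f sd %.3f (mu %.5f sigma %.5f)\n",
              if (is.null(x$stratum)) "" else paste0(" ", x$stratum),
              x$mean, x$sd, x$mu, x$sigma))
  invisible(x)
}

#' SD-vs-mean BMI shift relation
#'
#' When the mean BMI of a stratum moves, its SD is assumed to move with it:
#' `new_sd = sd + slope * (new_mean - mean)`. The slope is estimated from
#' two waves of observed stratum moments (see [estimate_sd_slope()]) or set
#' directly; `slope = 0` shifts the distribution rigidly.
#'
#' @param slope change in SD per unit change in mean (dimensionless).
#' @param reference_mean,intercept recorded for provenance; the shift rule
#'   uses only the slope.
#' @return an object of class `sd_relation`.
#' @export
sd_relation <- function(slope = 0, reference_mean = NULL, intercept = 0) {
  if (!is.finite(slope)) stop("slope must be finite", call. = FALSE)
  structure(list(slope = slope, reference_mean = reference_mean,
                 intercept = intercept), class = "sd_relation")
}

#' Estimate the SD-vs-mean slope from two waves of BMI moments
#'
#' Regresses the between-wave change in stratum SD on the change in stratum
#' mean (through the origin): the pooled slope used to co-move the SD when
#' the intervention or a secular trend shifts the mean.
#'
#' @param waves data.frame with columns `mean_wave1`, `sd_wave1`,
#'   `mean_wave2`, `sd_wave2` (one row per stratum).
#' @return the estimated slope (numeric scalar).
#' @export
estimate_sd_slope <- function(waves) {
  d_mean <- waves$mean_wave2 - waves$mean_wave1
  d_sd <- waves$sd_wave2 - waves$sd_wave1
  unname(stats::coef(stats::lm(d_sd ~ 0 + d_mean))[1L])
}

#' Shift a BMI distribution
#'
#' Moves the arithmetic mean by the intervention effect plus any secular
#' trend accrued by `year`, co-moves the SD via the [sd_relation()], and
#' refits the log-normal parameters from the new moments. Shifts are
#' additive on the natural (kg/m^2) scale.
#'
#' @param dist a [bmi_distribution()].
#' @param delta_bmi intervention-attributable mean change, kg/m^2.
#' @param rel an [sd_relation()].
#' @param trend secular trend, kg/m^2 per year.
#' @param year model year at which the trend is evaluated.
#' @return a new `bmi_distribution`.
#' @export
shift_distribution <- function(dist, delta_bmi, rel = sd_relation(),
                               trend = 0, year = 0) {
  stopifnot(inherits(dist, "bmi_distribution"), inherits(rel, "sd_relation"))
  new_mean <- dist$mean + delta_bmi + trend * year
  new_sd <- dist$sd + rel$slope * (new_mean - dist$mean)
  if (new_mean <= 0 || new_sd <= 0) {
    stop("degenerate shift: resulting mean/sd must be > 0", call. = FALSE)
  }
  bmi_distribution(new_mean, new_sd, stratum = dist$stratum)
}
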
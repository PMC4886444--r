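#' Monte Carlo configuration
#'
#' Controls the probabilistic uncertainty analysis. Per draw, the sampled
#' parameters are: the own- and cross-price elasticities (normal,
#' mean/SD from the elasticity table), the mean beverage consumption of
#' every stratum and beverage (normal, mean/SE, truncated at 0), the
#' energy-to-weight conversion factor (normal, default 94 kJ/day per kg,
#' SD 2.96, truncated at 0) and the stroke relative risks (log-normal on
#' the log-RR scale). Epidemiological rates are not varied.
#'
#' @param n_draws number of Monte Carlo draws (default 2000).
#' @param seed integer seed; draws are reproducible given `(seed, index)`.
#' @param max_resample maximum rejection-resampling rounds when truncating
#'   a parameter at its physical bound.
#' @return an object of class `mc_config`.
#' @export
mc_config <- function(n_draws = 2000L, seed = 1L, max_resample = 1000L) {
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 max_resample = as.integer(max_resample)),
            class = "mc_config")
}

# normal draw truncated below at `lo` by rejection resampling
rnorm_trunc <- function(n, mean, sd, lo = 0, max_rounds = 1000L) {
  x <- stats::rnorm(n, mean, sd)
  rounds <- 0L
  while (any(bad <- x < lo)) {
    rounds <- rounds + 1L
    if (rounds > max_rounds) {
      stop("truncation bound rejected > ", max_rounds,
           " resampling rounds; SD too large relative to the bound",
           call. = FALSE)
    }
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  x
}

#' Draw one Monte Carlo parameter set
#'
#' Deterministic given `(mc$seed, draw_index)`; draws with different
#' indices are independent streams. Operates on the compiled parameter
#' structure used internally by the pipeline; exposed for testing and for
#' custom uncertainty loops.
#'
#' @param P compiled parameters (internal structure; obtained via
#'   [run_monte_carlo()]'s bundle argument in normal use).
#' @param mc an [mc_config()].
#' @param draw_index 1-based draw index.
#' @return list with `eps` (elasticities), `Q` (consumption matrix), `k`
#'   (kJ/day per kg) and `rr` (relative risks).
#' @keywords internal
#' @export
draw_parameters <- function(P, mc, draw_index) {
  seed_i <- (mc$seed %% 1009L) * 1000003L + draw_index
  with_seed(seed_i, {
    eps <- stats::rnorm(length(P$eps), P$eps, P$eps_sd)
    names(eps) <- names(P$eps)
    q <- rnorm_trunc(length(P$Q), as.vector(P$Q), as.vector(P$Q_se),
                     lo = 0, max_rounds = mc$max_resample)
    Q <- matrix(q, nrow(P$Q), ncol(P$Q), dimnames = dimnames(P$Q))
    k <- rnorm_trunc(1L, P$k, P$k_sd, lo = .Machine$double.eps,
                     max_rounds = mc$max_resample)
    rr <- exp(stats::rnorm(length(P$rr), log(P$rr), P$rr_log_se))
    list(eps = eps, Q = Q, k = k, rr = rr)
  })
}

#' Monte Carlo uncertainty intervals for the horizon totals
#'
#' Re-runs the full pipeline for each parameter draw and summarises every
#' horizon total by its point estimate (all parameters at their means),
#' the mean of the draws and the empirical 2.5th/97.5th percentiles (the
#' 95% uncertainty interval). Draws that produce an invalid model state
#' are excluded with a warning and counted.
#'
#' @param bundle an `ssb_bundle`.
#' @param scenario a [tax_scenario()].
#' @param mc an [mc_config()].
#' @return list with `table` (data.frame: `outcome`, `point`, `mean`,
#'   `lo`, `hi`), `draws` (matrix of per-draw outcomes), `n_failed`, and
#'   the `mc` configuration.
#' @export
run_monte_carlo <- function(bundle, scenario = tax_scenario(),
                            mc = mc_config()) {
  P <- compile_params(bundle)
  point <- run_core(P, scenario)$totals
  track <- c("incident_cases_averted", "prevalent_cases_reduction_final_year",
             "stroke_deaths_averted", "total_deaths_averted",
             "dalys_averted", "costs_saved_zar")
  draws <- matrix(NA_real_, mc$n_draws, length(track),
                  dimnames = list(NULL, track))
  n_failed <- 0L
  for (d in seq_len(mc$n_draws)) {
    par <- draw_parameters(P, mc, d)
    P2 <- P
    P2$eps <- par$eps
    P2$Q <- par$Q
    P2$k <- par$k
    P2$rr <- par$rr
    tot <- tryCatch(run_core(P2, scenario)$totals,
                    error = function(e) NULL)
    if (is.null(tot)) {
      n_failed <- n_failed + 1L
    } else {
      draws[d, ] <- unlist(tot[track])
    }
  }
  if (n_failed > 0L) {
    warning(n_failed, " of ", mc$n_draws,
            " draws produced an invalid state and were excluded")
  }
  ok <- stats::complete.cases(draws)
  tab <- data.frame(
    outcome = track,
    point = unlist(point[track]),
    mean = colMeans(draws[ok, , drop = FALSE]),
    lo = apply(draws[ok, , drop = FALSE], 2L, stats::quantile, 0.025),
    hi = apply(draws[ok, , drop = FALSE], 2L, stats::quantile, 0.975),
    row.names = NULL)
  list(table = tab, draws = draws, n_failed = n_failed, mc = mc)
}

#' Deterministic sensitivity grid
#'
#' One-way sensitivity analysis around a base scenario: tax rate (10, 20,
#' 30%), discount rate (0-3%), SSB portion size (200, 250, 330, 500 ml,
#' implemented as volume rescaling relative to 330 ml), health-care cost
#' scaling (80-120%), background pYLD scaling (100-110%), secular BMI
#' trend (0-0.3 kg/m^2 per year, both arms), pass-on rate (80-100%) and
#' the conservative own-price elasticity (-0.85). One row per scenario;
#' the 20% tax, 0% discount, 330 ml, 100% rows all coincide with the base
#' case.
#'
#' @param bundle an `ssb_bundle`.
#' @param base a [tax_scenario()]; each row varies one lever from it.
#' @return data.frame with columns `parameter`, `level`,
#'   `incidence_change`, `dalys_averted`, `prevalence_change_final_year`,
#'   `costs_change_zar` (signs as conventionally reported: averted counts
#'   and costs are negative changes, DALYs averted positive).
#' @export
sensitivity_grid <- function(bundle, base = tax_scenario()) {
  P <- compile_params(bundle)
  modify <- function(field, value, level) {
    sc <- base
    sc[[field]] <- value
    sc$label <- level
    sc
  }
  rows <- list()
  add <- function(parameter, level, sc) {
    rows[[length(rows) + 1L]] <<- list(parameter = parameter, level = level,
                                       sc = sc)
  }
  for (v in c(0.10, 0.20, 0.30)) {
    add("tax_rate", sprintf("%.0f%%", 100 * v), modify("tax_rate", v, v))
  }
  for (v in c(0, 0.01, 0.02, 0.03)) {
    add("discount_rate", sprintf("%.0f%%", 100 * v),
        modify("discount_rate", v, v))
  }
  for (ml in c(200, 250, 330, 500)) {
    add("portion_size", sprintf("%d ml", ml),
        modify("portion_scale", ml / 330, ml))
  }
  for (v in c(1.2, 1.1, 1.0, 0.9, 0.8)) {
    add("cost_scale", sprintf("%.0f%%", 100 * v), modify("cost_scale", v, v))
  }
  for (v in c(1.0, 1.05, 1.10)) {
    add("pyld_scale", sprintf("%.0f%%", 100 * v), modify("pyld_scale", v, v))
  }
  for (v in c(0, 0.1, 0.2, 0.3)) {
    add("bmi_trend", sprintf("%.1f", v), modify("bmi_trend", v, v))
  }
  for (v in c(0.8, 0.9, 1.0)) {
    add("pass_on_rate", sprintf("%.0f%%", 100 * v),
        modify("pass_on_rate", v, v))
  }
  add("own_elasticity", "-0.85",
      modify("own_elasticity_override", -0.85, -0.85))
  out <- lapply(rows, function(r) {
    tot <- run_core(P, r$sc)$totals
    data.frame(parameter = r$parameter, level = r$level,
               incidence_change = -tot$incident_cases_averted,
               dalys_averted = tot$dalys_averted,
               prevalence_change_final_year =
                 -tot$prevalent_cases_reduction_final_year,
               costs_change_zar = -tot$costs_saved_zar)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
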
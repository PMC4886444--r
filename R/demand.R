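#' Define a tax scenario
#'
#' Bundles every lever of a model run: the tax itself (rate, pass-on),
#' the reporting horizon and discount rate, and the deterministic
#' sensitivity levers (portion-size rescaling of baseline volumes, secular
#' BMI trend applied to both arms, cost and disability scaling, an optional
#' own-price-elasticity override, and the demand functional form).
#'
#' @param tax_rate ad-valorem tax as a fraction of price (default 0.20).
#' @param pass_on_rate fraction of the tax passed on to retail prices
#'   (default 1).
#' @param horizon_years reporting horizon in years (default 20). Cohorts
#'   are always simulated until age 100; totals are summed over the horizon.
#' @param discount_rate annual discount rate applied to health-adjusted
#'   life years and costs only (default 0).
#' @param portion_scale multiplicative rescaling of baseline beverage
#'   volumes; `portion_ml / 330` reproduces the portion-size sensitivity.
#' @param bmi_trend secular trend in mean BMI, kg/m^2 per year, applied to
#'   both the reference and intervention arms.
#' @param cost_scale multiplier on health-care costs.
#' @param pyld_scale multiplier on the background pYLD rate.
#' @param own_elasticity_override if non-`NULL`, replaces the SSB own-price
#'   elasticity (e.g. -0.85 for the conservative bound).
#' @param demand_form `"linear"` (constant elasticity at the margin,
#'   `dQ = Q e dp/p`, the default) or `"isoelastic"`
#'   (`dQ = Q ((1 + dp/p)^e - 1)`).
#' @param label optional scenario label used in grid outputs.
#' @return an object of class `tax_scenario`.
#' @export
tax_scenario <- function(tax_rate = 0.20, pass_on_rate = 1.0,
                         horizon_years = 20L, discount_rate = 0.0,
                         portion_scale = 1.0, bmi_trend = 0.0,
                         cost_scale = 1.0, pyld_scale = 1.0,
                         own_elasticity_override = NULL,
                         demand_form = c("linear", "isoelastic"),
                         label = NULL) {
  demand_form <- match.arg(demand_form)
  if (!is.finite(tax_rate) || tax_rate < 0) {
    stop("tax_rate must be >= 0", call. = FALSE)
  }
  if (!is.finite(pass_on_rate) || pass_on_rate < 0 || pass_on_rate > 1) {
    stop("pass_on_rate must lie in [0, 1]", call. = FALSE)
  }
  if (horizon_years < 1) stop("horizon_years must be >= 1", call. = FALSE)
  if (discount_rate < 0) stop("discount_rate must be >= 0", call. = FALSE)
  if (portion_scale < 0 || cost_scale < 0 || pyld_scale < 0) {
    stop("scale factors must be >= 0", call. = FALSE)
  }
  sc <- list(tax_rate = tax_rate, pass_on_rate = pass_on_rate,
             horizon_years = as.integer(horizon_years),
             discount_rate = discount_rate, portion_scale = portion_scale,
             bmi_trend = bmi_trend, cost_scale = cost_scale,
             pyld_scale = pyld_scale,
             own_elasticity_override = own_elasticity_override,
             demand_form = demand_form,
             label = label %||% sprintf("tax %g%%", 100 * tax_rate))
  class(sc) <- "tax_scenario"
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportional retail price change implied by a scenario
#'
#' `dp/p = tax_rate * pass_on_rate`: a 20% tax fully passed on raises the
#' retail price by 20%; at 80% pass-on, by 16%.
#'
#' @param scenario a [tax_scenario()].
#' @return the proportional price increase (a fraction).
#' @export
effective_price_change <- function(scenario) {
  stopifnot(inherits(scenario, "tax_scenario"))
  scenario$tax_rate * scenario$pass_on_rate
}

#' Consumption change per stratum and beverage
#'
#' Applies the own-price elasticity to SSBs and the cross-price elasticities
#' to the substitutes, identically in every age-sex stratum. The linear form
#' is `dQ = portion_scale * Q * e * dp/p`; the iso-elastic alternative is
#' `portion_scale * Q * ((1 + dp/p)^e - 1)`.
#'
#' @param consumption data.frame `age_group`, `sex`, `beverage`,
#'   `intake_ml` (ml/day), `intake_se`.
#' @param elasticities data.frame `beverage`, `elasticity` (and optionally
#'   `sd`, ignored here).
#' @param dpp proportional price change (from [effective_price_change()]).
#' @param portion_scale volume rescaling factor.
#' @param form `"linear"` or `"isoelastic"`.
#' @return the consumption table with a `delta_ml` column (ml/day).
#' @export
consumption_change <- function(consumption, elasticities, dpp,
                               portion_scale = 1,
                               form = c("linear", "isoelastic")) {
  form <- match.arg(form)
  if (dpp < 0) stop("dpp must be >= 0", call. = FALSE)
  missing_bev <- setdiff(unique(consumption$beverage),
                         elasticities$beverage)
  if (length(missing_bev)) {
    stop("no elasticity for beverage(s): ",
         paste(missing_bev, collapse = ", "), call. = FALSE)
  }
  eps <- elasticities$elasticity[match(consumption$beverage,
                                       elasticities$beverage)]
  out <- consumption
  out$delta_ml <- if (form == "linear") {
    portion_scale * consumption$intake_ml * eps * dpp
  } else {
    portion_scale * consumption$intake_ml * ((1 + dpp)^eps - 1)
  }
  out
}

#' Net daily energy-intake change per stratum
#'
#' Multiplies each beverage's consumption change (ml/day) by its energy
#' density (kJ/litre) and sums across beverages: the energy removed from
#' SSBs net of the energy added back by substitution.
#'
#' @param dq output of [consumption_change()] (needs `delta_ml`).
#' @param densities data.frame `beverage`, `density_kj_per_l`.
#' @return data.frame `age_group`, `sex`, `delta_kj` (kJ/day).
#' @export
net_energy_change <- function(dq, densities) {
  dens <- densities$density_kj_per_l[match(dq$beverage, densities$beverage)]
  if (anyNA(dens)) {
    stop("no energy density for beverage(s): ",
         paste(unique(dq$beverage[is.na(dens)]), collapse = ", "),
         call. = FALSE)
  }
  kj <- dq$delta_ml * dens / 1000
  agg <- stats::aggregate(kj, by = list(age_group = dq$age_group,
                                        sex = dq$sex), FUN = sum)
  names(agg)[3L] <- "delta_kj"
  agg
}
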
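#' Sector-weighted health-care cost per prevalent case-year
#'
#' Weighted average of private and public unit costs, where the public unit
#' cost is a fixed ratio of the private one:
#' `share_priv * c_priv + (1 - share_priv) * ratio * c_priv`.
#'
#' @param cost_private private-sector cost per prevalent case-year (ZAR).
#' @param private_share share of the population using private facilities.
#' @param public_private_ratio public cost as a fraction of private cost.
#' @return weighted cost per prevalent case-year (ZAR).
#' @export
weighted_cost <- function(cost_private, private_share = 0.18,
                          public_private_ratio = 0.70) {
  if (private_share < 0 || private_share > 1) {
    stop("private_share must lie in [0, 1]", call. = FALSE)
  }
  if (public_private_ratio <= 0) {
    stop("public_private_ratio must be > 0", call. = FALSE)
  }
  private_share * cost_private +
    (1 - private_share) * public_private_ratio * cost_private
}

#' One annual cycle of the stroke multi-state difference equations
#'
#' Within a year, in order: (1) incidence moves healthy people into the
#' stroke state at effective rate `i * (1 - pif)`, converted to a
#' probability as `1 - exp(-rate)`; (2) a fraction `d28` of the incident
#' cases dies acutely (within 28 days) and never enters the prevalent pool;
#' (3) prevalent cases die of stroke at the case-fatality rate; (4) all
#' survivors, healthy or prevalent (including new entrants), are exposed to
#' other-cause mortality. Deaths are therefore apportioned across states in
#' proportion to occupancy, and persons are conserved exactly:
#' `S + C = S' + C' + total deaths`.
#'
#' All arguments are vectorised (element-wise over cohorts).
#'
#' @param S,C healthy and prevalent-stroke person counts at start of year.
#' @param i stroke incidence rate, /yr.
#' @param f case-fatality rate of prevalent cases, /yr.
#' @param d28 proportion of incident strokes fatal within 28 days.
#' @param m_other other-cause mortality rate, /yr.
#' @param pif potential impact fraction applied to incidence (0 = reference).
#' @return list with `S`, `C` (end of year), `new_cases`, `acute_deaths`,
#'   `case_deaths`, `other_deaths`, `stroke_deaths`, `total_deaths`.
#' @export
disease_step <- function(S, C, i, f, d28, m_other, pif = 0) {
  i_eff <- i * (1 - pif)
  if (any(i_eff < 0)) stop("effective incidence must be >= 0", call. = FALSE)
  new_cases <- S * (1 - exp(-i_eff))
  acute_deaths <- new_cases * d28
  entering <- new_cases - acute_deaths
  S1 <- S - new_cases
  case_deaths <- C * (1 - exp(-f))
  C1 <- C - case_deaths + entering
  p_other <- 1 - exp(-m_other)
  other_S <- S1 * p_other
  other_C <- C1 * p_other
  S2 <- S1 - other_S
  C2 <- C1 - other_C
  if (any(S2 < 0) || any(C2 < 0)) {
    stop("state count went negative; annual rates too large", call. = FALSE)
  }
  list(S = S2, C = C2, new_cases = new_cases, acute_deaths = acute_deaths,
       case_deaths = case_deaths, other_deaths = other_S + other_C,
       stroke_deaths = acute_deaths + case_deaths,
       total_deaths = acute_deaths + case_deaths + other_S + other_C)
}

#' Simulate a single cohort through the life table
#'
#' Follows one 5-year cohort from its entry age by single year of age,
#' applying [disease_step()] with the age-appropriate band rates, until age
#' 100 (or `n_years`). Mid-year conventions: life years, reported
#' prevalence and costs use the average of start- and end-of-year counts.
#' Health-adjusted life years deduct background disability
#' (`pyld_bg * pyld_scale`) from everyone and the stroke disability weight
#' from prevalent cases.
#'
#' @param population cohort size at entry.
#' @param prevalence initial prevalent-stroke fraction.
#' @param entry_age age at entry (years).
#' @param rate_fn function of age returning a list with elements
#'   `incidence`, `case_fatality`, `d28`, `mortality_all`, `pyld_bg`.
#' @param pif potential impact fraction: a scalar, or a vector indexed by
#'   simulation year (recycled value beyond its length is the last one).
#' @param n_years number of annual cycles (default: until age 100).
#' @param dw stroke disability weight.
#' @param cost_per_case_year weighted health-care cost per prevalent
#'   case-year.
#' @param pyld_scale,cost_scale sensitivity multipliers.
#' @return data.frame with one row per simulated year: `year`, `age`,
#'   start/end state counts, flows, `prevalent_mid`, `life_years`, `halys`,
#'   `costs`.
#' @export
run_cohort <- function(population, prevalence, entry_age, rate_fn,
                       pif = 0, n_years = NULL, dw = 0.28,
                       cost_per_case_year = 0, pyld_scale = 1,
                       cost_scale = 1) {
  if (is.null(n_years)) n_years <- max(100L - as.integer(entry_age), 0L)
  if (n_years < 1L) stop("cohort enters at or beyond age 100", call. = FALSE)
  S <- population * (1 - prevalence)
  C <- population * prevalence
  rows <- vector("list", n_years)
  for (t in seq_len(n_years)) {
    age <- entry_age + t - 1L
    r <- rate_fn(age)
    pif_t <- if (length(pif) == 1L) pif else pif[min(t, length(pif))]
    st <- disease_step(S, C, r$incidence, r$case_fatality, r$d28,
                       r$mortality_all, pif_t)
    alive0 <- S + C
    alive1 <- st$S + st$C
    prevalent_mid <- (C + st$C) / 2
    ly <- (alive0 + alive1) / 2
    haly <- ly * (1 - r$pyld_bg * pyld_scale) - prevalent_mid * dw
    rows[[t]] <- data.frame(
      year = t, age = age, S_start = S, C_start = C,
      new_cases = st$new_cases, acute_deaths = st$acute_deaths,
      case_deaths = st$case_deaths, other_deaths = st$other_deaths,
      stroke_deaths = st$stroke_deaths, total_deaths = st$total_deaths,
      S_end = st$S, C_end = st$C, prevalent_mid = prevalent_mid,
      life_years = ly, halys = haly,
      costs = prevalent_mid * cost_per_case_year * cost_scale)
    S <- st$S
    C <- st$C
  }
  do.call(rbind, rows)
}

#' Discount an annual series
#'
#' Divides `values[t]` by `(1 + rate)^(t - 1)`: the first model year is
#' undiscounted.
#'
#' @param values numeric vector, one element per model year.
#' @param rate annual discount rate (>= 0).
#' @return the discounted series.
#' @export
discount_series <- function(values, rate) {
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  values / (1 + rate)^(seq_along(values) - 1L)
}
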
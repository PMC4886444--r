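BEVERAGES <- c("ssb", "juice", "milk", "diet")

age_lo_of <- function(age_group) as.integer(sub("-.*", "", age_group))

# Compile a bundle into aligned numeric vectors/matrices (canonical stratum
# order: sex blocks, age bands ascending within sex), plus the cohort
# age-band lookup used by the life-table engine. All per-draw work in the
# Monte Carlo loop operates on this structure, not on the data.frames.
compile_params <- function(bundle) {
  stopifnot(inherits(bundle, "ssb_bundle"))
  epi <- bundle$epi
  sexes <- c("male", "female")
  epi$.lo <- age_lo_of(epi$age_group)
  ord <- order(match(epi$sex, sexes), epi$.lo)
  epi <- epi[ord, ]
  n <- nrow(epi)
  key <- paste(epi$age_group, epi$sex)
  align <- function(df) {
    idx <- match(key, paste(df$age_group, df$sex))
    if (anyNA(idx)) {
      stop("table missing stratum row(s): ",
           paste(key[is.na(idx)], collapse = "; "), call. = FALSE)
    }
    df[idx, , drop = FALSE]
  }
  bmi <- align(bundle$bmi)
  heights <- align(bundle$heights)
  rr <- align(bundle$rr)
  qmat <- sapply(BEVERAGES, function(b) {
    sub <- bundle$consumption[bundle$consumption$beverage == b, ]
    idx <- match(key, paste(sub$age_group, sub$sex))
    if (anyNA(idx)) stop("consumption table missing ", b, " row(s)",
                         call. = FALSE)
    sub$intake_ml[idx]
  })
  semat <- sapply(BEVERAGES, function(b) {
    sub <- bundle$consumption[bundle$consumption$beverage == b, ]
    sub$intake_se[match(key, paste(sub$age_group, sub$sex))]
  })
  eps <- bundle$elasticities$elasticity[
    match(BEVERAGES, bundle$elasticities$beverage)]
  eps_sd <- bundle$elasticities$sd[
    match(BEVERAGES, bundle$elasticities$beverage)]
  dens <- bundle$energy_densities$density_kj_per_l[
    match(BEVERAGES, bundle$energy_densities$beverage)]
  names(eps) <- names(eps_sd) <- names(dens) <- BEVERAGES
  pm <- bundle$params
  dw <- pm$disability_weight
  pyld_bg <- pmax(epi$pyld_rate - epi$stroke_prevalence * dw, 0)
  wc <- weighted_cost(bundle$costs$cost_private_per_case_year[1L],
                      bundle$costs$private_share[1L],
                      bundle$costs$public_private_ratio[1L])

  # cohort structure: one cohort per stratum, entering at the band midpoint
  band_lo <- sort(unique(epi$.lo))
  nb <- length(band_lo)
  entry_age <- epi$.lo + 2L
  n_years <- pmax(100L - entry_age, 0L)
  max_T <- max(n_years)
  sex_idx <- match(epi$sex, sexes)
  # rid[t, j]: stratum row whose band rates apply to cohort j in year t
  ages <- outer(rep(1L, max_T), entry_age) + (seq_len(max_T) - 1L)
  band <- pmin(pmax((ages - band_lo[1L]) %/% 5L + 1L, 1L), nb)
  rid <- band + (rep(sex_idx, each = max_T) - 1L) * nb

  list(n = n, key = key, age_group = epi$age_group, sex = epi$sex,
       sex_idx = sex_idx, nb = nb,
       pop = epi$population, m_all = epi$mortality_all,
       inc = epi$stroke_incidence, prev = epi$stroke_prevalence,
       cf = epi$case_fatality, d28 = epi$d28_fatality,
       pyld_bg = pyld_bg,
       bmi_mean = bmi$mean, bmi_sd = bmi$sd, heights = heights$height_m,
       rr = rr$rr_per_unit, rr_log_se = rr$log_se,
       Q = qmat, Q_se = semat, eps = eps, eps_sd = eps_sd, dens = dens,
       k = pm$kj_per_kg, k_sd = pm$kj_per_kg_sd, tmreb = pm$tmreb,
       dw = dw, sd_slope = pm$sd_slope, wc = wc,
       entry_age = entry_age, n_years = n_years, max_T = max_T, rid = rid)
}

# Per-stratum intervention-attributable BMI change (kg/m^2), via the demand
# and energy-balance chain.
delta_bmi_of <- function(P, scenario) {
  dpp <- scenario$tax_rate * scenario$pass_on_rate
  eps <- P$eps
  if (!is.null(scenario$own_elasticity_override)) {
    eps["ssb"] <- scenario$own_elasticity_override
  }
  resp <- if (scenario$demand_form == "linear") eps * dpp
          else (1 + dpp)^eps - 1
  dq <- scenario$portion_scale * sweep(P$Q, 2L, resp, `*`)
  de <- as.vector(dq %*% (P$dens / 1000))
  list(delta_kj = de, delta_bmi = (de / P$k) / P$heights^2)
}

# PIF matrix [stratum x year-column]; a single column when there is no BMI
# trend (the PIF is then time-constant).
pif_matrix <- function(P, scenario, delta_bmi,
                       method = c("batch", "adaptive")) {
  method <- match.arg(method)
  H <- scenario$horizon_years
  trend <- scenario$bmi_trend
  ncols <- if (trend == 0) 1L else H
  out <- matrix(0, P$n, ncols)
  for (tc in seq_len(ncols)) {
    drift <- trend * (if (trend == 0) 0 else tc)
    ref_mean <- P$bmi_mean + drift
    ref_sd <- P$bmi_sd + P$sd_slope * drift
    int_mean <- ref_mean + delta_bmi
    int_sd <- P$bmi_sd + P$sd_slope * (drift + delta_bmi)
    if (any(ref_mean <= 0) || any(ref_sd <= 0) ||
        any(int_mean <= 0) || any(int_sd <= 0)) {
      stop("degenerate BMI distribution after shift", call. = FALSE)
    }
    lr <- fit_lognormal(ref_mean, ref_sd)
    li <- fit_lognormal(int_mean, int_sd)
    if (method == "batch") {
      e_ref <- mean_rr_batch(lr$mu, lr$sigma, P$rr, P$tmreb)
      e_int <- mean_rr_batch(li$mu, li$sigma, P$rr, P$tmreb)
    } else {
      e_ref <- vapply(seq_len(P$n), function(j) {
        mean_rr(structure(list(mean = ref_mean[j], sd = ref_sd[j],
                               mu = lr$mu[j], sigma = lr$sigma[j]),
                          class = "bmi_distribution"),
                P$rr[j], P$tmreb)
      }, numeric(1L))
      e_int <- vapply(seq_len(P$n), function(j) {
        mean_rr(structure(list(mean = int_mean[j], sd = int_sd[j],
                               mu = li$mu[j], sigma = li$sigma[j]),
                          class = "bmi_distribution"),
                P$rr[j], P$tmreb)
      }, numeric(1L))
    }
    out[, tc] <- (e_ref - e_int) / e_ref
  }
  out
}

OUTCOMES <- c("new_cases", "prevalent_mid", "stroke_deaths", "total_deaths",
              "life_years", "halys", "costs")

# Both arms of the proportional multi-state life table, all cohorts at
# once. Returns, per arm, a [year x sex] matrix per outcome.
simulate_arms <- function(P, pif_mat, scenario) {
  TT <- P$max_T
  n <- P$n
  ind <- cbind(male = as.numeric(P$sex_idx == 1L),
               female = as.numeric(P$sex_idx == 2L))
  res <- lapply(1:2, function(a) {
    lapply(stats::setNames(OUTCOMES, OUTCOMES),
           function(o) matrix(0, TT, n))
  })
  names(res) <- c("reference", "intervention")
  S0 <- P$pop * (1 - P$prev)
  C0 <- P$pop * P$prev
  dw <- P$dw
  wc_eff <- P$wc * scenario$cost_scale
  for (a in 1:2) {
    S <- S0
    C <- C0
    M <- res[[a]]
    for (t in seq_len(TT)) {
      act <- P$n_years >= t
      rid <- P$rid[t, act]
      pif <- if (a == 1L) 0 else pif_mat[rid, min(t, ncol(pif_mat))]
      st <- disease_step(S[act], C[act], P$inc[rid], P$cf[rid],
                         P$d28[rid], P$m_all[rid], pif)
      alive0 <- S[act] + C[act]
      alive1 <- st$S + st$C
      prev_mid <- (C[act] + st$C) / 2
      ly <- (alive0 + alive1) / 2
      M$new_cases[t, act] <- st$new_cases
      M$prevalent_mid[t, act] <- prev_mid
      M$stroke_deaths[t, act] <- st$stroke_deaths
      M$total_deaths[t, act] <- st$total_deaths
      M$life_years[t, act] <- ly
      M$halys[t, act] <- ly * (1 - P$pyld_bg[rid] * scenario$pyld_scale) -
        prev_mid * dw
      M$costs[t, act] <- prev_mid * wc_eff
      S[act] <- st$S
      C[act] <- st$C
    }
    res[[a]] <- lapply(M, function(m) m %*% ind)
  }
  res
}

# Horizon totals and per-year differences from the simulated arms.
collect_results <- function(sim, scenario) {
  H <- scenario$horizon_years
  r <- scenario$discount_rate
  diff <- Map(function(a, b) a - b, sim$reference, sim$intervention)
  tot <- function(m) sum(m[seq_len(min(H, nrow(m))), ])
  at_h <- function(m) sum(m[min(H, nrow(m)), ])
  disc_tot <- function(m) {
    v <- rowSums(m)[seq_len(min(H, nrow(m)))]
    sum(discount_series(v, r))
  }
  totals <- list(
    incident_cases_averted = tot(diff$new_cases),
    prevalent_cases_reduction_final_year = at_h(diff$prevalent_mid),
    stroke_deaths_averted = tot(diff$stroke_deaths),
    total_deaths_averted = tot(diff$total_deaths),
    life_years_gained = -disc_tot(diff$life_years),
    dalys_averted = -disc_tot(diff$halys),
    costs_saved_zar = disc_tot(diff$costs),
    reference_incident_cases = tot(sim$reference$new_cases),
    reference_stroke_deaths = tot(sim$reference$stroke_deaths))
  list(totals = totals, diff = diff)
}

# Table-1-shaped percentage reductions by year and sex.
percentage_reductions <- function(sim, scenario) {
  H <- min(scenario$horizon_years, nrow(sim$reference$new_cases))
  out <- list()
  map <- c(incidence = "new_cases", prevalence = "prevalent_mid",
           mortality = "stroke_deaths")
  for (oc in names(map)) {
    ref <- sim$reference[[map[[oc]]]][seq_len(H), , drop = FALSE]
    int <- sim$intervention[[map[[oc]]]][seq_len(H), , drop = FALSE]
    pct <- ifelse(ref > 0, 100 * (ref - int) / ref, NA_real_)
    out[[oc]] <- data.frame(year = rep(seq_len(H), 2L),
                            sex = rep(c("male", "female"), each = H),
                            outcome = oc, pct_reduction = as.vector(pct))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

run_core <- function(P, scenario, pif_method = "batch") {
  db <- delta_bmi_of(P, scenario)
  pm <- pif_matrix(P, scenario, db$delta_bmi, method = pif_method)
  sim <- simulate_arms(P, pm, scenario)
  cr <- collect_results(sim, scenario)
  list(totals = cr$totals, diff = cr$diff, sim = sim, pif = pm,
       delta_kj = db$delta_kj, delta_bmi = db$delta_bmi)
}

#' Run the full tax-to-stroke pipeline
#'
#' Executes demand (price to consumption to energy), the BMI shift, the
#' potential impact fraction and the two-arm proportional multi-state life
#' table for one scenario, and aggregates per-year results and horizon
#' totals.
#'
#' @param bundle an `ssb_bundle` ([generate_bundle()] or [read_bundle()]).
#' @param scenario a [tax_scenario()].
#' @param pif_method `"batch"` (vectorised fixed-order quadrature, default)
#'   or `"adaptive"` (per-stratum adaptive quadrature); the two agree to
#'   better than 1e-8 and the choice does not affect any reported quantity
#'   at reporting precision.
#' @return an object of class `ssb_run`: `totals` (horizon sums of averted
#'   incident cases, deaths, DALYs and costs, plus the final-year prevalent
#'   case reduction), `per_year` (long data.frame of both arms by year, sex
#'   and outcome), `table1` (percentage reductions in incidence, prevalence
#'   and stroke mortality by year and sex), `pif` (per-stratum potential
#'   impact fractions), `delta_energy` (per-stratum kJ/day and BMI
#'   changes), and the `scenario`.
#' @export
run_pipeline <- function(bundle, scenario = tax_scenario(),
                         pif_method = c("batch", "adaptive")) {
  pif_method <- match.arg(pif_method)
  P <- compile_params(bundle)
  core <- run_core(P, scenario, pif_method)
  per_year <- do.call(rbind, lapply(names(core$sim), function(arm) {
    do.call(rbind, lapply(OUTCOMES, function(oc) {
      m <- core$sim[[arm]][[oc]]
      data.frame(arm = arm, outcome = oc,
                 year = rep(seq_len(nrow(m)), 2L),
                 sex = rep(c("male", "female"), each = nrow(m)),
                 value = as.vector(m))
    }))
  }))
  pif_df <- data.frame(age_group = P$age_group, sex = P$sex,
                       pif_year1 = core$pif[, 1L],
                       pif_final = core$pif[, ncol(core$pif)])
  de_df <- data.frame(age_group = P$age_group, sex = P$sex,
                      delta_kj_per_day = core$delta_kj,
                      delta_bmi = core$delta_bmi)
  structure(list(totals = core$totals,
                 per_year = per_year,
                 table1 = percentage_reductions(core$sim, scenario),
                 pif = pif_df, delta_energy = de_df,
                 scenario = scenario),
            class = "ssb_run")
}

#' @export
print.ssb_run <- function(x, ...) {
  t <- x$totals
  cat("<ssb_run>", x$scenario$label, "over", x$scenario$horizon_years,
      "years\n")
  cat(sprintf("  incident cases averted : %12.0f\n", t$incident_cases_averted))
  cat(sprintf("  stroke deaths averted  : %12.0f\n", t$stroke_deaths_averted))
  cat(sprintf("  prevalent cases, final : %12.0f\n",
              t$prevalent_cases_reduction_final_year))
  cat(sprintf("  DALYs averted          : %12.0f\n", t$dalys_averted))
  cat(sprintf("  costs saved (ZAR)      : %12.0f\n", t$costs_saved_zar))
  invisible(x)
}

#' Validate an input bundle
#'
#' Applies the same structural and plausibility checks to any bundle,
#' whether generated synthetically or read from user-supplied CSVs: table
#' and column presence, stratum coverage across tables, rate and fraction
#' ranges, and prevalence consistency with incidence, case fatality and
#' mortality. Structural problems are errors; plausibility issues are
#' reported as warnings in the returned report.
#'
#' @param bundle an `ssb_bundle`.
#' @return an object of class `bundle_validation` with elements `ok`
#'   (logical: no error-severity violations) and `violations` (data.frame
#'   with columns `table`, `stratum`, `field`, `severity`, `message`).
#' @export
validate_bundle <- function(bundle) {
  v <- list()
  note <- function(table, stratum, field, severity, message) {
    v[[length(v) + 1L]] <<- data.frame(table = table, stratum = stratum,
                                       field = field, severity = severity,
                                       message = message)
  }
  need <- list(
    consumption = c("age_group", "sex", "beverage", "intake_ml", "intake_se"),
    bmi = c("age_group", "sex", "mean", "sd"),
    heights = c("age_group", "sex", "height_m"),
    epi = c("age_group", "sex", "population", "mortality_all",
            "stroke_incidence", "stroke_prevalence", "case_fatality",
            "d28_fatality", "pyld_rate"),
    rr = c("age_group", "sex", "rr_per_unit", "log_se"),
    elasticities = c("beverage", "elasticity", "sd"),
    energy_densities = c("beverage", "density_kj_per_l"),
    costs = c("cost_private_per_case_year", "private_share",
              "public_private_ratio"))
  for (tb in names(need)) {
    if (is.null(bundle[[tb]]) || !is.data.frame(bundle[[tb]])) {
      stop("bundle is missing table '", tb, "'", call. = FALSE)
    }
    miss <- setdiff(need[[tb]], names(bundle[[tb]]))
    if (length(miss)) {
      stop("table '", tb, "' is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  epi <- bundle$epi
  key <- paste(epi$age_group, epi$sex)
  chk_range <- function(tb, field, lo = 0, hi = Inf, hi_open = FALSE,
                        strat = NULL) {
    x <- bundle[[tb]][[field]]
    strat <- strat %||% (if (all(c("age_group", "sex") %in%
                                 names(bundle[[tb]])))
      paste(bundle[[tb]]$age_group, bundle[[tb]]$sex) else
        rep("-", length(x)))
    bad <- !is.finite(x) | x < lo | (if (hi_open) x >= hi else x > hi)
    for (j in which(bad)) {
      note(tb, strat[j], field, "error",
           sprintf("%s = %g outside [%g, %g%s", field, x[j], lo, hi,
                   if (hi_open) ")" else "]"))
    }
  }
  # stratum coverage
  for (tb in c("bmi", "heights", "rr")) {
    missing <- setdiff(key, paste(bundle[[tb]]$age_group, bundle[[tb]]$sex))
    for (m in missing) note(tb, m, "-", "error", "stratum missing")
  }
  for (b in BEVERAGES) {
    sub <- bundle$consumption[bundle$consumption$beverage == b, ]
    missing <- setdiff(key, paste(sub$age_group, sub$sex))
    for (m in missing) note("consumption", m, b, "error", "stratum missing")
  }
  chk_range("epi", "population", 0)
  chk_range("epi", "mortality_all", 0)
  chk_range("epi", "stroke_incidence", 0)
  chk_range("epi", "stroke_prevalence", 0, 1, hi_open = TRUE)
  chk_range("epi", "case_fatality", 0)
  chk_range("epi", "d28_fatality", 0, 1)
  chk_range("epi", "pyld_rate", 0)
  chk_range("consumption", "intake_ml", 0)
  chk_range("consumption", "intake_se", 0)
  chk_range("bmi", "mean", 1e-9)
  chk_range("bmi", "sd", 1e-9)
  chk_range("heights", "height_m", 1e-9)
  chk_range("rr", "rr_per_unit", 1e-9)
  chk_range("rr", "log_se", 0)
  chk_range("elasticities", "sd", 0)
  chk_range("energy_densities", "density_kj_per_l", 0)
  chk_range("costs", "private_share", 0, 1)
  # plausibility: annual rates large enough to break the annual cycle
  for (field in c("mortality_all", "case_fatality", "stroke_incidence")) {
    big <- which(epi[[field]] > 2)
    for (j in big) note("epi", key[j], field, "warning",
                        sprintf("%s = %g exceeds 2/yr", field, epi[[field]][j]))
  }
  own <- bundle$elasticities$elasticity[bundle$elasticities$beverage == "ssb"]
  if (length(own) && own > 0) {
    note("elasticities", "-", "ssb", "warning",
         "own-price elasticity is positive (not a normal good)")
  }
  # prevalence consistent with flows: compare to quasi-steady state
  ss <- epi$stroke_incidence * (1 - epi$d28_fatality) /
    pmax(epi$stroke_incidence + epi$case_fatality + epi$mortality_all, 1e-12)
  far <- which(epi$stroke_prevalence > pmax(10 * ss, 1e-6))
  for (j in far) note("epi", key[j], "stroke_prevalence", "warning",
                      "prevalence implausibly high given incidence, case fatality and mortality")
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), stratum = character(),
               field = character(), severity = character(),
               message = character())
  structure(list(ok = !any(violations$severity == "error"),
                 violations = violations),
            class = "bundle_validation")
}

#' @export
print.bundle_validation <- function(x, ...) {
  if (nrow(x$violations) == 0L) {
    cat("<bundle_validation> OK: no violations\n")
  } else {
    cat("<bundle_validation>", sum(x$violations$severity == "error"),
        "error(s),", sum(x$violations$severity == "warning"),
        "warning(s)\n")
    print(utils::head(x$violations, 20L))
  }
  invisible(x)
}

#' Run a scenario end to end and write its artifacts to disk
#'
#' Orchestrates the whole analysis for one configuration: obtain a bundle
#' (synthetic from `seed`, or supplied/read from disk), validate it, run
#' the pipeline, and write per-year results, the percentage-reduction
#' table, per-stratum energy/PIF tables and a JSON summary (horizon totals
#' plus a full scenario echo) under `out_dir`. Optionally also runs the
#' deterministic sensitivity grid and/or the Monte Carlo uncertainty
#' analysis.
#'
#' @param out_dir output directory (created if needed).
#' @param bundle an `ssb_bundle`; alternatively give `bundle_dir` or `seed`.
#' @param bundle_dir directory of bundle CSVs to read.
#' @param seed seed for a synthetic bundle (exactly one of `bundle`,
#'   `bundle_dir`, `seed` must be supplied).
#' @param scenario a [tax_scenario()].
#' @param grid if `TRUE`, also write the sensitivity grid CSV.
#' @param mc optional [mc_config()]; if supplied, also write Monte Carlo
#'   uncertainty intervals as JSON.
#' @return the `ssb_run` object, invisibly.
#' @export
run_scenario <- function(out_dir, bundle = NULL, bundle_dir = NULL,
                         seed = NULL, scenario = tax_scenario(),
                         grid = FALSE, mc = NULL) {
  given <- c(!is.null(bundle), !is.null(bundle_dir), !is.null(seed))
  if (sum(given) != 1L) {
    stop("supply exactly one of bundle, bundle_dir, seed", call. = FALSE)
  }
  if (!is.null(bundle_dir)) bundle <- read_bundle(bundle_dir)
  if (!is.null(seed)) bundle <- generate_bundle(synthetic_config(seed = seed))
  val <- validate_bundle(bundle)
  if (!val$ok) {
    stop("bundle failed validation with ",
         sum(val$violations$severity == "error"), " error(s); ",
         "see validate_bundle() for details", call. = FALSE)
  }
  run <- run_pipeline(bundle, scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$per_year, file.path(out_dir, "per_year.csv"),
                   row.names = FALSE)
  utils::write.csv(run$table1, file.path(out_dir, "percent_reductions.csv"),
                   row.names = FALSE)
  utils::write.csv(run$delta_energy, file.path(out_dir, "delta_energy.csv"),
                   row.names = FALSE)
  utils::write.csv(run$pif, file.path(out_dir, "pif.csv"), row.names = FALSE)
  summary <- list(totals = run$totals,
                  scenario = unclass(scenario),
                  bundle_seed = bundle$manifest$seed,
                  n_strata = nrow(bundle$epi))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(grid)) {
    g <- sensitivity_grid(bundle, scenario)
    utils::write.csv(g, file.path(out_dir, "sensitivity_grid.csv"),
                     row.names = FALSE)
  }
  if (!is.null(mc)) {
    ui <- run_monte_carlo(bundle, scenario, mc)
    jsonlite::write_json(ui$table, file.path(out_dir, "uncertainty.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(run)
}
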
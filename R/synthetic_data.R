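#' Configuration for the synthetic input generator
#'
#' Builds the full set of "knobs" controlling the synthetic input bundle that
#' stands in for the survey (beverage consumption), panel (BMI), burden-of-
#' disease (relative risks, pYLD), vital-registration (all-cause mortality)
#' and claims (cost) inputs of the model. All defaults aim for magnitudes a
#' South African adult population in 2012 would plausibly show; the only
#' quantities anchored to published figures are the population mean SSB
#' intake (184 ml/day), the stroke disability weight (0.28), the 28-day
#' fatality proportion (about one third) and the energy-balance constants.
#' Everything else is a structural stand-in, not an estimate.
#'
#' @param seed integer seed; the same seed always yields an identical bundle.
#' @param n_bmi_samples_per_stratum number of individual-level BMI draws to
#'   attach per stratum (0 = moments only). Samples are drawn from the
#'   log-normal whose true `(mu, sigma)` are recorded in the manifest, so
#'   fit-recovery is testable.
#' @param age_lo integer vector of 5-year band lower bounds; must be
#'   contiguous ascending steps of 5 (default 15 to 95, i.e. bands
#'   15-19 ... 95-99).
#' @param mean_ssb_ml target population-weighted mean SSB intake, ml/day.
#' @param consumption_age_decay exponential decay of SSB intake with age
#'   (per year of age); young adults drink the most.
#' @param bmi_base,bmi_rise named numeric (male, female): BMI mean at age
#'   17 and the asymptotic rise with age, kg/m^2.
#' @param bmi_sd_slope true slope of stratum BMI SD against mean BMI used to
#'   generate the two BMI "waves" from which the shift relation is re-fitted.
#' @param mortality_base,mortality_age_slope all-cause mortality /yr at age
#'   17 and its log-linear age slope.
#' @param incidence_base,incidence_age_slope stroke incidence /yr at age 17
#'   and its log-linear age slope.
#' @param case_fatality_base,case_fatality_age_slope annual case-fatality
#'   rate of prevalent stroke at age 17 and its linear age slope.
#' @param d28 proportion of incident strokes fatal within 28 days.
#' @param rr_base,rr_age_atten relative risk of stroke per 5 kg/m^2 BMI at
#'   young-adult age, and the exponential attenuation of the excess risk
#'   with age.
#' @param rr_log_se standard error of log RR (uncertainty for Monte Carlo).
#' @param disability_weight average stroke disability weight.
#' @param pyld_base,pyld_age_slope background prevalent years lived with
#'   disability per person-year (excluding stroke) at age 17, and linear
#'   age slope.
#' @param cost_private private-sector health-care cost per prevalent stroke
#'   case-year, ZAR.
#' @param private_share,public_private_ratio share of the population using
#'   private facilities, and public:private cost ratio.
#' @param heights named numeric (male, female): mean standing height, m.
#' @param pop_base,pop_decay population of the youngest band per sex, and
#'   its exponential decay per 5-year band.
#' @param elasticities data.frame with columns `beverage`, `elasticity`,
#'   `sd`: own-price elasticity for `ssb`, cross-price elasticities (with
#'   respect to the SSB price) for the others.
#' @param energy_densities data.frame with columns `beverage`,
#'   `density_kj_per_l`, `sd`.
#' @param kj_per_kg,kj_per_kg_sd equilibrium energy-balance constant: kJ/day
#'   of sustained intake change per kg of body-weight change, with SD.
#' @param tmreb theoretical-minimum-risk BMI threshold, kg/m^2.
#'
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_bmi_samples_per_stratum = 0L,
                             age_lo = seq(15L, 95L, by = 5L),
                             mean_ssb_ml = 184,
                             consumption_age_decay = 0.035,
                             bmi_base = c(male = 22.5, female = 24.5),
                             bmi_rise = c(male = 5.0, female = 6.5),
                             bmi_sd_slope = 0.45,
                             mortality_base = 0.002,
                             mortality_age_slope = 0.068,
                             incidence_base = 2.4e-5,
                             incidence_age_slope = 0.088,
                             case_fatality_base = 0.12,
                             case_fatality_age_slope = 0.0028,
                             d28 = 0.33,
                             rr_base = 1.35,
                             rr_age_atten = 0.022,
                             rr_log_se = 0.05,
                             disability_weight = 0.28,
                             pyld_base = 0.015,
                             pyld_age_slope = 0.0016,
                             cost_private = 36000,
                             private_share = 0.18,
                             public_private_ratio = 0.70,
                             heights = c(male = 1.68, female = 1.58),
                             pop_base = 4e6,
                             pop_decay = 0.30,
                             elasticities = default_elasticities(),
                             energy_densities = default_energy_densities(),
                             kj_per_kg = 94,
                             kj_per_kg_sd = 2.96,
                             tmreb = 21) {
  age_lo <- as.integer(age_lo)
  if (length(age_lo) < 2L || any(diff(age_lo) != 5L)) {
    stop("age_lo must be contiguous ascending 5-year band lower bounds",
         call. = FALSE)
  }
  scalars <- c(mean_ssb_ml = mean_ssb_ml,
               consumption_age_decay = consumption_age_decay,
               bmi_sd_slope = bmi_sd_slope,
               mortality_base = mortality_base,
               mortality_age_slope = mortality_age_slope,
               incidence_base = incidence_base,
               incidence_age_slope = incidence_age_slope,
               case_fatality_base = case_fatality_base,
               case_fatality_age_slope = case_fatality_age_slope,
               d28 = d28, rr_base = rr_base, rr_age_atten = rr_age_atten,
               rr_log_se = rr_log_se, disability_weight = disability_weight,
               pyld_base = pyld_base, pyld_age_slope = pyld_age_slope,
               cost_private = cost_private, private_share = private_share,
               public_private_ratio = public_private_ratio,
               pop_base = pop_base, pop_decay = pop_decay,
               kj_per_kg = kj_per_kg, kj_per_kg_sd = kj_per_kg_sd,
               tmreb = tmreb)
  bad <- names(scalars)[!is.finite(scalars) | scalars < 0]
  if (length(bad)) {
    stop("negative or non-finite generator knob(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (d28 > 1) stop("d28 must lie in [0, 1]", call. = FALSE)
  if (disability_weight > 1) stop("disability_weight must lie in [0, 1]",
                                  call. = FALSE)
  if (any(heights <= 0) || any(bmi_base <= 0) || any(bmi_rise < 0)) {
    stop("heights and bmi_base must be positive; bmi_rise non-negative",
         call. = FALSE)
  }
  stopifnot(is.data.frame(elasticities),
            all(c("beverage", "elasticity", "sd") %in% names(elasticities)),
            is.data.frame(energy_densities),
            all(c("beverage", "density_kj_per_l", "sd") %in%
                  names(energy_densities)))
  cfg <- list(seed = as.integer(seed),
              n_bmi_samples_per_stratum = as.integer(n_bmi_samples_per_stratum),
              age_lo = age_lo,
              sexes = c("male", "female"),
              mean_ssb_ml = mean_ssb_ml,
              consumption_age_decay = consumption_age_decay,
              bmi_base = bmi_base, bmi_rise = bmi_rise,
              bmi_sd_slope = bmi_sd_slope,
              mortality_base = mortality_base,
              mortality_age_slope = mortality_age_slope,
              incidence_base = incidence_base,
              incidence_age_slope = incidence_age_slope,
              case_fatality_base = case_fatality_base,
              case_fatality_age_slope = case_fatality_age_slope,
              d28 = d28, rr_base = rr_base, rr_age_atten = rr_age_atten,
              rr_log_se = rr_log_se,
              disability_weight = disability_weight,
              pyld_base = pyld_base, pyld_age_slope = pyld_age_slope,
              cost_private = cost_private, private_share = private_share,
              public_private_ratio = public_private_ratio,
              heights = heights, pop_base = pop_base, pop_decay = pop_decay,
              elasticities = elasticities,
              energy_densities = energy_densities,
              kj_per_kg = kj_per_kg, kj_per_kg_sd = kj_per_kg_sd,
              tmreb = tmreb)
  class(cfg) <- "synthetic_config"
  cfg
}

#' Default beverage price-elasticity matrix
#'
#' Own-price elasticity of SSB demand and cross-price elasticities of milk,
#' diet drinks and unsweetened fruit juice with respect to the SSB price,
#' with standard deviations for Monte Carlo sampling. Point values follow the
#' systematic-review estimates commonly used in SSB tax models; the SDs are
#' stand-ins. All are assumptions, configurable per run.
#'
#' @return data.frame with columns `beverage`, `elasticity`, `sd`.
#' @export
default_elasticities <- function() {
  data.frame(beverage = c("ssb", "juice", "milk", "diet"),
             elasticity = c(-1.299, 0.388, 0.129, 0.423),
             sd = c(0.32, 0.18, 0.09, 0.28),
             stringsAsFactors = FALSE)
}

#' Default beverage energy densities (kJ/litre)
#'
#' SSB 1800, unsweetened juice 1340, whole milk 2540, diet drinks 0. The SSB
#' SD of 400 reflects label-survey variation around an alternative mean of
#' 1880 kJ/l and is used only when Monte Carlo sampling of densities is
#' requested.
#'
#' @return data.frame with columns `beverage`, `density_kj_per_l`, `sd`.
#' @export
default_energy_densities <- function() {
  data.frame(beverage = c("ssb", "juice", "milk", "diet"),
             density_kj_per_l = c(1800, 1340, 2540, 0),
             sd = c(400, 0, 0, 0),
             stringsAsFactors = FALSE)
}

band_label <- function(age_lo) sprintf("%d-%d", age_lo, age_lo + 4L)

# Evaluate with a private, seeded RNG stream, restoring the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a complete synthetic input bundle
#'
#' Produces every table the pipeline consumes: beverage consumption with
#' standard errors, BMI moments (plus two "waves" for the SD-vs-mean shift
#' relation, and optional individual samples), mean heights, stroke and
#' all-cause epidemiology, relative risks, elasticities, energy densities
#' and cost inputs, all by 5-year age band and sex. Deterministic for a
#' given configuration: the same seed yields an identical bundle.
#'
#' Structural guarantees (tested): all-cause mortality and stroke incidence
#' increase with age; SSB consumption decreases with age; all rates are
#' non-negative and prevalence is consistent with incidence, case fatality
#' and mortality (a quasi-steady-state prevalence, always < 1).
#'
#' @param config a [synthetic_config()].
#' @return an object of class `ssb_bundle`: a list of data.frames
#'   (`consumption`, `bmi`, `bmi_waves`, `heights`, `epi`, `rr`,
#'   `elasticities`, `energy_densities`, `costs`), scalar `params`, a
#'   `manifest` recording the seed and the true generating parameters, and
#'   optionally `bmi_samples` (a named list of numeric vectors).
#' @export
generate_bundle <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  age_lo <- config$age_lo
  mids <- age_lo + 2L
  nb <- length(age_lo)
  strata <- expand.grid(age_group = band_label(age_lo),
                        sex = config$sexes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  strata_mid <- rep(mids, times = length(config$sexes))
  sex_idx <- rep(seq_along(config$sexes), each = nb)

  # population: young-heavy pyramid
  pop <- round(config$pop_base *
                 exp(-config$pop_decay * (rep(seq_len(nb), 2L) - 1L)) *
                 ifelse(sex_idx == 1L, 1.0, 1.04))

  # consumption: SSB declines with age; scale to hit the target weighted mean
  sexfac_ssb <- ifelse(sex_idx == 1L, 1.05, 0.95)
  ssb_shape <- exp(-config$consumption_age_decay * (strata_mid - 17)) *
    sexfac_ssb
  ssb_ml <- ssb_shape * config$mean_ssb_ml * sum(pop) / sum(pop * ssb_shape)
  milk_ml <- 110 * exp(-0.005 * (strata_mid - 17)) *
    ifelse(sex_idx == 1L, 0.95, 1.05)
  juice_ml <- 40 * exp(-0.010 * (strata_mid - 17))
  diet_ml <- 25 * exp(-0.020 * (strata_mid - 17)) *
    ifelse(sex_idx == 1L, 0.9, 1.1)
  consumption <- do.call(rbind, Map(function(bev, q) {
    data.frame(strata, beverage = bev, intake_ml = q, intake_se = 0.08 * q,
               stringsAsFactors = FALSE)
  }, c("ssb", "juice", "milk", "diet"),
  list(ssb_ml, juice_ml, milk_ml, diet_ml)))
  rownames(consumption) <- NULL

  # BMI: rises with age, mild late-life decline; SD tied to the mean
  bbase <- config$bmi_base[config$sexes][sex_idx]
  brise <- config$bmi_rise[config$sexes][sex_idx]
  bmi_mean <- bbase + brise * (1 - exp(-0.06 * (strata_mid - 17))) -
    0.03 * pmax(strata_mid - 65, 0)
  bmi_sd <- 3.2 + config$bmi_sd_slope * (bmi_mean - 22)
  ln <- fit_lognormal(bmi_mean, bmi_sd)
  bmi <- data.frame(strata, mean = bmi_mean, sd = bmi_sd,
                    stringsAsFactors = FALSE)

  heights <- data.frame(strata,
                        height_m = config$heights[config$sexes][sex_idx] -
                          0.0005 * pmax(strata_mid - 50, 0),
                        stringsAsFactors = FALSE)

  # epidemiology
  m_all <- config$mortality_base *
    exp(config$mortality_age_slope * (strata_mid - 17)) *
    ifelse(sex_idx == 1L, 1.0, 0.85)
  inc <- config$incidence_base *
    exp(config$incidence_age_slope * (strata_mid - 17)) *
    ifelse(sex_idx == 1L, 1.0, 0.95)
  cf <- config$case_fatality_base +
    config$case_fatality_age_slope * (strata_mid - 17)
  d28 <- rep(config$d28, nrow(strata))
  prev <- inc * (1 - d28) / (inc + cf + m_all) # quasi-steady state, < 1
  pyld <- config$pyld_base + config$pyld_age_slope * (strata_mid - 17) +
    prev * config$disability_weight
  epi <- data.frame(strata, population = pop, mortality_all = m_all,
                    stroke_incidence = inc, stroke_prevalence = prev,
                    case_fatality = cf, d28_fatality = d28,
                    pyld_rate = pyld, stringsAsFactors = FALSE)

  rr <- data.frame(strata,
                   rr_per_unit = 1 + (config$rr_base - 1) *
                     exp(-config$rr_age_atten * (strata_mid - 22)),
                   log_se = rep(config$rr_log_se, nrow(strata)),
                   stringsAsFactors = FALSE)

  costs <- data.frame(cost_private_per_case_year = config$cost_private,
                      private_share = config$private_share,
                      public_private_ratio = config$public_private_ratio)

  seeded <- with_seed(config$seed, {
    # two BMI "waves" to re-estimate the SD-vs-mean shift relation
    d_mean <- 0.4 + stats::rnorm(nrow(strata), 0, 0.05)
    d_sd <- config$bmi_sd_slope * d_mean + stats::rnorm(nrow(strata), 0, 0.01)
    waves <- data.frame(strata,
                        mean_wave1 = bmi_mean, sd_wave1 = bmi_sd,
                        mean_wave2 = bmi_mean + d_mean,
                        sd_wave2 = bmi_sd + d_sd,
                        stringsAsFactors = FALSE)
    samples <- NULL
    if (config$n_bmi_samples_per_stratum > 0L) {
      samples <- lapply(seq_len(nrow(strata)), function(i) {
        stats::rlnorm(config$n_bmi_samples_per_stratum, ln$mu[i], ln$sigma[i])
      })
      names(samples) <- paste(strata$age_group, strata$sex, sep = "_")
    }
    list(waves = waves, samples = samples)
  })

  sd_slope_hat <- estimate_sd_slope(seeded$waves)

  params <- list(kj_per_kg = config$kj_per_kg,
                 kj_per_kg_sd = config$kj_per_kg_sd,
                 tmreb = config$tmreb,
                 disability_weight = config$disability_weight,
                 sd_slope = sd_slope_hat,
                 portion_ref_ml = 330)

  manifest <- list(seed = config$seed,
                   age_lo = age_lo,
                   sexes = config$sexes,
                   n_bmi_samples_per_stratum = config$n_bmi_samples_per_stratum,
                   true_bmi = data.frame(strata, mu = ln$mu, sigma = ln$sigma,
                                         stringsAsFactors = FALSE),
                   true_sd_slope = config$bmi_sd_slope,
                   params = params)

  bundle <- list(consumption = consumption, bmi = bmi,
                 bmi_waves = seeded$waves, heights = heights, epi = epi,
                 rr = rr, elasticities = config$elasticities,
                 energy_densities = config$energy_densities, costs = costs,
                 params = params, manifest = manifest,
                 bmi_samples = seeded$samples)
  class(bundle) <- "ssb_bundle"
  bundle
}

#' @export
print.ssb_bundle <- function(x, ...) {
  cat("<ssb_bundle>", nrow(x$epi), "strata (",
      length(unique(x$epi$age_group)), "age bands x",
      length(unique(x$epi$sex)), "sexes ), seed", x$manifest$seed, "\n")
  cat("  population:", format(sum(x$epi$population), big.mark = " "),
      " mean SSB intake:",
      round(sum(with(subset(x$consumption, beverage == "ssb"),
                     intake_ml * x$epi$population)) / sum(x$epi$population), 1),
      "ml/day\n")
  invisible(x)
}

# full-precision CSV so that write -> read round-trips bit-exactly
write_csv_fp <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- sprintf("%.17g", out[[j]])
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
}

#' Write an input bundle to a directory of CSV files
#'
#' One CSV per table plus `manifest.json` recording the seed, the scalar
#' parameters and the true log-normal parameters of each stratum (the test
#' oracle). Numeric columns are written at full precision so that
#' `read_bundle(write_bundle(b))` reproduces `b` exactly.
#'
#' @param bundle an `ssb_bundle`.
#' @param dir output directory (created if needed).
#' @param include_samples also write individual BMI samples (can be large).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, include_samples = FALSE) {
  stopifnot(inherits(bundle, "ssb_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("consumption", "bmi", "bmi_waves", "heights", "epi", "rr",
            "elasticities", "energy_densities", "costs")
  for (tb in tabs) {
    write_csv_fp(bundle[[tb]], file.path(dir, paste0(tb, ".csv")))
  }
  if (include_samples && !is.null(bundle$bmi_samples)) {
    wide <- data.frame(bundle$bmi_samples, check.names = FALSE)
    write_csv_fp(wide, file.path(dir, "bmi_samples.csv"))
  }
  man <- bundle$manifest
  man$true_bmi <- as.list(man$true_bmi)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(dir)
}

#' Read an input bundle from a directory of CSV files
#'
#' @param dir directory written by [write_bundle()] (or hand-authored CSVs
#'   with the same headers).
#' @return an `ssb_bundle`.
#' @export
read_bundle <- function(dir) {
  tabs <- c("consumption", "bmi", "bmi_waves", "heights", "epi", "rr",
            "elasticities", "energy_densities", "costs")
  bundle <- lapply(tabs, function(tb) {
    p <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(p)) stop("missing bundle table: ", p, call. = FALSE)
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    # all numeric columns are doubles by contract (whole numbers included)
    df[] <- lapply(df, function(x) if (is.integer(x)) as.numeric(x) else x)
    df
  })
  names(bundle) <- tabs
  manp <- file.path(dir, "manifest.json")
  if (file.exists(manp)) {
    man <- jsonlite::read_json(manp, simplifyVector = TRUE)
    man$true_bmi <- as.data.frame(man$true_bmi, stringsAsFactors = FALSE)
    bundle$manifest <- man
    bundle$params <- lapply(man$params, function(x) {
      if (is.integer(x)) as.numeric(x) else x
    })
  } else {
    stop("missing manifest.json in ", dir, call. = FALSE)
  }
  sp <- file.path(dir, "bmi_samples.csv")
  if (file.exists(sp)) {
    wide <- utils::read.csv(sp, check.names = FALSE)
    bundle$bmi_samples <- as.list(wide)
  } else {
    bundle$bmi_samples <- NULL
  }
  class(bundle) <- "ssb_bundle"
  bundle
}
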
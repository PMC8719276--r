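#' World configuration for the synthetic burden world
#'
#' Defines the demographic frame (locations, years, age groups, sexes, cancer
#' groups) and the observation process (registry coverage, vital-registration
#' completeness, garbage-code fraction, count dispersion) of a small synthetic
#' world with known ground truth. The defaults give the standard testing
#' world: 8 locations x 20 years x 12 age groups x 2 sexes x 5 cancer groups.
#'
#' @param n_locations number of locations (>= 2)
#' @param years inclusive integer year range (default 2000:2019)
#' @param age_breaks ordered age-interval breaks starting at 0 and ending at
#'   `Inf`; consecutive breaks define left-closed, right-open intervals, the
#'   last interval is open-ended
#' @param cancer_groups character vector of cancer cause identifiers (>= 2)
#' @param registry_coverage fraction in \[0,1\]: probability that a
#'   location-year is covered by a cancer registry
#' @param vr_completeness fraction in (0,1\]: completeness of the
#'   vital-registration death counts
#' @param garbage_fraction fraction in \[0,1): share of liver-cancer deaths
#'   coded to the unspecified code "C22.9"
#' @param noise_scale non-negative dispersion of observed counts
#'   (negative-binomial; 0 gives Poisson). Affects observation sampling only,
#'   never the true world.
#' @param haq_range range of location baseline values of the health-care
#'   access and quality (HAQ) covariate, on \[0,100\]
#' @param haq_trend HAQ units gained per year in every location
#' @param mir_cap upper bound of the MIR ratio scale
#' @param seed master integer seed for the world
#' @return a `world_config` list
#' @export
#' @examples
#' cfg <- world_config(n_locations = 3, cancer_groups = c("stomach", "liver"))
#' cfg$locations
world_config <- function(n_locations = 8,
                         years = 2000:2019,
                         age_breaks = c(0, 15, 25, 35, 45, 50, 55, 60,
                                        65, 70, 75, 80, Inf),
                         cancer_groups = c("tracheal_bronchus_lung",
                                           "colon_rectum", "stomach",
                                           "breast", "liver"),
                         registry_coverage = 0.7,
                         vr_completeness = 0.95,
                         garbage_fraction = 0.15,
                         noise_scale = 0.1,
                         haq_range = c(35, 80),
                         haq_trend = 0.5,
                         mir_cap = 1.0,
                         seed = 1L) {
  fail <- function(field, msg) {
    stop(sprintf("invalid world configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (!is.numeric(n_locations) || n_locations < 2) {
    fail("n_locations", "must be at least 2")
  }
  years <- as.integer(years)
  if (length(years) < 2 || is.unsorted(years, strictly = TRUE)) {
    fail("years", "must be a strictly increasing integer range")
  }
  if (age_breaks[1] != 0 || !is.infinite(age_breaks[length(age_breaks)]) ||
      is.unsorted(age_breaks, strictly = TRUE)) {
    fail("age_breaks", "must partition [0, Inf): start at 0, strictly increase, end at Inf")
  }
  if (length(cancer_groups) < 2 || anyDuplicated(cancer_groups)) {
    fail("cancer_groups", "must list at least 2 distinct cancer groups")
  }
  if (registry_coverage < 0 || registry_coverage > 1) {
    fail("registry_coverage", "must lie in [0,1]")
  }
  if (vr_completeness <= 0 || vr_completeness > 1) {
    fail("vr_completeness", "must lie in (0,1]")
  }
  if (garbage_fraction < 0 || garbage_fraction >= 1) {
    fail("garbage_fraction", "must lie in [0,1)")
  }
  if (noise_scale < 0) fail("noise_scale", "must be non-negative")
  if (length(haq_range) != 2 || any(haq_range < 0) || any(haq_range > 100) ||
      haq_range[1] > haq_range[2]) {
    fail("haq_range", "must be an ordered pair within [0,100]")
  }
  if (mir_cap <= 0) fail("mir_cap", "must be positive")
  structure(list(
    n_locations = as.integer(n_locations),
    locations = sprintf("L%02d", seq_len(n_locations)),
    years = years,
    age_breaks = age_breaks,
    cancer_groups = cancer_groups,
    registry_coverage = registry_coverage,
    vr_completeness = vr_completeness,
    garbage_fraction = garbage_fraction,
    noise_scale = noise_scale,
    haq_range = haq_range,
    haq_trend = haq_trend,
    mir_cap = mir_cap,
    seed = as.integer(seed)
  ), class = "world_config")
}

# cancer-specific true parameters of the synthetic world. MIR model on the
# logit scale: intercept + age slope * (midpoint - 50) + beta_haq * haq +
# year drift; incidence: peak rate per 100k at the modal age of a unimodal
# gamma-shaped age schedule, with a sex multiplier.
cancer_params <- function(cancer_groups) {
  ref <- data.table::data.table(
    cause = c("tracheal_bronchus_lung", "colon_rectum", "stomach",
              "breast", "liver"),
    mir_intercept = c(2.6, 1.2, 2.2, 0.4, 3.0),
    mir_age_slope = c(0.012, 0.010, 0.010, 0.008, 0.010),
    mir_beta_haq  = c(-0.030, -0.035, -0.030, -0.040, -0.025),
    mir_year_drift = c(-0.010, -0.012, -0.010, -0.015, -0.008),
    inc_peak_rate = c(180, 160, 90, 200, 60),   # per 100k at modal age
    inc_age_mode  = c(70, 68, 70, 62, 66),
    inc_age_shape = c(16, 14, 15, 9, 13),
    male_mult     = c(1.5, 1.15, 1.5, 0.02, 1.6)
  )
  known <- ref[ref$cause %in% cancer_groups]
  extra <- setdiff(cancer_groups, ref$cause)
  if (length(extra)) {
    # unknown causes get a generic mid-range parameterisation, perturbed
    # deterministically by name so two extras differ
    h <- vapply(extra, function(x) sum(utf8ToInt(x)) %% 13L, integer(1))
    known <- rbind(known, data.table::data.table(
      cause = extra,
      mir_intercept = 1.5 + 0.05 * h,
      mir_age_slope = 0.010,
      mir_beta_haq = -0.030,
      mir_year_drift = -0.010,
      inc_peak_rate = 80 + 5 * h,
      inc_age_mode = 65 + (h %% 5L),
      inc_age_shape = 12,
      male_mult = 1.2
    ))
  }
  known[match(cancer_groups, known$cause)]
}

#' Generate the true synthetic world
#'
#' Builds the ground truth every downstream stage is tested against:
#' populations, the HAQ covariate, SDI components, and true MIR, incidence and
#' mortality surfaces. True MIR is inverse-logit of (cancer intercept + age
#' effect + beta x HAQ + year drift) with beta < 0, so MIR declines as health
#' care access improves; incidence age schedules are unimodal gamma shapes;
#' mortality is defined as incidence x MIR, so the identity M = I x MIR holds
#' on every grid cell by construction.
#'
#' Only the world seed feeds this stage: observation parameters such as
#' `noise_scale` play no role, keeping truth and observation separate.
#'
#' @param config a [world_config()]
#' @return a `true_world` list: `config`, `population`, `haq`,
#'   `sdi_components`, and `rates` (cause grid with `true_mir`,
#'   `true_incidence_rate`, `true_mortality_rate`, rates per 100 000
#'   person-years)
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  par <- cancer_params(config$cancer_groups)
  with_rng(derive_seed(config$seed, "world"), {
    locs <- config$locations
    yrs <- config$years
    ages <- age_table(config$age_breaks)
    mids <- ifelse(is.finite(ages$age_end),
                   (ages$age_start + ages$age_end) / 2,
                   ages$age_start + 5)

    # HAQ: location baselines spread over haq_range, common upward trend
    base <- if (diff(config$haq_range) == 0) {
      rep(config$haq_range[1], length(locs))
    } else {
      seq(config$haq_range[1], config$haq_range[2], length.out = length(locs))
    }
    haq <- data.table::CJ(location = locs, year = yrs, sorted = FALSE)
    haq[, haq := pmin(100, pmax(0, base[match(location, locs)] +
                                  config$haq_trend * (year - min(yrs))))]

    # SDI components in [0,1], tied to HAQ with location-specific offsets
    off <- stats::rnorm(length(locs), 0, 0.04)
    sdi <- data.table::copy(haq)
    sdi[, income := pmin(0.99, pmax(0.05, (haq / 100)^1.1 +
                                      off[match(location, locs)]))]
    sdi[, edu := pmin(0.99, pmax(0.05, (haq / 100)^0.9 -
                                   off[match(location, locs)] / 2))]
    sdi[, fert_u25 := pmin(0.99, pmax(0.05, (haq / 100)^1.0 +
                                        off[match(location, locs)] / 3))]
    sdi[, haq := NULL]

    # population: location size x declining age pyramid x 1%/yr growth
    loc_size <- 10^stats::runif(length(locs), 5.8, 6.8)
    pyramid <- exp(-0.025 * mids)
    pyramid <- pyramid / sum(pyramid)
    pop <- demographic_grid(config, by_cause = FALSE)
    pop[, population :=
          loc_size[match(location, locs)] *
          pyramid[match(age_start, ages$age_start)] * 0.5 *
          1.01^(year - min(yrs))]

    # true surfaces
    rates <- demographic_grid(config, by_cause = TRUE)
    rates <- merge(rates, haq, by = c("location", "year"), sort = FALSE)
    i <- match(rates$cause, par$cause)
    mid <- mids[match(rates$age_start, ages$age_start)]
    lg <- par$mir_intercept[i] +
      par$mir_age_slope[i] * (mid - 50) +
      par$mir_beta_haq[i] * rates$haq +
      par$mir_year_drift[i] * (rates$year - min(yrs))
    rates[, mir_true := invlogit_mir(lg, cap = config$mir_cap)]
    shape <- par$inc_age_shape[i]
    mode_age <- par$inc_age_mode[i]
    sched <- stats::dgamma(mid, shape = shape, rate = (shape - 1) / mode_age) /
      stats::dgamma(mode_age, shape = shape, rate = (shape - 1) / mode_age)
    sexmul <- ifelse(rates$sex == "male", par$male_mult[i], 1)
    rates[, true_incidence_rate := par$inc_peak_rate[i] * sched * sexmul]
    rates[, true_mortality_rate := true_incidence_rate * mir_true]
    data.table::setnames(rates, "mir_true", "true_mir")
    rates[, haq := NULL]

    structure(list(config = config, population = pop[], haq = haq[],
                   sdi_components = sdi[], rates = rates[]),
              class = "true_world")
  })
}

#' @export
print.true_world <- function(x, ...) {
  cat(sprintf(
    "<true_world: %d locations, %d years, %d age groups, %d cancer groups>\n",
    length(x$config$locations), length(x$config$years),
    length(x$config$age_breaks) - 1, length(x$config$cancer_groups)))
  invisible(x)
}

# negative-binomial counts with dispersion = noise_scale; Poisson when 0.
# var = mu + noise_scale * mu^2
sample_counts <- function(mu, noise_scale) {
  n <- length(mu)
  if (noise_scale <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / noise_scale, mu = mu)
}

#' Registry coverage mask
#'
#' Deterministic (seed-derived) Bernoulli mask over location-years declaring
#' which cells a cancer registry observes; sampling respects it exactly.
#'
#' @param world a `true_world`
#' @return `data.table` (location, year, covered)
#' @export
registry_coverage_mask <- function(world) {
  cfg <- world$config
  with_rng(derive_seed(cfg$seed, "registry_mask"), {
    m <- data.table::CJ(location = cfg$locations, year = cfg$years,
                        sorted = FALSE)
    m[, covered := stats::runif(.N) < cfg$registry_coverage]
    m[]
  })
}

#' Sample cancer-registry incidence data from the true world
#'
#' Emits observed incident case counts for covered location-years only, drawn
#' from a negative-binomial distribution centred on
#' `true_incidence_rate x population / 1e5` with dispersion `noise_scale`
#' (Poisson when `noise_scale = 0`). Person-years equal the cell population.
#'
#' @param world a `true_world`
#' @param config the [world_config()] the world was generated from
#' @return `data.table` (location, year, age_start, age_end, sex, cause,
#'   cases, person_years)
#' @export
sample_registry_data <- function(world, config = world$config) {
  mask <- registry_coverage_mask(world)
  covered <- mask[covered == TRUE, .(location, year)]
  reg <- merge(world$rates, world$population,
               by = c("location", "year", "age_start", "age_end", "sex"),
               sort = FALSE)
  reg <- merge(reg, covered, by = c("location", "year"), sort = FALSE)
  data.table::setorderv(reg, c("cause", "location", "year", "age_start", "sex"))
  with_rng(derive_seed(config$seed, "registry"), {
    reg[, cases := sample_counts(true_incidence_rate * population / 1e5,
                                 config$noise_scale)]
  })
  out <- reg[, .(location, year, age_start, age_end, sex, cause, cases,
                 person_years = population)]
  data.table::setattr(out, "coverage_mask", mask)
  out[]
}

# representative ICD-10 code per synthetic cancer group
cause_to_icd <- function(causes) {
  ref <- c(tracheal_bronchus_lung = "C34", colon_rectum = "C18",
           stomach = "C16", breast = "C50", liver = "C22.0")
  out <- ref[causes]
  # unknown causes get a stable code in the C76-C80 "other" block
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- sprintf("C%02d", 76 + (vapply(causes[miss], function(x)
      sum(utf8ToInt(x)), numeric(1)) %% 5))
  }
  unname(out)
}

#' Sample vital-registration death records from the true world
#'
#' Deaths per demographic cell are negative-binomial around
#' `true_mortality_rate x population / 1e5 x vr_completeness`, keyed by a
#' representative ICD-10 code per cancer group. A binomial fraction
#' `garbage_fraction` of liver-cancer deaths is recoded to the unspecified
#' liver code "C22.9" (the garbage code downstream redistribution must fix).
#'
#' @inheritParams sample_registry_data
#' @return `data.table` (location, year, age_start, age_end, sex, icd_code,
#'   deaths)
#' @export
sample_vr_data <- function(world, config = world$config) {
  vr <- merge(world$rates, world$population,
              by = c("location", "year", "age_start", "age_end", "sex"),
              sort = FALSE)
  data.table::setorderv(vr, c("cause", "location", "year", "age_start", "sex"))
  with_rng(derive_seed(config$seed, "vr"), {
    vr[, deaths := sample_counts(
      true_mortality_rate * population / 1e5 * config$vr_completeness,
      config$noise_scale)]
    vr[, icd_code := cause_to_icd(cause)]
    liver <- vr$cause == "liver"
    if (any(liver) && config$garbage_fraction > 0) {
      garb <- stats::rbinom(sum(liver), vr$deaths[liver],
                            config$garbage_fraction)
      g <- vr[liver][, `:=`(deaths = garb, icd_code = "C22.9")]
      vr[liver, deaths := deaths - garb]
      vr <- rbind(vr, g[deaths >= 0])
    }
  })
  out <- vr[, .(location, year, age_start, age_end, sex, icd_code, deaths)]
  data.table::setorderv(out, c("location", "year", "age_start", "sex",
                               "icd_code"))
  out[]
}

#' Write the synthetic world observation CSVs
#'
#' Runs [generate_world()], [sample_registry_data()] and [sample_vr_data()]
#' and writes `registry.csv`, `vr.csv`, `population.csv` and `covariates.csv`
#' to a directory, the file interface downstream stages read.
#'
#' @param config a [world_config()]
#' @param out_dir output directory (created if absent)
#' @return invisibly, the `true_world` (so tests can compare against truth)
#' @export
simulate_world_csvs <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  world <- generate_world(config)
  reg <- sample_registry_data(world, config)
  vr <- sample_vr_data(world, config)
  cov <- merge(world$haq, world$sdi_components, by = c("location", "year"))
  data.table::fwrite(reg, file.path(out_dir, "registry.csv"))
  data.table::fwrite(vr, file.path(out_dir, "vr.csv"))
  data.table::fwrite(world$population, file.path(out_dir, "population.csv"))
  data.table::fwrite(cov, file.path(out_dir, "covariates.csv"))
  invisible(world)
}
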
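# shared fixtures: small worlds are cheap to build, the full default-world
# pipeline run is memoized so several test files can interrogate it

small_config <- function(seed = 101, ...) {
  world_config(n_locations = 4, years = 2010:2019,
               age_breaks = c(0, 25, 45, 55, 65, 75, Inf),
               cancer_groups = c("stomach", "breast"),
               seed = seed, ...)
}

.cache <- new.env(parent = emptyenv())

# small prepared world: observations and grid ready for model stages
small_prepared <- function(seed = 101) {
  key <- paste0("prep", seed)
  if (is.null(.cache[[key]])) {
    cfg <- small_config(seed)
    w <- generate_world(cfg)
    reg <- sample_registry_data(w, cfg)
    vr <- sample_vr_data(w, cfg)
    mv <- map_vr_deaths(vr, default_cause_map(cfg$cancer_groups))
    deaths <- redistribute_unspecified_liver(mv$mapped, mv$garbage,
                                             proportions = c(liver = 1))
    obs <- suppressWarnings(
      stabilized_mir_observations(reg, deaths, cap = cfg$mir_cap))
    .cache[[key]] <- list(cfg = cfg, world = w, registry = reg, vr = vr,
                          deaths = deaths, obs = obs,
                          grid = demographic_grid(cfg))
  }
  .cache[[key]]
}

# the full default-world pipeline run (8 locations x 20 years x 12 ages x
# 2 sexes x 5 cancers, 1000 draws); computed once, with its wall time
full_run <- function() {
  if (is.null(.cache$full)) {
    cfg <- pipeline_config(n_draws = 1000, seed = 20190)
    t0 <- Sys.time()
    res <- run_pipeline(cfg)
    .cache$full <- list(res = res, config = cfg,
                        minutes = as.numeric(Sys.time() - t0,
                                             units = "mins"))
  }
  .cache$full
}

# true age-standardized mortality per cause from a world's ground truth
true_asmr_by_cause <- function(world, std, ref_year = 2019) {
  wv <- stats::setNames(std$weight / sum(std$weight),
                        as.character(std$age_start))
  tr <- merge(world$rates, world$population,
              by = c("location", "year", "age_start", "age_end", "sex"))
  t19 <- tr[tr$year == ref_year,
            list(deaths = sum(true_mortality_rate * population / 1e5),
                 pop = sum(population)),
            by = c("cause", "age_start")]
  t19$rate <- t19$deaths / t19$pop * 1e5
  out <- t19[, list(asmr = sum(rate * wv[as.character(age_start)])),
             by = "cause"]
  stats::setNames(out$asmr, out$cause)
}
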
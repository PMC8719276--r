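#' Mortality modeling table for the ensemble
#'
#' Joins mapped vital-registration deaths with population, covariates and
#' the all-cause envelope rate, and appends MIR-converted registry
#' pseudo-deaths (registry incident cases times the estimated MIR) carrying
#' an inflated variance, ie a down-weighted regression weight
#' `1 / inflation`.
#'
#' @param deaths_tab mapped deaths (location, year, age_start, age_end, sex,
#'   cause, deaths)
#' @param registry registry table
#' @param mir_mean_tab table (cause, location, year, age_start, sex,
#'   mir_mean)
#' @param world a `true_world` (for population and covariates)
#' @param envelope_rate table (location, year, age_start, sex,
#'   envelope_rate) of all-cause deaths per 100 000
#' @param inflation pseudo-observation variance inflation
#' @return modeling `data.table` with a `weight` column
#' @export
assemble_mortality_data <- function(deaths_tab, registry, mir_mean_tab,
                                    world, envelope_rate, inflation = 2) {
  sdi <- world$sdi_components[, .(location, year,
                                  sdi = compute_sdi(income, edu, fert_u25))]
  covs <- merge(world$haq, sdi, by = c("location", "year"))
  base <- merge(data.table::as.data.table(deaths_tab),
                world$population,
                by = c("location", "year", "age_start", "age_end", "sex"))
  base[, weight := 1]
  pseudo <- merge(data.table::as.data.table(registry), mir_mean_tab,
                  by = c("cause", "location", "year", "age_start", "sex"))
  pseudo <- pseudo[, .(location, year, age_start, age_end, sex, cause,
                       deaths = cases * mir_mean,
                       population = person_years,
                       weight = 1 / inflation)]
  d <- rbind(base[, names(pseudo), with = FALSE], pseudo)
  d <- merge(d, covs, by = c("location", "year"))
  d <- merge(d, envelope_rate, by = c("location", "year", "age_start", "sex"))
  d[]
}

# per-cell relative survival matrix S(1..10) from MIR means and the
# frontier curves (cause-specific, falling back to "default" rows)
survival_matrix <- function(grid, mir_mean, frontier, cap = 1) {
  S <- matrix(NA_real_, nrow(grid), 10)
  mirs <- pmin(pmax(mir_mean / cap, 1e-6), 1)
  for (cz in unique(grid$cause)) {
    fc <- frontier[cause == cz][order(t_year)]
    if (!nrow(fc)) fc <- frontier[cause == "default"][order(t_year)]
    rows <- which(grid$cause == cz)
    S[rows, ] <- survival_from_mir(mirs[rows], fc$best, fc$worst)
  }
  S
}

# draw-wise sequela YLDs, chunked over draw columns to bound memory
sequela_yld_draws <- function(prevalence, deaths, incidence, params,
                              chunk = 200) {
  dur <- setNames(params$duration_years, params$phase)
  dur <- dur[c("diagnosis_treatment", "metastatic", "terminal")]
  dw <- setNames(params$disability_weight, params$phase)
  n <- nrow(prevalence$draws)
  nd <- ncol(prevalence$draws)
  out <- matrix(0, n, nd)
  for (j0 in seq(1, nd, by = chunk)) {
    j <- j0:min(j0 + chunk - 1, nd)
    ph <- partition_sequelae(as.vector(prevalence$draws[, j]),
                             as.vector(deaths$draws[, j]),
                             as.vector(incidence$draws[, j]),
                             durations = dur)
    out[, j] <- matrix(compute_ylds(ph, weights = dw), nrow = n)
  }
  draw_surface(prevalence$grid, out)
}

# mean-level procedure-related YLDs for eligible causes, spread across age
# groups in proportion to prevalent person-years
procedure_yld_means <- function(incidence, prevalence, surv, bg, params) {
  g <- incidence$grid
  yld <- numeric(nrow(g))
  inc_mean <- rowMeans(incidence$draws)
  prev_mean <- rowMeans(prevalence$draws)
  s10 <- surv[, 10] * exp(-bg * 10)
  eligible <- intersect(unique(g$cause),
                        c(procedure_cancers, "colon_rectum"))
  for (cz in eligible) {
    nm <- if (cz == "colon_rectum") "colorectal" else cz
    pr <- params[cause == nm]
    if (!nrow(pr)) next
    rows <- which(g$cause == cz)
    gg <- g[rows]
    sv <- data.table::data.table(gg, survivors = inc_mean[rows] * s10[rows])
    ser <- split(seq_len(nrow(gg)), gg[, paste(location, sex)])
    for (ix in ser) {
      byy <- rowsum(sv$survivors[ix], sv$year[ix])
      years <- as.integer(rownames(byy))
      pp <- procedure_prevalence(
        cz, data.table::data.table(year = years,
                                   proportion = pr$proportion[1]),
        data.table::data.table(year = years, survivors = byy[, 1]),
        background = mean(bg[rows][ix]))
      # spread the series prevalence over the cells of each year by
      # prevalent person-years
      for (k in seq_len(nrow(pp))) {
        cells <- ix[sv$year[ix] == pp$year[k]]
        w <- prev_mean[rows][cells]
        w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(cells),
                                                 length(cells))
        yld[rows[cells]] <- yld[rows[cells]] +
          pp$prevalence[k] * w * pr$disability_weight[1]
      }
    }
  }
  yld
}

#' Run the full burden estimation pipeline
#'
#' Simulate (or accept) a synthetic world, prepare the data (ICD mapping,
#' garbage-code redistribution, MIR observations), fit the three-stage MIR
#' model, fit the mortality ensemble per cancer and sex and scale it to the
#' all-cause envelope (alongside a synthetic non-cancer remainder cause so
#' the cancer causes keep their level while the scaler is exercised),
#' back-calculate incidence, compute 10-year prevalence, sequela and
#' procedure YLDs, YLLs and DALYs, and assemble the burden report. With an
#' `out_dir`, stage CSVs and a manifest (stage, file, md5, seed) are
#' written; re-running an identical configuration reproduces identical
#' outputs.
#'
#' @param config a [pipeline_config()]
#' @param world optional pre-generated `true_world` (must match
#'   `config$world`)
#' @param life_table reference life table (default packaged fixture)
#' @param std standard population (default packaged fixture)
#' @param verbose print stage progress to stderr?
#' @return list of class `pipeline_result`: `world`, `mir`, `mortality`,
#'   `incidence`, `yll`, `yld`, `daly` (draw surfaces), `report` (a
#'   `burden_report`), `validation`, `mir_observations`
#' @export
run_pipeline <- function(config = pipeline_config(), world = NULL,
                         life_table = reference_life_table(),
                         std = standard_population(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message("[oncoburden] ", sprintf(...))
  wcfg <- config$world
  say("stage 1/6: synthetic world")
  if (is.null(world)) world <- generate_world(wcfg)
  registry <- sample_registry_data(world, wcfg)
  vr <- sample_vr_data(world, wcfg)
  val <- validate_inputs(list(registry = registry, vr = vr,
                              population = world$population,
                              covariates = world$haq))
  if (length(val$fatal)) {
    stop("pipeline halted at stage data_prep: ",
         paste(val$fatal, collapse = "; "), call. = FALSE)
  }

  say("stage 2/6: data preparation")
  cmap <- default_cause_map(wcfg$cancer_groups)
  mv <- map_vr_deaths(vr, cmap)
  # synthetic garbage C22.9 deaths are recoded primary liver deaths, so the
  # pipeline default returns them to liver; real-world proportions are
  # unknown and configurable at the operation level
  deaths_tab <- redistribute_unspecified_liver(mv$mapped, mv$garbage,
                                               proportions = c(liver = 1))
  # completeness correction with the declared VR completeness (estimating
  # completeness is out of scope)
  deaths_tab[, deaths := deaths / wcfg$vr_completeness]
  obs <- suppressWarnings(
    stabilized_mir_observations(registry, deaths_tab, cap = wcfg$mir_cap))

  say("stage 3/6: MIR model (%d observations)", nrow(obs))
  grid <- demographic_grid(wcfg, by_cause = TRUE)
  mir_surf <- fit_mir(obs, world$haq, grid, config$mir)
  mir_mean <- surface_mean(mir_surf)
  mir_mean_tab <- data.table::data.table(
    mir_surf$grid[, .(cause, location, year, age_start, sex)],
    mir_mean = mir_mean)

  say("stage 4/6: mortality ensemble")
  env <- synthetic_envelope(world, config$n_draws,
                            config$ensemble$envelope_multiplier,
                            seed = derive_seed(config$seed, "envelope"))
  env_mean <- surface_mean(env)
  popg <- world$population
  env_rate <- data.table::data.table(
    env$grid[, .(location, year, age_start, sex)],
    envelope_rate = env_mean /
      popg[env$grid, population,
           on = c("location", "year", "age_start", "sex")] * 1e5)
  mdata <- assemble_mortality_data(deaths_tab, registry, mir_mean_tab,
                                   world, env_rate,
                                   config$ensemble$pseudo_variance_inflation)
  pred_grid <- merge(grid, popg,
                     by = c("location", "year", "age_start", "age_end",
                            "sex"), sort = FALSE)
  pred_grid <- merge(pred_grid, mdata[
    , unique(.SD), .SDcols = c("location", "year", "haq", "sdi")],
    by = c("location", "year"), sort = FALSE)
  pred_grid <- merge(pred_grid, env_rate,
                     by = c("location", "year", "age_start", "sex"),
                     sort = FALSE)
  data.table::setorderv(pred_grid, c("cause", "location", "year",
                                     "age_start", "sex"))

  # score submodel validity with the same age weights the report uses
  if (is.null(config$ensemble$asr_weights)) {
    ages <- sort(unique(grid$age_start))
    hit <- match(ages, std$age_start)
    if (!anyNA(hit)) {
      config$ensemble$asr_weights <- stats::setNames(std$weight[hit],
                                                     as.character(ages))
    }
  }
  submodels <- enumerate_submodels(config$ensemble$covariate_pool,
                                   config$ensemble$max_subset_size)
  mort_draws <- matrix(NA_real_, nrow(grid), config$n_draws)
  ens_info <- list()
  for (cz in wcfg$cancer_groups) for (sx in c("male", "female")) {
    dcs <- mdata[cause == cz & sex == sx]
    gcs_rows <- which(pred_grid$cause == cz & pred_grid$sex == sx)
    gcs <- pred_grid[gcs_rows]
    ccfg <- config$ensemble
    ccfg$seed <- derive_seed(config$seed, paste("ens", cz, sx))
    w <- oos_validity_weights(submodels, dcs, ccfg)
    ds <- ensemble_draws(submodels, w$weights, dcs, gcs, ccfg,
                         oos_rmse = w$oos_rmse)
    mort_draws[gcs_rows, ] <- ds$draws
    ens_info[[paste(cz, sx)]] <- w
  }
  # align to canonical grid order
  ord <- data.table::copy(grid)
  data.table::setorderv(ord, c("cause", "location", "year", "age_start",
                               "sex"))
  pg_key <- pred_grid[, paste(cause, location, year, age_start, sex)]
  ord_key <- ord[, paste(cause, location, year, age_start, sex)]
  mort <- draw_surface(ord, mort_draws[match(ord_key, pg_key), ,
                                       drop = FALSE])

  say("stage 4/6: envelope scaling")
  # synthetic non-cancer remainder so the all-cause scaler has headroom
  tot_cancer <- agg_draws(mort$grid, mort$draws,
                          c("location", "year", "age_start", "sex"))
  rem_mean <- pmax(env_mean - rowMeans(tot_cancer$draws), env_mean * 0.05)
  rem_draws <- with_rng(derive_seed(config$seed, "remainder"), {
    rem_mean * exp(matrix(stats::rnorm(length(rem_mean) * config$n_draws,
                                       0, 0.02),
                          length(rem_mean), config$n_draws))
  })
  rem_grid <- data.table::copy(tot_cancer$grid)[, cause := "_non_cancer"]
  ae <- grid[, .(age_start, age_end)][!duplicated(age_start)]
  rem_grid <- merge(rem_grid, ae, by = "age_start", sort = FALSE)
  all_cause <- draw_surface(
    rbind(mort$grid, rem_grid[, names(mort$grid), with = FALSE]),
    rbind(mort$draws, rem_draws))
  scaled <- scale_to_envelope(all_cause, env)
  keep <- scaled$grid$cause != "_non_cancer"
  mort <- draw_surface(scaled$grid[keep], scaled$draws[keep, , drop = FALSE])
  rm(all_cause, scaled, rem_draws, mort_draws)

  say("stage 5/6: incidence, survival, prevalence, YLDs")
  mir_aligned <- draw_surface(mort$grid, mir_surf$draws)
  inc <- incidence_from_mortality(mort, mir_aligned)
  bg <- env_mean / popg[env$grid, population,
                        on = c("location", "year", "age_start", "sex")]
  bg_cells <- bg[match(mort$grid[, paste(location, year, age_start, sex)],
                       env$grid[, paste(location, year, age_start, sex)])]
  surv <- survival_matrix(mort$grid, surface_mean(mir_aligned),
                          frontier_survival(), cap = wcfg$mir_cap)
  prev <- ten_year_prevalence(inc, surv, bg_cells)
  yld <- sequela_yld_draws(prev, mort, inc, sequela_params())
  proc <- procedure_yld_means(inc, prev, surv, bg_cells, procedure_params())
  yld <- draw_surface(yld$grid, yld$draws + proc)

  say("stage 6/6: burden metrics and report")
  yll <- compute_ylls(mort, life_table)
  daly <- compute_dalys(yll, yld)
  sdi_panel <- world$sdi_components[
    , .(location, year, sdi = compute_sdi(income, edu, fert_u25))]
  report <- burden_report(
    list(deaths = mort, incidence = inc, yll = yll, yld = yld, daly = daly),
    world$population, std, sdi_panel = sdi_panel,
    exclude_causes = config$exclude_causes,
    change_years = config$change_years)

  result <- structure(list(world = world, mir = mir_surf, mortality = mort,
                           incidence = inc, yll = yll, yld = yld,
                           daly = daly, report = report, validation = val,
                           mir_observations = obs,
                           ensemble_info = ens_info),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(result, config)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result: %d cells x %d draws; report with %d rows>\n",
    nrow(x$mortality$draws), ncol(x$mortality$draws),
    nrow(x$report$estimates)))
  invisible(x)
}

# write stage CSVs and a manifest with file hashes and the master seed
write_pipeline_artifacts <- function(result, config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- c(mir_surface = "mir_surface.csv",
             burden_estimates = "burden_report.csv",
             burden_changes = "burden_changes.csv",
             ranking = "ranking.csv")
  data.table::fwrite(
    data.table::data.table(result$mir$grid,
                           mir_mean = surface_mean(result$mir)),
    file.path(out, files["mir_surface"]))
  data.table::fwrite(result$report$estimates,
                     file.path(out, files["burden_estimates"]))
  data.table::fwrite(result$report$changes,
                     file.path(out, files["burden_changes"]))
  data.table::fwrite(result$report$ranking, file.path(out, files["ranking"]))
  manifest <- data.table::data.table(
    stage = names(files), file = unname(files),
    md5 = unname(tools::md5sum(file.path(out, files))),
    seed = config$seed)
  data.table::fwrite(manifest, file.path(out, "manifest.csv"))
  invisible(manifest)
}
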
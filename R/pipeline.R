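#' Pipeline configuration
#'
#' Bundles the stage configurations and propagates the master seed and draw
#' count consistently into every stage (a single draw count runs end to
#' end). Per-stage child seeds are derived deterministically from the master
#' seed so single-stage re-runs reproduce full-pipeline results.
#'
#' @param world a [world_config()]
#' @param mir an [stgpr_config()]
#' @param ensemble an [ensemble_config()]
#' @param n_draws draw count used by every stage
#' @param seed master seed
#' @param out_dir optional output directory for stage artifacts and the
#'   manifest; `NULL` keeps everything in memory
#' @param exclude_causes causes dropped from totals and rankings (eg a
#'   high-incidence low-mortality group reported separately)
#' @param change_years the (start, end) years for percent changes and
#'   annualized rates of change
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(world = world_config(),
                            mir = stgpr_config(),
                            ensemble = ensemble_config(),
                            n_draws = 1000,
                            seed = 1L,
                            out_dir = NULL,
                            exclude_causes = character(),
                            change_years = c(2010, 2019)) {
  stopifnot(n_draws >= 100, length(change_years) == 2,
            change_years[1] < change_years[2])
  world$seed <- as.integer(seed)
  mir$n_draws <- as.integer(n_draws)
  mir$seed <- derive_seed(seed, "mir_draws")
  mir$mir_cap <- world$mir_cap
  ensemble$n_draws <- as.integer(n_draws)
  ensemble$seed <- derive_seed(seed, "ensemble")
  structure(list(world = world, mir = mir, ensemble = ensemble,
                 n_draws = as.integer(n_draws), seed = as.integer(seed),
                 out_dir = out_dir, exclude_causes = exclude_causes,
                 change_years = change_years),
            class = "pipeline_config")
}

#' Validate pipeline input tables
#'
#' Schema, bounds and key-uniqueness checks on the observation tables. Fatal
#' issues (missing columns, negative counts, duplicated demographic keys)
#' are enumerated with row coordinates; non-fatal issues are listed as
#' warnings.
#'
#' @param tables named list with any of `registry`, `vr`, `population`,
#'   `covariates`
#' @return list: `fatal` (character), `warnings` (character)
#' @export
validate_inputs <- function(tables) {
  fatal <- character()
  warns <- character()
  need <- list(
    registry = c("location", "year", "age_start", "sex", "cause", "cases",
                 "person_years"),
    vr = c("location", "year", "age_start", "sex", "icd_code", "deaths"),
    population = c("location", "year", "age_start", "sex", "population"),
    covariates = c("location", "year", "haq"))
  counts <- c(registry = "cases", vr = "deaths", population = "population")
  for (nm in names(tables)) {
    t <- data.table::as.data.table(tables[[nm]])
    req <- need[[nm]]
    if (is.null(req)) next
    miss <- setdiff(req, names(t))
    if (length(miss)) {
      fatal <- c(fatal, sprintf("%s: missing column(s) %s", nm,
                                paste(miss, collapse = ", ")))
      next
    }
    cc <- if (nm %in% names(counts)) counts[[nm]] else NA_character_
    if (!is.na(cc)) {
      bad <- which(t[[cc]] < 0)
      if (length(bad)) {
        fatal <- c(fatal, sprintf("%s: negative %s at row(s) %s", nm, cc,
                                  paste(utils::head(bad, 5), collapse = ", ")))
      }
    }
    keys <- intersect(c("location", "year", "age_start", "sex", "cause",
                        "icd_code"), names(t))
    dup <- duplicated(t, by = keys)
    if (any(dup)) {
      fatal <- c(fatal, sprintf("%s: duplicated demographic key at row(s) %s",
                                nm, paste(utils::head(which(dup), 5),
                                          collapse = ", ")))
    }
    if ("haq" %in% names(t) && any(t$haq < 0 | t$haq > 100)) {
      warns <- c(warns, sprintf("%s: haq outside [0,100]", nm))
    }
  }
  list(fatal = fatal, warnings = warns)
}

# draw-level aggregation: sum draw rows over groups of the given columns,
# in first-occurrence order; returns list(grid, draws)
agg_draws <- function(grid, draws, by) {
  id <- do.call(paste, c(grid[, by, with = FALSE], sep = "\r"))
  first <- !duplicated(id)
  key <- match(id, id[first])
  s <- rowsum(draws, group = key, reorder = TRUE)
  list(grid = grid[first, by, with = FALSE], draws = s)
}

# summarize a draw matrix into mean/lower/upper columns
ui_summary <- function(draws) {
  q <- t(apply(draws, 1, stats::quantile, probs = c(0.025, 0.975),
               type = 7, names = FALSE))
  data.table::data.table(mean = rowMeans(draws), lower = q[, 1],
                         upper = q[, 2])
}

# expand an age-retaining (cause, year, sex, age) block with an all-cause
# "total" (minus excluded causes) and a both-sex aggregate; pop is a vector
expand_block <- function(grid, draws, pop, exclude_causes) {
  keep <- !grid$cause %in% exclude_causes
  tot <- agg_draws(grid[keep], draws[keep, , drop = FALSE],
                   c("year", "sex", "age_start"))
  cz1 <- grid$cause[keep][1]
  sel1 <- keep & grid$cause == cz1
  tot_pop <- agg_draws(grid[sel1], matrix(pop[sel1], ncol = 1),
                       c("year", "sex", "age_start"))$draws[, 1]
  g <- rbind(grid, tot$grid[, cause := "total"][, names(grid), with = FALSE])
  d <- rbind(draws, tot$draws)
  p <- c(pop, tot_pop)
  bo <- agg_draws(g, d, c("cause", "year", "age_start"))
  bo_pop <- agg_draws(g, matrix(p, ncol = 1),
                      c("cause", "year", "age_start"))$draws[, 1]
  g <- rbind(g, bo$grid[, sex := "both"][, names(g), with = FALSE])
  list(grid = g, draws = rbind(d, bo$draws), pop = c(p, bo_pop))
}

#' Assemble the burden report from measure surfaces
#'
#' Aggregates draw surfaces of deaths, incident cases, YLLs, YLDs and DALYs
#' to cause x location x year x sex summaries - including both-sex rows, an
#' all-cause "total" (minus any excluded causes), a "global" aggregate and
#' SDI-quintile aggregates - and reports counts, crude rates and
#' age-standardized rates (ASR, per 100 000 person-years) with 95%
#' uncertainty intervals. ASRs at every level use the level's own pooled
#' age-specific rates against the standard population weights. Draw-level
#' percent changes and annualized rates of change between the change years,
#' a DALY ranking of cancer groups, and global YLL/YLD shares complete the
#' report.
#'
#' @param surfaces named list of aligned `draw_surface`s: `deaths`,
#'   `incidence`, `yll`, `yld`, `daly`
#' @param population population table (location, year, age_start, sex,
#'   population)
#' @param std standard population (age_start, weight)
#' @param sdi_panel optional (location, year, sdi) panel; adds quintile
#'   aggregates
#' @param exclude_causes causes excluded from "total" and rankings
#' @param change_years (start, end) for changes
#' @return list of class `burden_report`: `estimates` (long table),
#'   `changes`, `ranking`, `shares`
#' @export
burden_report <- function(surfaces, population, std, sdi_panel = NULL,
                          exclude_causes = character(),
                          change_years = c(2010, 2019)) {
  stopifnot(all(c("deaths", "incidence", "yll", "yld", "daly") %in%
                  names(surfaces)))
  pop <- data.table::as.data.table(population)
  std <- data.table::as.data.table(std)
  wstd <- std$weight / sum(std$weight)
  names(wstd) <- as.character(std$age_start)

  g0 <- surfaces$deaths$grid
  for (s in surfaces) assert_aligned(surfaces$deaths, s)
  popv <- pop[g0, population, on = c("location", "year", "age_start", "sex")]
  if (anyNA(popv)) stop("population does not cover the grid", call. = FALSE)

  levels_ <- as.list(setNames(unique(g0$location), unique(g0$location)))
  levels_$global <- unique(g0$location)
  if (!is.null(sdi_panel)) {
    qp <- assign_sdi_quintiles(sdi_panel, ref_year = max(sdi_panel$year))
    quint <- unique(qp[, .(location, quintile)])
    for (q in levels(quint$quintile)) {
      locs <- quint$location[quint$quintile == q]
      if (length(locs)) levels_[[paste0("sdi_", q)]] <- locs
    }
  }

  est <- list()
  chg <- list()
  store <- list()  # end/start-year draw matrices for changes/ranks/shares
  for (ms in names(surfaces)) {
    s <- surfaces[[ms]]
    for (lv in names(levels_)) {
      sel <- s$grid$location %in% levels_[[lv]]
      a <- agg_draws(s$grid[sel], s$draws[sel, , drop = FALSE],
                     c("cause", "year", "sex", "age_start"))
      p <- agg_draws(s$grid[sel], matrix(popv[sel], ncol = 1),
                     c("cause", "year", "sex", "age_start"))$draws[, 1]
      ex <- expand_block(a$grid, a$draws, p, exclude_causes)
      # collapse ages: counts, crude rates, ASR
      cnt <- agg_draws(ex$grid, ex$draws, c("cause", "year", "sex"))
      pp <- agg_draws(ex$grid, matrix(ex$pop, ncol = 1),
                      c("cause", "year", "sex"))$draws[, 1]
      wa <- wstd[as.character(ex$grid$age_start)] / ex$pop * 1e5
      asr <- agg_draws(ex$grid, ex$draws * wa, c("cause", "year", "sex"))
      tab <- data.table::copy(cnt$grid)
      tab[, `:=`(location = lv, measure = ms)]
      est[[paste(ms, lv)]] <- rbind(
        cbind(tab, metric = "count", ui_summary(cnt$draws)),
        cbind(tab, metric = "crude_rate", ui_summary(cnt$draws / pp * 1e5)),
        cbind(tab, metric = "asr", ui_summary(asr$draws)))

      yr_sel <- cnt$grid$year %in% change_years
      store[[paste(ms, lv)]] <- list(
        grid = data.table::copy(cnt$grid[yr_sel]),
        count = cnt$draws[yr_sel, , drop = FALSE],
        asr = asr$draws[yr_sel, , drop = FALSE])

      # draw-level changes
      sg <- store[[paste(ms, lv)]]
      i0 <- which(sg$grid$year == change_years[1])
      i1 <- which(sg$grid$year == change_years[2])
      k <- sg$grid[, paste(cause, sex)]
      m <- match(k[i0], k[i1])
      for (metric in c("count", "asr")) {
        v0 <- sg[[metric]][i0, , drop = FALSE]
        v1 <- sg[[metric]][i1[m], , drop = FALSE]
        ok <- rowSums(v0 <= 0) == 0 & rowSums(v1 <= 0) == 0
        if (!any(ok)) next
        pc <- percent_change(v0[ok, , drop = FALSE], v1[ok, , drop = FALSE])
        arc <- annualized_rate_of_change(v0[ok, , drop = FALSE],
                                         v1[ok, , drop = FALSE],
                                         change_years[1], change_years[2])
        cg <- sg$grid[i0][ok, .(cause, sex)]
        cg[, `:=`(location = lv, measure = ms, metric = metric)]
        chg[[paste(ms, lv, metric)]] <- cbind(
          cg,
          stats::setNames(ui_summary(pc),
                          c("pct_mean", "pct_lower", "pct_upper")),
          stats::setNames(ui_summary(arc),
                          c("arc_mean", "arc_lower", "arc_upper")))
      }
    }
  }
  estimates <- data.table::rbindlist(est, use.names = TRUE)
  data.table::setcolorder(estimates, c("measure", "metric", "cause",
                                       "location", "year", "sex"))
  changes <- data.table::rbindlist(chg, use.names = TRUE)

  # ranking: global both-sex DALY counts in the end year
  sg <- store[["daly global"]]
  i <- which(sg$grid$sex == "both" & sg$grid$year == change_years[2] &
               sg$grid$cause != "total")
  counts <- rowMeans(sg$count[i, , drop = FALSE])
  names(counts) <- sg$grid$cause[i]
  ranking <- rank_cancer_groups(counts, exclude = exclude_causes)

  # global YLL/YLD shares of total DALYs in the end year
  gy <- function(ms) {
    sg <- store[[paste(ms, "global")]]
    i <- which(sg$grid$sex == "both" & sg$grid$year == change_years[2] &
                 sg$grid$cause == "total")
    sg$count[i, ]
  }
  shares <- yll_yld_shares(gy("yll"), gy("yld"))

  structure(list(estimates = estimates[], changes = changes[],
                 ranking = ranking, shares = shares),
            class = "burden_report")
}

#' @export
print.burden_report <- function(x, ...) {
  cat(sprintf(
    "<burden_report: %d estimate rows, %d change rows, %d ranked causes>\n",
    nrow(x$estimates), nrow(x$changes), nrow(x$ranking)))
  invisible(x)
}
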
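#' Configuration for the mortality ensemble
#'
#' @param covariate_pool predictive covariates available to submodels; any
#'   of `"haq"`, `"sdi"`, `"year"` (linear trend). Age-group effects are
#'   structural: every submodel carries them (an "intercept-only" submodel
#'   is an age pattern with no covariates)
#' @param max_subset_size largest covariate subset enumerated
#' @param n_folds holdout folds for out-of-sample validity (>= 2)
#' @param holdout_frac fraction of location-years held out per fold
#' @param tau softmax temperature override; `NULL` uses the minimum
#'   out-of-sample RMSE (self-scaling)
#' @param n_draws ensemble draws
#' @param pseudo_variance_inflation variance inflation applied to
#'   MIR-converted registry pseudo-death observations (their regression
#'   weight is `1 / inflation`)
#' @param envelope_multiplier synthetic all-cause envelope as a multiple of
#'   total cancer deaths
#' @param asr_weights optional named age weights (names = age_start) used
#'   when scoring held-out location-years by age-standardized rate;
#'   `NULL` weighs age groups uniformly
#' @param seed seed for fold assignment and draw sampling
#' @return an `ensemble_config` list
#' @export
ensemble_config <- function(covariate_pool = c("haq", "year"),
                            max_subset_size = 3,
                            n_folds = 5,
                            holdout_frac = 0.2,
                            tau = NULL,
                            n_draws = 1000,
                            pseudo_variance_inflation = 2,
                            envelope_multiplier = 6,
                            asr_weights = NULL,
                            seed = 1L) {
  stopifnot(n_folds >= 2, holdout_frac > 0, holdout_frac < 1,
            n_draws >= 1, pseudo_variance_inflation >= 1,
            envelope_multiplier >= 1)
  structure(list(covariate_pool = covariate_pool,
                 max_subset_size = max_subset_size, n_folds = n_folds,
                 holdout_frac = holdout_frac, tau = tau,
                 n_draws = as.integer(n_draws),
                 pseudo_variance_inflation = pseudo_variance_inflation,
                 envelope_multiplier = envelope_multiplier,
                 asr_weights = asr_weights,
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Enumerate ensemble submodels
#'
#' Both response spaces (log death rate; logit cause fraction of the
#' all-cause envelope) crossed with every non-empty covariate subset up to
#' `max_size`, plus the intercept-only model in each space, in a fixed
#' deterministic order (by space, then subset size, then lexicographically).
#'
#' @param pool covariate pool (character)
#' @param max_size largest subset size
#' @return list of submodel specs: `list(space, covariates)`
#' @export
#' @examples
#' length(enumerate_submodels("haq", 1))  # 4: 2 spaces x {intercept, haq}
enumerate_submodels <- function(pool, max_size = length(pool)) {
  pool <- sort(unique(pool))
  subsets <- list(character(0))
  if (length(pool)) {
    for (k in seq_len(min(max_size, length(pool)))) {
      cmb <- utils::combn(pool, k, simplify = FALSE)
      subsets <- c(subsets, cmb[order(vapply(cmb, paste, "",
                                             collapse = "|"))])
    }
  }
  specs <- list()
  for (space in c("log_rate", "logit_fraction")) {
    for (s in subsets) {
      specs[[length(specs) + 1]] <- list(space = space, covariates = s)
    }
  }
  specs
}

# submodel design formula: age-group effects are structural in every
# submodel; the spec's covariate subset adds predictive covariates
submodel_formula <- function(spec) {
  terms <- c("age_f",
             if ("haq" %in% spec$covariates) "haq",
             if ("sdi" %in% spec$covariates) "sdi",
             if ("year" %in% spec$covariates) "year_c")
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

# prepare a modeling frame: covariates plus the pieces each response space
# needs. d carries deaths, population, envelope_rate (all-cause deaths per
# 100k), haq, sdi, year, age_start, weight
submodel_frame <- function(d, spec, age_levels) {
  f <- data.table::copy(data.table::as.data.table(d))
  f[, age_f := factor(age_start, levels = age_levels)]
  f[, year_c := year - min(year)]
  f[, log_off := log(population / 1e5)]
  f[, env_deaths := pmax(envelope_rate * population / 1e5, 1e-6)]
  if ("deaths" %in% names(f)) f[, frac := pmin(pmax(deaths / env_deaths, 0), 1)]
  f
}

# fit one submodel: quasi-Poisson count regression with a population offset
# (log death rate space) or quasi-binomial cause fraction of the all-cause
# envelope (logit fraction space); both handle zero-death cells without the
# bias of log(count + c) least squares. A small continuity count (0.01 per
# cell, fit only) prevents quasi-complete separation when an entire age
# group has zero deaths, which would otherwise send that coefficient's
# sampling variance to infinity.
submodel_fit <- function(fr, spec) {
  rhs <- paste(deparse(submodel_formula(spec)[[3]]), collapse = "")
  fr <- data.table::copy(fr)
  fr[, deaths_fit := deaths + 0.01]
  if (spec$space == "log_rate") {
    form <- stats::as.formula(paste("deaths_fit ~", rhs, "+ offset(log_off)"))
    suppressWarnings(stats::glm(form, family = stats::quasipoisson(),
                                data = fr, weights = weight))
  } else {
    form <- stats::as.formula(paste("frac_fit ~", rhs))
    fr[, frac_fit := pmin(pmax(deaths_fit / env_deaths, 0), 1)]
    fr[, wbin := weight * env_deaths]
    suppressWarnings(stats::glm(form, family = stats::quasibinomial(),
                                data = fr, weights = wbin))
  }
}

# predicted death rate per 100k from a fitted submodel on new data
submodel_predict <- function(fit, spec, newdata, age_levels) {
  nd <- submodel_frame(newdata, spec, age_levels)
  mu <- as.numeric(stats::predict(fit, newdata = nd, type = "response"))
  if (spec$space == "log_rate") mu / nd$population * 1e5
  else mu * nd$envelope_rate
}

#' Out-of-sample predictive-validity weights
#'
#' Splits location-years into seeded holdout folds, fits every submodel on
#' each training partition, and scores it on the held-out location-years by
#' root-mean-square error of the log age-standardized death rate
#' (standard-population age weights when the configuration carries them,
#' uniform otherwise; 0.5-per-100k continuity constant on both sides). Scoring
#' the standardized rate rather than raw cells aggregates away cell-level
#' count noise — which would otherwise compress the skill differences
#' between submodels — and directly penalizes misallocating deaths across
#' age groups, the failure mode that matters for the reported
#' age-standardized estimates. Weights are a softmax on negative RMSE,
#' `w_i` proportional to `exp(-rmse_i / tau)` with temperature `tau` equal
#' to the smallest RMSE (unless overridden). A submodel that fails to fit
#' gets weight 0.
#'
#' @param submodels list from [enumerate_submodels()]
#' @param data modeling table (deaths, population, envelope_rate, haq, sdi,
#'   year, age_start, weight)
#' @param config an [ensemble_config()]
#' @return list: `weights` (sums to 1), `oos_rmse`, `folds`
#' @export
oos_validity_weights <- function(submodels, data, config = ensemble_config()) {
  d <- data.table::as.data.table(data)
  if (!"weight" %in% names(d)) d[, weight := 1]
  age_levels <- sort(unique(d$age_start))
  ly <- unique(d[, .(location, year)])
  folds <- with_rng(derive_seed(config$seed, "folds"), {
    sample(rep(seq_len(config$n_folds), length.out = nrow(ly)))
  })
  ly[, fold := folds]
  d <- merge(d, ly, by = c("location", "year"), sort = FALSE)
  rmse <- vapply(submodels, function(spec) {
    errs <- unlist(lapply(seq_len(config$n_folds), function(k) {
      train <- d[fold != k]
      test <- data.table::copy(d[fold == k])
      if (!nrow(test)) return(numeric(0))
      fr <- submodel_frame(train, spec, age_levels)
      fit <- tryCatch(submodel_fit(fr, spec), error = function(e) NULL)
      if (is.null(fit)) return(NA_real_)
      pred <- tryCatch(submodel_predict(fit, spec, test, age_levels),
                       error = function(e) rep(NA_real_, nrow(test)))
      if (anyNA(pred)) return(NA_real_)
      test[, pred_rate := pmax(pred, 0)]
      test[, obs_rate := deaths / population * 1e5]
      wv <- if (is.null(config$asr_weights)) {
        stats::setNames(rep(1, length(age_levels)),
                        as.character(age_levels))
      } else config$asr_weights
      test[, wa := wv[as.character(age_start)]]
      asr <- test[, .(pa = sum(wa * pred_rate) / sum(wa),
                      oa = sum(wa * obs_rate) / sum(wa)),
                  by = .(location, year)]
      log(asr$pa + 0.5) - log(asr$oa + 0.5)
    }))
    if (anyNA(errs)) NA_real_ else sqrt(mean(errs^2))
  }, numeric(1))
  ok <- is.finite(rmse)
  if (!any(ok)) stop("no submodel could be fitted", call. = FALSE)
  tau <- if (is.null(config$tau)) min(rmse[ok]) else config$tau
  tau <- max(tau, 1e-8)
  w <- numeric(length(submodels))
  w[ok] <- exp(-rmse[ok] / tau)
  w <- w / sum(w)
  list(weights = w, oos_rmse = rmse, folds = ly[])
}

#' Largest-remainder apportionment of draws to submodels
#'
#' @param weights non-negative weights summing to 1
#' @param n total number of draws
#' @return integer slots summing exactly to `n`
#' @export
#' @examples
#' apportion_draws(c(0.731, 0.269), 1000)  # 731, 269
apportion_draws <- function(weights, n) {
  stopifnot(abs(sum(weights) - 1) < 1e-9, all(weights >= 0))
  quota <- weights * n
  slots <- floor(quota)
  rem <- n - sum(slots)
  if (rem > 0) {
    extra <- order(quota - slots, decreasing = TRUE)[seq_len(rem)]
    slots[extra] <- slots[extra] + 1
  }
  as.integer(slots)
}

#' Ensemble mortality draws
#'
#' Allocates the draw budget across submodels by largest-remainder
#' apportionment of `n_draws x weight`, refits each contributing submodel on
#' the full data, and fills its slots with parametric-uncertainty samples:
#' regression coefficients drawn from their estimated sampling distribution
#' (multivariate normal around the fit), pushed through the response-space
#' inverse link, times population. Returns predicted deaths per cell.
#'
#' When the out-of-sample RMSEs are supplied, the draw spread is calibrated
#' to them: parametric coefficient uncertainty understates predictive error
#' whenever the submodels share a structural misfit, so the draws are
#' widened multiplicatively (about their cell means, mean-preserving) until
#' the ensemble's internal spread of the log age-standardized rate per
#' location-year matches the weighted out-of-sample error — uncertainty
#' anchored to measured predictive validity rather than to in-sample
#' algebra.
#'
#' @param submodels list from [enumerate_submodels()]
#' @param weights ensemble weights (sum to 1)
#' @param data full modeling table (see [oos_validity_weights()])
#' @param grid prediction grid with covariates (population, envelope_rate,
#'   haq, sdi, year, age_start)
#' @param config an [ensemble_config()]
#' @param oos_rmse optional per-submodel out-of-sample RMSEs from
#'   [oos_validity_weights()]; enables uncertainty calibration
#' @return a `draw_surface` of deaths on `grid`
#' @export
ensemble_draws <- function(submodels, weights, data, grid,
                           config = ensemble_config(), oos_rmse = NULL) {
  d <- data.table::as.data.table(data)
  if (!"weight" %in% names(d)) d[, weight := 1]
  g <- data.table::as.data.table(grid)
  age_levels <- sort(unique(c(d$age_start, g$age_start)))
  slots <- apportion_draws(weights, config$n_draws)
  draws <- matrix(NA_real_, nrow(g), config$n_draws)
  col <- 1L
  with_rng(derive_seed(config$seed, "ensemble_draws"), {
    for (i in seq_along(submodels)) {
      if (slots[i] == 0) next
      spec <- submodels[[i]]
      fr <- submodel_frame(d, spec, age_levels)
      fit <- submodel_fit(fr, spec)
      nd <- submodel_frame(g[, setdiff(names(g), "deaths"), with = FALSE],
                           spec, age_levels)
      X <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                               data = nd)
      cf <- stats::coef(fit)
      keep <- !is.na(cf)
      V <- stats::vcov(fit)  # aliased coefficients already dropped
      B <- MASS::mvrnorm(slots[i], cf[keep], V)
      if (slots[i] == 1) B <- matrix(B, nrow = 1)
      eta <- X[, keep, drop = FALSE] %*% t(B)
      rate <- if (spec$space == "log_rate") {
        # draws are lognormal in the rate; recenter by half the predictive
        # log-variance so the draw mean matches the fitted prediction
        # rather than exp(se^2/2) times it
        v <- rowSums((X[, keep, drop = FALSE] %*% t(chol(V)))^2)
        exp(eta - v / 2)
      } else {
        1 / (1 + exp(-eta)) * nd$envelope_rate
      }
      # a single cause cannot exceed all-cause mortality
      rate <- pmin(rate, nd$envelope_rate)
      draws[, col:(col + slots[i] - 1L)] <- rate * g$population / 1e5
      col <- col + slots[i]
    }
  })
  out <- draw_surface(g[, intersect(c("cause", "location", "year",
                                      "age_start", "age_end", "sex"),
                                    names(g)), with = FALSE], draws)
  if (!is.null(oos_rmse)) {
    ok <- is.finite(oos_rmse) & weights > 0
    if (any(ok)) {
      rmse_w <- sqrt(sum(weights[ok] * oos_rmse[ok]^2) / sum(weights[ok]))
      out <- calibrate_draw_spread(out, g$population, rmse_w, config)
    }
  }
  out
}

# widen draw spread (mean-preserving, multiplicative) until the internal
# spread of log age-standardized rate per location-year matches the
# out-of-sample error
calibrate_draw_spread <- function(ds, population, rmse_target, config) {
  g <- ds$grid
  ages <- sort(unique(g$age_start))
  wv <- config$asr_weights
  if (is.null(wv)) wv <- stats::setNames(rep(1, length(ages)),
                                         as.character(ages))
  wa <- wv[as.character(g$age_start)]
  wa <- wa / sum(wv[as.character(ages)])
  key <- g[, paste(location, year)]
  asr <- rowsum(ds$draws * (wa / population * 1e5), key)
  # ensemble draws are right-skewed (mixtures of log-linked submodels), so
  # calibrate the weaker lower tail: its reach from the median, expressed
  # as a normal-equivalent sd, must match the out-of-sample error
  lq <- t(apply(log(pmax(asr, 1e-8)), 1, stats::quantile,
                probs = c(0.025, 0.5), names = FALSE))
  reach <- (lq[, 2] - lq[, 1]) / stats::qnorm(0.975)
  s_int <- stats::median(reach[is.finite(reach) & reach > 0])
  if (!is.finite(s_int) || s_int <= 0) return(ds)
  k <- min(max(1, rmse_target / s_int), 50)
  if (k == 1) return(ds)
  m <- rowMeans(ds$draws)
  pos <- m > 0
  ratio <- ds$draws[pos, , drop = FALSE] / m[pos]
  widened <- ratio^k
  widened <- widened / rowMeans(widened) * m[pos]
  draws <- ds$draws
  draws[pos, ] <- widened
  out <- draw_surface(g, draws)
  attr(out, "spread_calibration") <- k
  out
}

#' Synthetic all-cause mortality envelope
#'
#' All-cause deaths per demographic cell: the world's total true cancer
#' deaths times a multiplier (cancer being a minority of all deaths) plus a
#' Gompertz-shaped non-cancer background, with mild lognormal draw-level
#' noise so envelope uncertainty propagates. The background term keeps the
#' envelope positive and realistic in young age groups where cancer
#' mortality is negligible (a bare multiple of cancer deaths would vanish
#' there, and an all-cause envelope never does).
#'
#' @param world a `true_world`
#' @param n_draws draw count
#' @param multiplier all-cause / cancer death ratio (default 6)
#' @param cv lognormal coefficient of variation of the envelope draws
#' @param seed seed
#' @return a `draw_surface` of all-cause deaths on the no-cause grid
#' @export
synthetic_envelope <- function(world, n_draws, multiplier = 6, cv = 0.02,
                               seed = 1L) {
  tot <- merge(world$rates, world$population,
               by = c("location", "year", "age_start", "age_end", "sex"))
  tot <- tot[, .(deaths = sum(true_mortality_rate * population / 1e5),
                 population = population[1]),
             by = .(location, year, age_start, age_end, sex)]
  data.table::setorderv(tot, c("location", "year", "age_start", "sex"))
  mid <- ifelse(is.finite(tot$age_end), (tot$age_start + tot$age_end) / 2,
                tot$age_start + 5)
  base_rate <- 80 * exp(0.045 * mid)  # non-cancer background per 100k
  mu <- tot$deaths * multiplier + tot$population * base_rate / 1e5
  dr <- with_rng(derive_seed(seed, "envelope"), {
    mu * exp(matrix(stats::rnorm(length(mu) * n_draws, -cv^2 / 2, cv),
                    length(mu), n_draws))
  })
  draw_surface(tot[, .(location, year, age_start, age_end, sex)], dr)
}

#' Scale cause-specific death draws to the all-cause envelope
#'
#' Per demographic cell and per draw, every cause is multiplied by
#' `envelope / sum(causes)`, so after scaling the causes sum to the envelope
#' exactly, draw by draw. Cells where the cause total is zero against a
#' positive envelope cannot be scaled; they are left unscaled and reported
#' in the `"unscaled_cells"` attribute.
#'
#' @param cause_draws `draw_surface` with a `cause` grid column
#' @param envelope `draw_surface` of all-cause deaths on the matching
#'   no-cause grid
#' @return the scaled `draw_surface`
#' @export
scale_to_envelope <- function(cause_draws, envelope) {
  gk <- c("location", "year", "age_start", "sex")
  stopifnot(all(gk %in% names(cause_draws$grid)),
            ncol(cause_draws$draws) == ncol(envelope$draws))
  if (any(envelope$draws <= 0)) {
    stop("envelope must be positive everywhere", call. = FALSE)
  }
  idx <- envelope$grid[, ..gk][, cell_id := .I]
  m <- merge(cause_draws$grid[, ..gk][, row := .I], idx, by = gk,
             sort = FALSE)
  data.table::setorderv(m, "row")
  env_of <- m$cell_id
  sums <- rowsum(cause_draws$draws, group = env_of, reorder = TRUE)
  env <- envelope$draws[sort(unique(env_of)), , drop = FALSE]
  factor_m <- env / sums
  zero <- sums == 0
  flagged <- which(zero & env > 0, arr.ind = TRUE)
  factor_m[zero] <- 1
  scaled <- cause_draws$draws *
    factor_m[match(env_of, sort(unique(env_of))), , drop = FALSE]
  out <- draw_surface(cause_draws$grid, scaled)
  attr(out, "unscaled_cells") <- flagged
  out
}
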
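#' Configuration for the three-stage MIR smoother
#'
#' Hyperparameters of the space-time Gaussian process regression used to turn
#' sparse, noisy MIR observations into a complete surface: a squared
#' exponential kernel over years, a space-time residual-averaging stage with
#' a time-decay exponent and a cross-location pooling weight, and a posterior
#' draw count.
#'
#' @param kernel_length_scale GP kernel length scale, in years (> 0)
#' @param kernel_amplitude GP kernel amplitude, in logit units (> 0)
#' @param time_window_decay lambda in (0,1\]: exponent of the linear time
#'   decay used when averaging residuals; larger values decay faster
#' @param location_pool_weight zeta in \[0,1\]: weight given to residuals
#'   observed in other locations (1 = full pooling, 0 = none)
#' @param n_draws posterior draws per cell (>= 100, default 1000)
#' @param age_smoothing apply a moving-average pass across adjacent age
#'   groups in logit space after the GP stage?
#' @param mir_cap upper bound of the MIR scale
#' @param seed seed for posterior draw sampling
#' @return an `stgpr_config` list
#' @export
stgpr_config <- function(kernel_length_scale = 6,
                         kernel_amplitude = 0.4,
                         time_window_decay = 0.7,
                         location_pool_weight = 0.3,
                         n_draws = 1000,
                         age_smoothing = TRUE,
                         mir_cap = 1.0,
                         seed = 1L) {
  stopifnot(kernel_length_scale > 0, kernel_amplitude > 0,
            time_window_decay > 0, time_window_decay <= 1,
            location_pool_weight >= 0, location_pool_weight <= 1,
            n_draws >= 100, mir_cap > 0)
  structure(list(kernel_length_scale = kernel_length_scale,
                 kernel_amplitude = kernel_amplitude,
                 time_window_decay = time_window_decay,
                 location_pool_weight = location_pool_weight,
                 n_draws = as.integer(n_draws),
                 age_smoothing = isTRUE(age_smoothing),
                 mir_cap = mir_cap,
                 seed = as.integer(seed)),
            class = "stgpr_config")
}

#' Stage 1: linear covariate prior for MIR in logit space
#'
#' Fits, per cancer-sex, `logit(mir) ~ age-group effects + beta x HAQ +
#' year trend` by
#' weighted least squares (binomial information weights
#' `ess x p x (1 - p)`, so near-boundary ratios from thin cells carry the
#' little information they actually hold) and predicts on the full grid. If
#' HAQ is constant (or any term collinear) the offending term is dropped
#' with a warning and the prior reduces to an age pattern. The fitted
#' coefficients are attached as the `"coefficients"` attribute so covariate
#' effects (notably the sign of the HAQ slope) can be inspected.
#'
#' @param observations MIR observation table from [build_mir_observations()]
#' @param haq covariate table (location, year, haq) on the full grid
#' @param grid full cause demographic grid to predict on
#' @param cap MIR cap used for the logit transform
#' @return the grid with a `prior_logit` column; attribute `"coefficients"`
#' @export
fit_prior <- function(observations, haq, grid, cap = 1) {
  obs <- merge(data.table::as.data.table(observations), haq,
               by = c("location", "year"), sort = FALSE)
  obs[, value := logit_mir(mir, cap = cap)]
  if (!"ess" %in% names(obs)) obs[, ess := 1]
  obs[, year_c := year - min(year)]
  g <- data.table::copy(data.table::as.data.table(grid))
  g <- merge(g, haq, by = c("location", "year"), sort = FALSE)
  age_levels <- sort(unique(g$age_start))
  ord <- intersect(c("cause", "location", "year", "age_start", "sex"),
                   names(g))
  data.table::setorderv(g, ord)

  coefs <- list()
  g[, prior_logit := NA_real_]
  for (cz in unique(g$cause)) for (sx in unique(g$sex)) {
    o <- obs[cause == cz & sex == sx]
    if (!nrow(o)) {
      o <- obs[cause == cz]  # pool sexes if one sex is unobserved
      if (!nrow(o)) {
        stop(sprintf("no MIR observations for cancer '%s'", cz),
             call. = FALSE)
      }
    }
    o[, age_f := factor(age_start, levels = age_levels)]
    use_haq <- length(unique(o$haq)) > 1
    if (!use_haq) {
      warning(sprintf(
        "HAQ constant for %s/%s: covariate dropped, age-pattern prior only",
        cz, sx), call. = FALSE)
    }
    use_year <- length(unique(o$year_c)) > 1
    rhs <- c("age_f", if (use_haq) "haq", if (use_year) "year_c")
    form <- stats::reformulate(rhs, response = "value")
    # binomial information weights evaluated at fitted, not observed,
    # ratios: weighting by observed p(1-p) correlates weight with noise
    # and biases small-MIR fits upward
    o[, info_w := pmax(ess, 1)]
    fit0 <- stats::lm(form, data = o, weights = info_w)
    ph <- pmin(pmax(1 / (1 + exp(-stats::fitted(fit0))), 1e-3), 1 - 1e-3)
    o[, info_w := pmax(ess, 1) * ph * (1 - ph)]
    fit <- stats::lm(form, data = o, weights = info_w)
    cf <- stats::coef(fit)
    if (anyNA(cf)) {
      warning(sprintf("rank-deficient MIR prior design for %s/%s: %s dropped",
                      cz, sx, paste(names(cf)[is.na(cf)], collapse = ", ")),
              call. = FALSE)
      cf[is.na(cf)] <- 0
    }
    tgt <- g[cause == cz & sex == sx]
    X <- stats::model.matrix(
      ~ age_f + haq + year_c,
      data = data.frame(age_f = factor(tgt$age_start, levels = age_levels),
                        haq = tgt$haq,
                        year_c = tgt$year - min(obs$year)))
    beta <- setNames(numeric(ncol(X)), colnames(X))
    beta[names(cf)] <- cf
    g[cause == cz & sex == sx, prior_logit := as.numeric(X %*% beta)]
    coefs[[paste(cz, sx, sep = "/")]] <- cf
  }
  g[, haq := NULL]
  data.table::setattr(g, "coefficients", coefs)
  g[]
}

#' Stage 2: space-time weighted averaging of logit-scale residuals
#'
#' For every grid cell, the smoothed residual is a normalized weighted
#' average of the observed residuals for the same cancer, age group and sex:
#' time weight `(1 - |dyear| / (window + 1))^lambda` (window = widest
#' observed year gap in the panel) times a location weight of 1 for the same
#' location and `zeta` for any other; an optional `prec` column multiplies
#' the weights with observation precisions so noisy residuals pull less.
#' Cells whose slice carries no observations at all get residual 0 (the
#' prior stands).
#'
#' @param residuals table (cause, location, year, age_start, sex, resid) of
#'   logit-space residuals at observed cells, optionally with `prec`
#' @param grid full cause grid to smooth onto
#' @param config an [stgpr_config()]
#' @return the grid with a `resid_sm` column
#' @export
spacetime_smooth <- function(residuals, grid, config) {
  res <- data.table::as.data.table(residuals)
  stopifnot(all(is.finite(res$resid)))
  g <- data.table::copy(data.table::as.data.table(grid))
  g[, resid_sm := 0]
  if (!nrow(res)) return(g[])
  window <- max(abs(outer(unique(g$year), unique(res$year), "-")))
  lam <- config$time_window_decay
  zeta <- config$location_pool_weight
  slices <- split(seq_len(nrow(res)),
                  res[, paste(cause, age_start, sex)])
  gkey <- g[, paste(cause, age_start, sex)]
  for (nm in names(slices)) {
    o <- res[slices[[nm]]]
    rows <- which(gkey == nm)
    if (!length(rows)) next
    tw <- (1 - abs(outer(g$year[rows], o$year, "-")) / (window + 1))^lam
    lw <- outer(g$location[rows], o$location,
                function(a, b) ifelse(a == b, 1, zeta))
    w <- tw * pmax(lw, 0)
    if ("prec" %in% names(o)) w <- w * rep(o$prec, each = length(rows))
    sw <- rowSums(w)
    val <- as.numeric(w %*% o$resid)
    g[rows, resid_sm := ifelse(sw > 0, val / sw, 0)]
  }
  g[]
}

# squared-exponential kernel matrix over year vectors
se_kernel <- function(t1, t2, amplitude, length_scale) {
  amplitude^2 * exp(-outer(t1, t2, "-")^2 / (2 * length_scale^2))
}

#' Stage 3: Gaussian-process posterior over years with draws
#'
#' Per cancer-location-age-sex series, a 1-D GP over years with a squared
#' exponential kernel is anchored on the stage-1 + stage-2 mean
#' (`prior_logit + resid_sm`) and updated with the logit-scale observations,
#' whose heteroskedastic nugget is the delta-method binomial variance
#' `1 / (ess x p x (1 - p))`. The posterior mean and `n_draws` joint samples
#' per series are inverse-logit transformed and clamped to (0, cap\].
#'
#' @param prior grid with `prior_logit` and `resid_sm` columns (stage 1 + 2)
#' @param observations MIR observation table (mir, ess at observed cells)
#' @param config an [stgpr_config()]
#' @return a `draw_surface` of MIR draws on the full grid (the MIR surface);
#'   attribute `"posterior_logit_mean"` carries the analytic logit-space mean
#' @export
gpr_posterior <- function(prior, observations, config) {
  g <- data.table::copy(data.table::as.data.table(prior))
  if (!"resid_sm" %in% names(g)) g[, resid_sm := 0]
  ord <- intersect(c("cause", "location", "year", "age_start", "sex"),
                   names(g))
  data.table::setorderv(g, ord)
  g[, cell_id := .I]
  cap <- config$mir_cap
  obs <- data.table::as.data.table(observations)
  obs[, value := logit_mir(mir, cap = cap)]
  obs <- merge(obs, g[, c(ord, "cell_id", "prior_logit", "resid_sm"),
                      with = FALSE], by = ord, sort = FALSE)
  # binomial-scale nugget at a compromise ratio: the average of the
  # observed ratio and the stage-1+2 mean, tempering both the noise
  # correlation of a purely observed-ratio variance and the prior
  # dependence of a purely fitted one
  p_fit <- 1 / (1 + exp(-(obs$prior_logit + obs$resid_sm)))
  p <- pmin(pmax((obs$mir / cap + p_fit) / 2, 1e-3), 1 - 1e-3)
  obs[, var := pmax(1 / (pmax(ess, 1) * p * (1 - p)), 1e-6)]
  # registry counts are overdispersed relative to the binomial-scale
  # nugget; estimate a robust per-cancer-sex inflation from standardized
  # residuals against the stage-1 + stage-2 mean (median chi-square(1) is
  # 0.455). When the stage-1+2 mean explains the data at binomial scale
  # the factor stays at 1 and dense observations are interpolated.
  obs[, z2 := (value - prior_logit - resid_sm)^2 / var]
  # at least 10 observations before trusting a dispersion estimate
  obs[, var := var * (if (.N >= 10) max(1, stats::median(z2) / 0.455) else 1),
      by = .(cause, sex)]

  years <- sort(unique(g$year))
  K <- se_kernel(years, years, config$kernel_amplitude,
                 config$kernel_length_scale)
  n_d <- config$n_draws
  mean_logit <- numeric(nrow(g))
  draws <- matrix(0, nrow(g), n_d)

  skey <- g[, paste(cause, location, age_start, sex)]
  series <- split(seq_len(nrow(g)), skey)
  okey <- obs[, paste(cause, location, age_start, sex)]
  obs_by <- split(seq_len(nrow(obs)), okey)

  with_rng(config$seed, {
    for (nm in names(series)) {
      rows <- series[[nm]]
      rows <- rows[order(g$year[rows])]
      m0 <- g$prior_logit[rows] + g$resid_sm[rows]
      oi <- obs_by[[nm]]
      if (is.null(oi) || !length(oi)) {
        post_mean <- m0
        post_cov <- K
      } else {
        yi <- match(obs$year[oi], years)
        yobs <- obs$value[oi]
        m_at <- m0[yi]
        Ko <- K[yi, yi, drop = FALSE] + diag(obs$var[oi],
                                             nrow = length(oi))
        Ks <- K[, yi, drop = FALSE]
        sol <- tryCatch(solve(Ko, cbind(yobs - m_at, t(Ks))),
                        error = function(e) NULL)
        jit <- 1e-8
        while (is.null(sol) && jit <= 1e-6) {
          sol <- tryCatch(
            solve(Ko + diag(jit, nrow(Ko)), cbind(yobs - m_at, t(Ks))),
            error = function(e) NULL)
          jit <- jit * 10
        }
        if (is.null(sol)) {
          stop("GP covariance not positive definite after jitter",
               call. = FALSE)
        }
        post_mean <- m0 + as.numeric(Ks %*% sol[, 1])
        post_cov <- K - Ks %*% sol[, -1, drop = FALSE]
      }
      L <- tryCatch(chol(post_cov + diag(1e-8, nrow(post_cov))),
                    error = function(e)
                      chol(post_cov + diag(1e-6, nrow(post_cov))))
      z <- matrix(stats::rnorm(length(rows) * n_d), length(rows), n_d)
      mean_logit[rows] <- post_mean
      draws[rows, ] <- post_mean + crossprod(L, z)
    }
  })

  if (config$age_smoothing) {
    sm <- age_smooth_matrix(g)
    mean_logit <- as.numeric(sm %*% mean_logit)
    draws <- as.matrix(sm %*% draws)
  }
  out_draws <- invlogit_mir(draws, cap = cap)
  g[, cell_id := NULL]
  surf <- draw_surface(g[, ord, with = FALSE], out_draws)
  attr(surf, "posterior_logit_mean") <- mean_logit
  surf
}

# sparse moving-average operator over adjacent age groups (0.25/0.5/0.25,
# renormalized at the boundaries) within cause-location-year-sex slices
age_smooth_matrix <- function(g) {
  ages <- sort(unique(g$age_start))
  a_idx <- match(g$age_start, ages)
  slice <- g[, paste(cause, location, year, sex)]
  n <- nrow(g)
  # neighbor row lookup: same slice, adjacent age index
  lut <- data.table::data.table(slice = slice, a = a_idx, row = seq_len(n))
  up <- lut[data.table::data.table(slice = slice, a = a_idx + 1L),
            row, on = c("slice", "a")]
  dn <- lut[data.table::data.table(slice = slice, a = a_idx - 1L),
            row, on = c("slice", "a")]
  ii <- c(seq_len(n), which(!is.na(up)), which(!is.na(dn)))
  jj <- c(seq_len(n), up[!is.na(up)], dn[!is.na(dn)])
  xx <- c(rep(0.5, n), rep(0.25, sum(!is.na(up))), rep(0.25, sum(!is.na(dn))))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  M / Matrix::rowSums(M)
}

#' Fit the full three-stage MIR model
#'
#' Runs covariate prior, space-time residual smoothing, and GP posterior in
#' sequence and returns the complete MIR surface with draws.
#'
#' @inheritParams fit_prior
#' @param config an [stgpr_config()]
#' @return a `draw_surface` of MIRs (see [gpr_posterior()])
#' @export
fit_mir <- function(observations, haq, grid, config = stgpr_config()) {
  prior <- fit_prior(observations, haq, grid, cap = config$mir_cap)
  obs <- data.table::as.data.table(observations)
  okey <- intersect(c("cause", "location", "year", "age_start", "sex"),
                    names(obs))
  res <- merge(obs, prior, by = okey, sort = FALSE)
  res[, resid := logit_mir(mir, cap = config$mir_cap) - prior_logit]
  pb <- pmin(pmax(res$mir / config$mir_cap, 1e-4), 1 - 1e-4)
  res[, prec := pmax(ess, 1) * pb * (1 - pb)]
  st <- spacetime_smooth(res[, c(okey, "resid", "prec"), with = FALSE],
                         prior, config)
  surf <- gpr_posterior(st, observations, config)
  attr(surf, "prior_coefficients") <- attr(prior, "coefficients")
  surf
}
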
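library(data.table)

# a tiny deterministic panel for model-stage unit tests
toy_grid <- function(locs = c("A", "B"), years = 2000:2009,
                     ages = c(40, 60), cause = "stomach") {
  g <- data.table::CJ(cause = cause, location = locs, year = years,
                      age_start = ages, sex = c("male", "female"),
                      sorted = FALSE)
  data.table::setorderv(g, c("cause", "location", "year", "age_start",
                             "sex"))
  g[]
}

test_that("the covariate prior recovers known coefficients from exact observations", {
  g <- toy_grid()
  haq <- data.table::CJ(location = c("A", "B"), year = 2000:2009)
  haq[, haq := 40 + 3 * (year - 2000) + ifelse(location == "B", 12, 0)]
  beta <- -0.04
  intercept <- 1.1
  age_eff <- 0.5  # age 60 relative to 40
  obs <- merge(g, haq, by = c("location", "year"))
  obs[, value := intercept + age_eff * (age_start == 60) + beta * haq]
  obs[, mir := 1 / (1 + exp(-value))]
  obs[, ess := 1e6]
  prior <- fit_prior(obs[, .(cause, location, year, age_start, sex, mir,
                             ess)], haq, g, cap = 1)
  cf <- attr(prior, "coefficients")[["stomach/male"]]
  expect_lt(abs(cf[["(Intercept)"]] - intercept), 1e-3)
  expect_lt(abs(cf[["age_f60"]] - age_eff), 1e-3)
  expect_lt(abs(cf[["haq"]] - beta), 1e-3)
  # predictions reproduce the generating surface
  chk <- merge(prior, obs[, .(cause, location, year, age_start, sex, value)],
               by = c("cause", "location", "year", "age_start", "sex"))
  expect_lt(max(abs(chk$prior_logit - chk$value)), 1e-3)
})

test_that("degenerate priors: constant observations and constant HAQ", {
  g <- toy_grid()
  haq <- data.table::CJ(location = c("A", "B"), year = 2000:2009)
  haq[, haq := 50]
  obs <- merge(g, haq, by = c("location", "year"))
  obs[, `:=`(mir = 0.4, ess = 1000)]
  expect_warning(
    prior <- fit_prior(obs[, .(cause, location, year, age_start, sex, mir,
                               ess)], haq, g, cap = 1),
    "constant")
  expect_lt(max(abs(prior$prior_logit - log(0.4 / 0.6))), 1e-9)
})

test_that("space-time smoothing: zeros, single-residual pooling, normalization", {
  cfg <- stgpr_config(location_pool_weight = 0, n_draws = 100)
  g <- toy_grid(ages = 50)
  zero <- data.table::data.table(
    cause = "stomach", location = "A", year = c(2002, 2007),
    age_start = 50, sex = "male", resid = 0)
  st0 <- spacetime_smooth(zero, g, cfg)
  expect_true(all(st0$resid_sm == 0))

  one <- data.table::data.table(cause = "stomach", location = "A",
                                year = 2003, age_start = 50, sex = "male",
                                resid = 0.8)
  st1 <- spacetime_smooth(one, g, cfg)
  # normalized weights: the single residual is reproduced across all of
  # location A; location B (zeta = 0) gets nothing
  expect_true(all(abs(st1[location == "A" & sex == "male", resid_sm] -
                        0.8) < 1e-12))
  expect_true(all(st1[location == "B" & sex == "male", resid_sm] == 0))
  # slices with no observations (female) stay at zero
  expect_true(all(st1[sex == "female", resid_sm] == 0))

  # constant residuals at several cells reproduce the constant everywhere
  # weights reach (weights sum to 1)
  cfg2 <- stgpr_config(location_pool_weight = 0.5, n_draws = 100)
  many <- data.table::data.table(
    cause = "stomach", location = c("A", "A", "B"),
    year = c(2001, 2006, 2004), age_start = 50, sex = "male", resid = -0.3)
  st2 <- spacetime_smooth(many, g, cfg2)
  expect_true(all(abs(st2[sex == "male", resid_sm] + 0.3) < 1e-12))
})

test_that("GP posterior: prior reversion, interpolation, bounds", {
  cfg <- stgpr_config(kernel_amplitude = 0.6, kernel_length_scale = 4,
                      n_draws = 400, age_smoothing = FALSE, seed = 9)
  g <- toy_grid(locs = "A", ages = 50)
  g[, prior_logit := 0.2]
  g[, resid_sm := 0]

  # no observations: posterior mean equals the prior, draw spread matches
  # the kernel amplitude
  surf0 <- gpr_posterior(g, data.table::data.table(
    cause = character(), location = character(), year = integer(),
    age_start = numeric(), sex = character(), mir = numeric(),
    ess = numeric()), cfg)
  expect_equal(attr(surf0, "posterior_logit_mean"), rep(0.2, nrow(g)))
  logit_draws <- log(surf0$draws / (1 - surf0$draws))
  expect_lt(abs(mean(apply(logit_draws, 1, stats::sd)) - 0.6), 0.08)

  # one effectively noise-free observation: the posterior passes through it
  obs <- data.table::data.table(cause = "stomach", location = "A",
                                year = 2004, age_start = 50, sex = "male",
                                mir = 0.7, ess = 1e7)
  surf1 <- gpr_posterior(g, obs, cfg)
  m <- attr(surf1, "posterior_logit_mean")
  at <- which(g$year == 2004 & g$sex == "male")
  expect_lt(abs(1 / (1 + exp(-m[at])) - 0.7), 1e-3)

  expect_true(all(surf1$draws > 0 & surf1$draws <= 1))
})

test_that("GP posterior matches a direct matrix-algebra oracle on a 3-point series", {
  cfg <- stgpr_config(kernel_amplitude = 0.5, kernel_length_scale = 3,
                      n_draws = 100, age_smoothing = FALSE)
  years <- 2000:2009
  g <- toy_grid(locs = "A", years = years, ages = 50)
  g <- g[sex == "male"]
  prior_mean <- 0.3 - 0.02 * (years - 2000)
  g[, prior_logit := rep(prior_mean, each = 1)]
  g[, resid_sm := 0]
  obs <- data.table::data.table(
    cause = "stomach", location = "A", year = c(2001, 2004, 2008),
    age_start = 50, sex = "male", mir = c(0.62, 0.55, 0.48), ess = 400)

  surf <- gpr_posterior(g, obs, cfg)
  got <- attr(surf, "posterior_logit_mean")

  # independent oracle: textbook GP regression by direct matrix algebra,
  # reproducing the declared nugget (inflated binomial logit variance)
  se_k <- function(a, b) 0.5^2 * exp(-outer(a, b, "-")^2 / (2 * 3^2))
  yobs <- log(obs$mir / (1 - obs$mir))
  m_obs <- prior_mean[match(obs$year, years)]
  # declared nugget: binomial variance at the average of the observed
  # ratio and the stage-1+2 mean; no dispersion inflation under 10 obs
  p <- (obs$mir + 1 / (1 + exp(-m_obs))) / 2
  v <- 1 / (400 * p * (1 - p))
  K_oo <- se_k(obs$year, obs$year) + diag(v)
  K_so <- se_k(years, obs$year)
  oracle <- prior_mean + as.numeric(K_so %*% solve(K_oo, yobs - m_obs))
  expect_lt(max(abs(got - oracle)), 1e-8)
})

test_that("increasing the kernel length scale never roughens the posterior mean", {
  p <- small_prepared()
  rough <- function(ls) {
    cfg <- stgpr_config(kernel_length_scale = ls, n_draws = 100,
                        age_smoothing = FALSE, seed = 3)
    surf <- fit_mir(p$obs, p$world$haq, p$grid, cfg)
    m <- attr(surf, "posterior_logit_mean")
    g <- surf$grid
    d <- data.table::data.table(g, m = m)
    sum(d[, list(r = sum(diff(m[order(year)])^2)),
          by = c("cause", "location", "age_start", "sex")]$r)
  }
  r_short <- rough(2)
  r_mid <- rough(6)
  r_long <- rough(15)
  expect_lte(r_mid, r_short)
  expect_lte(r_long, r_mid)
})

test_that("full MIR fit is data-dominated in the noise-free dense limit", {
  # noise-free limit: observations on the full grid drawn exactly from a
  # surface the covariate prior can represent, with very large effective
  # sample sizes. The posterior must reproduce the observations to within
  # 1e-2 everywhere (the GP interpolates once the nugget vanishes and the
  # dispersion estimate finds nothing to inflate).
  cfg <- small_config(77)
  g <- demographic_grid(cfg)
  haq <- generate_world(cfg)$haq
  obs <- merge(g, haq, by = c("location", "year"))
  age_eff <- stats::setNames(seq(-0.6, 0.9, length.out = 6),
                             sort(unique(g$age_start)))
  obs[, value := -0.3 + age_eff[as.character(age_start)] - 0.035 * haq +
        0.4 * (cause == "stomach")]
  obs[, mir := 1 / (1 + exp(-value))]
  obs[, ess := 1e6]
  surf <- fit_mir(obs[, list(cause, location, year, age_start, sex, mir,
                             ess)], haq, g,
                  stgpr_config(n_draws = 100, age_smoothing = FALSE,
                               seed = 4))
  est <- data.table::data.table(surf$grid, m = surface_mean(surf))
  chk <- merge(est, obs, by = c("cause", "location", "year", "age_start",
                                "sex"))
  expect_lt(max(abs(chk$m - chk$mir)), 1e-2)
})
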
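library(data.table)

# small deterministic modeling table: Poisson-ish deaths with an age
# gradient and mild HAQ effect
toy_mortality_data <- function(seed = 3, n_loc = 4, years = 2010:2017) {
  withr::with_seed(seed, {
    d <- data.table::CJ(location = sprintf("L%02d", seq_len(n_loc)),
                        year = years, age_start = c(30, 50, 70),
                        sex = "male")
    d[, age_end := age_start + 20]
    d[, cause := "stomach"]
    d[, population := 2e5]
    d[, haq := 40 + 2 * (year - min(year)) +
        5 * as.integer(factor(location))]
    d[, sdi := haq / 100]
    true_rate <- exp(log(c(5, 25, 90))[match(d$age_start, c(30, 50, 70))] -
                       0.01 * d$haq)
    d[, deaths := stats::rpois(.N, true_rate * population / 1e5)]
    d[, envelope_rate := true_rate * 8 + 300]
    d[, weight := 1]
    d[]
  })
}

test_that("submodel enumeration covers both spaces and all subsets in fixed order", {
  s1 <- enumerate_submodels("haq", 1)
  expect_length(s1, 4)  # 2 spaces x {intercept-only, haq}
  expect_identical(vapply(s1, `[[`, "", "space"),
                   rep(c("log_rate", "logit_fraction"), each = 2))

  s0 <- enumerate_submodels(character(0))
  expect_length(s0, 2)
  expect_true(all(lengths(lapply(s0, `[[`, "covariates")) == 0))

  pool <- c("year", "haq", "age")
  expect_identical(enumerate_submodels(pool, 2), enumerate_submodels(pool, 2))
  s2 <- enumerate_submodels(pool, 2)
  expect_length(s2, 2 * (1 + 3 + 3))

  s3 <- enumerate_submodels(c("age", "haq", "sdi", "year"), 4)
  expect_length(s3, 2 * (1 + 4 + 6 + 4 + 1))
})

test_that("out-of-sample weights normalize, favor the informative submodel, and follow the softmax rule", {
  d <- toy_mortality_data()
  specs <- enumerate_submodels(c("age", "haq"), 2)
  cfg <- ensemble_config(covariate_pool = "haq",
                         max_subset_size = 2, n_folds = 4, n_draws = 100,
                         seed = 5)
  w <- oos_validity_weights(specs, d, cfg)
  expect_equal(sum(w$weights), 1, tolerance = 1e-9)
  # softmax consistency with the returned RMSEs at tau = min RMSE
  tau <- min(w$oos_rmse, na.rm = TRUE)
  ref <- exp(-w$oos_rmse / tau)
  ref[!is.finite(ref)] <- 0
  expect_equal(w$weights, ref / sum(ref), tolerance = 1e-9)
  # age effects are structural, so the {} and {"age"} specs share one
  # formula and must score identically
  covs <- lapply(specs, `[[`, "covariates")
  i_empty <- which(vapply(covs, length, 1L) == 0)
  i_age <- which(vapply(covs, identical, logical(1), "age"))
  expect_equal(w$oos_rmse[i_empty], w$oos_rmse[i_age])
  expect_equal(w$weights[i_empty], w$weights[i_age])

  # a single submodel takes weight 1
  w1 <- oos_validity_weights(specs[2], d, cfg)
  expect_equal(w1$weights, 1)

  # two copies of the same submodel split evenly by symmetry
  w2 <- oos_validity_weights(specs[c(2, 2)], d, cfg)
  expect_equal(w2$weights, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("draw apportionment follows the largest-remainder rule exactly", {
  expect_identical(apportion_draws(1, 1000), 1000L)
  expect_identical(apportion_draws(c(0.5, 0.5), 1000), c(500L, 500L))
  expect_identical(apportion_draws(c(0.731, 0.269), 1000), c(731L, 269L))
  w <- c(1 / 3, 1 / 3, 1 / 3)
  expect_identical(sum(apportion_draws(w, 1000)), 1000L)
  expect_identical(apportion_draws(c(0.335, 0.335, 0.33), 10),
                   c(4L, 3L, 3L))
})

test_that("ensemble draws fill the exact draw budget and track the data", {
  d <- toy_mortality_data()
  specs <- enumerate_submodels(c("age", "haq"), 2)
  cfg <- ensemble_config(covariate_pool = "haq",
                         max_subset_size = 2, n_folds = 4, n_draws = 200,
                         seed = 5)
  w <- oos_validity_weights(specs, d, cfg)
  ds <- ensemble_draws(specs, w$weights, d, d, cfg)
  expect_identical(ncol(ds$draws), 200L)
  expect_false(anyNA(ds$draws))
  expect_true(all(ds$draws >= 0))
  # ensemble mean deaths near observed totals
  expect_lt(abs(sum(rowMeans(ds$draws)) / sum(d$deaths) - 1), 0.05)
  # single-submodel ensemble: all draws from that submodel
  ds1 <- ensemble_draws(specs[2], 1, d, d, cfg)
  expect_identical(ncol(ds1$draws), 200L)
})

test_that("envelope scaling is an exact draw-wise conservation law", {
  g <- data.table::CJ(cause = c("a", "b"), location = "L01", year = 2010,
                      age_start = 50, sex = "male")
  env_g <- unique(g[, !"cause"])
  # worked example: causes (3, 7) against envelope 20 -> (6, 14)
  cd <- draw_surface(g, matrix(c(3, 7), 2, 1))
  env <- draw_surface(env_g, matrix(20, 1, 1))
  sc <- scale_to_envelope(cd, env)
  expect_equal(as.numeric(sc$draws), c(6, 14))

  # already consistent: identity
  cd2 <- draw_surface(g, matrix(c(8, 12), 2, 1))
  sc2 <- scale_to_envelope(cd2, draw_surface(env_g, matrix(20, 1, 1)))
  expect_equal(as.numeric(sc2$draws), c(8, 12))

  # random positive draws: sums match the envelope within 1e-9 relative
  withr::with_seed(8, {
    gg <- data.table::CJ(cause = c("a", "b", "c"),
                         location = c("L01", "L02"), year = 2010:2012,
                         age_start = c(40, 60), sex = c("male", "female"))
    eg <- unique(gg[, !"cause"])
    cdr <- draw_surface(gg, matrix(stats::rexp(nrow(gg) * 50), nrow(gg)))
    envr <- draw_surface(eg, matrix(stats::rexp(nrow(eg) * 50) + 1,
                                    nrow(eg)))
    scr <- scale_to_envelope(cdr, envr)
    sums <- rowsum(scr$draws, scr$grid[, paste(location, year, age_start,
                                               sex)])
    envs <- envr$draws[order(envr$grid[, paste(location, year, age_start,
                                               sex)]), ]
    expect_lt(max(abs(sums / envs - 1)), 1e-9)
  })

  # zero cause total against a positive envelope: flagged, left unscaled
  cd0 <- draw_surface(g, matrix(c(0, 0), 2, 1))
  sc0 <- scale_to_envelope(cd0, env)
  expect_equal(as.numeric(sc0$draws), c(0, 0))
  expect_gt(nrow(attr(sc0, "unscaled_cells")), 0)
})

test_that("an irrelevant covariate does not degrade the weighted ensemble error", {
  d <- toy_mortality_data()
  withr::with_seed(11, d[, sdi := stats::runif(.N)])  # decouple sdi: pure noise
  cfg <- ensemble_config(covariate_pool = "haq",
                         max_subset_size = 3, n_folds = 4, n_draws = 100,
                         seed = 5)
  base_specs <- enumerate_submodels(c("age", "haq"), 3)
  ext_specs <- enumerate_submodels(c("age", "haq", "sdi"), 3)
  wb <- oos_validity_weights(base_specs, d, cfg)
  we <- oos_validity_weights(ext_specs, d, cfg)
  score <- function(w) sum(w$weights * w$oos_rmse, na.rm = TRUE)
  margin <- max(wb$oos_rmse, na.rm = TRUE) - min(wb$oos_rmse, na.rm = TRUE)
  expect_lt(score(we), score(wb) + margin)
  # weight mass shifts away from noise-only submodels
  noise_only <- vapply(ext_specs, function(s)
    identical(s$covariates, "sdi"), logical(1))
  expect_lt(sum(we$weights[noise_only]), 0.2)
})
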
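library(data.table)

cells2 <- data.table::data.table(
  cause = "stomach", location = "L01", year = 2019,
  age_start = c(30, 70), age_end = c(50, Inf), sex = "male")

test_that("YLLs multiply deaths by remaining life expectancy, per age group", {
  lt <- data.table::data.table(age_start = c(30, 70), e_star = c(50, 20))
  d <- draw_surface(cells2, matrix(c(2, 3), 2, 1))
  yll <- compute_ylls(d, lt)
  expect_equal(as.numeric(yll$draws), c(100, 60))
  expect_equal(sum(yll$draws), 160)
  d0 <- draw_surface(cells2, matrix(0, 2, 1))
  expect_true(all(compute_ylls(d0, lt)$draws == 0))
  expect_equal(as.numeric(compute_ylls(
    draw_surface(cells2[1], matrix(1, 1, 1)),
    data.table::data.table(age_start = 30, e_star = 30))$draws), 30)
  expect_error(compute_ylls(d, lt[1]), "missing age group")
})

test_that("the packaged reference life table and standard population are valid", {
  lt <- reference_life_table()
  expect_true(all(diff(lt$e_star) < 0))
  expect_true(all(lt$e_star > 0))
  sp <- standard_population()
  expect_equal(sum(sp$weight), 1, tolerance = 1e-12)
  expect_true(all(sp$weight >= 0))
})

test_that("DALYs are the draw-wise sum of YLLs and YLDs", {
  withr::with_seed(5, {
    yll <- draw_surface(cells2, matrix(stats::rexp(2 * 50), 2))
    yld <- draw_surface(cells2, matrix(stats::rexp(2 * 50), 2))
  })
  daly <- compute_dalys(yll, yld)
  expect_identical(daly$draws, yll$draws + yld$draws)
  zero <- draw_surface(cells2, matrix(0, 2, 50))
  expect_identical(compute_dalys(yll, zero)$draws, yll$draws)
  bad <- draw_surface(cells2[1], matrix(1, 1, 50))
  expect_error(compute_dalys(yll, bad), "aligned")
})

test_that("age standardization is a fixed-weight average, invariant to population scale", {
  std <- data.table::data.table(age_start = c(30, 70),
                                weight = c(0.75, 0.25))
  expect_equal(age_standardize(c(10, 30), std), 15)
  expect_equal(age_standardize(c(7, 7), std), 7)
  # invariance: rates from counts are unchanged when population doubles
  counts <- c(40, 90)
  pop <- c(2e5, 1e5)
  expect_equal(age_standardize(counts / pop * 1e5, std),
               age_standardize(2 * counts / (2 * pop) * 1e5, std))
  expect_error(age_standardize(c(-1, 3), std), "non-negative")
  expect_error(
    age_standardize(data.table::data.table(age_start = 30, rate = 5), std),
    "cover")
})

test_that("percent change operates at the draw level, where it differs from point estimates", {
  expect_equal(percent_change(100, 100), 0)
  expect_equal(percent_change(100, 150), 50)
  expect_error(percent_change(0, 10), "positive")
  # skewed 3-draw counterexample: draw-level mean change vs change of means
  v0 <- c(1, 1, 4)
  v1 <- c(2, 2, 2)
  draw_level <- mean(percent_change(v0, v1))
  point_level <- percent_change(mean(v0), mean(v1))
  expect_equal(draw_level, 50)
  expect_equal(point_level, 0)
  expect_false(isTRUE(all.equal(draw_level, point_level)))
})

test_that("annualized rates of change follow the log formula and match printed roundings", {
  expect_equal(annualized_rate_of_change(100, 200, 2010, 2019),
               100 * log(2) / 9)
  expect_equal(annualized_rate_of_change(5, 5, 2000, 2010), 0)
  # a -5.9% decade decline annualizes to -0.7%/yr at one decimal, under
  # both the log and geometric conventions
  expect_equal(round(annualized_rate_of_change(100, 94.1, 2010, 2019), 1),
               -0.7)
  expect_equal(round(annualized_rate_of_change(100, 94.1, 2010, 2019,
                                               method = "geometric"), 1),
               -0.7)
  expect_error(annualized_rate_of_change(-1, 5, 2010, 2019), "positive")
  expect_error(annualized_rate_of_change(5, 5, 2019, 2010), "y_end")
  # round trip with percent change
  arc <- annualized_rate_of_change(80, 95, 2010, 2019)
  expect_equal(percent_change(80, 80 * exp(9 * arc / 100)),
               percent_change(80, 95), tolerance = 1e-9)
})

test_that("uncertainty intervals use mean and type-7 percentiles of the draws", {
  expect_equal(uncertainty_interval(rep(3.2, 200)),
               c(lower = 3.2, mean = 3.2, upper = 3.2))
  ui <- uncertainty_interval(1:1000)
  expect_equal(ui[["lower"]], 25.975)
  expect_equal(ui[["upper"]], 975.025)
  expect_equal(ui[["mean"]], 500.5)
  expect_error(uncertainty_interval(1:50), "100")
  withr::with_seed(6, {
    for (i in 1:20) {
      ui <- uncertainty_interval(stats::rlnorm(150, 0, 2))
      expect_lte(ui[["lower"]], ui[["upper"]])
    }
  })
})

test_that("SDI is the geometric mean of scaled components, within component bounds", {
  expect_equal(compute_sdi(1, 1, 1), 1)
  expect_equal(compute_sdi(0.5, 0.5, 0.5), 0.5)
  expect_equal(compute_sdi(0.2, 0.4, 0.8), 0.4)
  expect_error(compute_sdi(1.2, 0.5, 0.5), "\\[0,1\\]")
  withr::with_seed(7, {
    comp <- matrix(stats::runif(300), ncol = 3)
    sdi <- compute_sdi(comp[, 1], comp[, 2], comp[, 3])
    expect_true(all(sdi >= apply(comp, 1, min) - 1e-12))
    expect_true(all(sdi <= apply(comp, 1, max) + 1e-12))
  })
})

test_that("SDI quintile labels are fixed by the reference year, with ties to the lower quintile", {
  panel <- data.table::CJ(location = sprintf("L%d", 1:5), year = 2010:2019)
  panel[, sdi := 0.1 + 0.2 * (as.integer(substr(location, 2, 2)) - 1) +
          0.001 * (year - 2010)]
  q <- assign_sdi_quintiles(panel, ref_year = 2019)
  lab <- unique(q[, list(location, quintile)])
  expect_equal(nrow(lab), 5)  # one label per location
  expect_setequal(as.character(lab$quintile),
                  c("low", "low-middle", "middle", "high-middle", "high"))
  # same label in 2010 and 2019 rows
  expect_identical(q[year == 2010, quintile], q[year == 2019, quintile])

  # a location exactly on a cutoff falls into the lower quintile
  p2 <- data.table::data.table(location = sprintf("L%d", 1:5), year = 2019,
                               sdi = c(0.1, 0.3, 0.5, 0.7, 0.9))
  q2 <- assign_sdi_quintiles(p2, ref_year = 2019,
                             cutoffs = c(0.3, 0.5, 0.7, 0.9))
  expect_identical(as.character(q2$quintile[q2$location == "L2"]), "low")
  expect_identical(as.character(q2$quintile[q2$location == "L5"]),
                   "high-middle")

  expect_error(assign_sdi_quintiles(panel[year < 2019], ref_year = 2019),
               "2019")
})

test_that("cancer rankings order by count with exclusions and flagged alphabetical ties", {
  r <- rank_cancer_groups(c(a = 10, b = 20, c = 5), exclude = character())
  expect_identical(r$cause, c("b", "a", "c"))
  expect_identical(r$rank, 1:3)
  r2 <- rank_cancer_groups(c(a = 10, other_malignant_neoplasms = 99,
                             b = 20))
  expect_false("other_malignant_neoplasms" %in% r2$cause)
  r3 <- rank_cancer_groups(c(zeta = 7, alpha = 7, mid = 9),
                           exclude = character())
  expect_identical(r3$cause, c("mid", "alpha", "zeta"))
  expect_identical(r3$tied, c(FALSE, TRUE, TRUE))
})

test_that("YLL/YLD shares are draw-wise complements", {
  s <- yll_yld_shares(100, 0)
  expect_equal(s$yll_share, 100)
  expect_equal(s$yld_share, 0)
  expect_true(is.na(yll_yld_shares(0, 0)$yll_share))
  withr::with_seed(9, {
    yll <- stats::rlnorm(500, 3)
    yld <- stats::rlnorm(500, 0.5)
    s <- yll_yld_shares(yll, yld)
    expect_equal(s$yll_share[["mean"]] + s$yld_share[["mean"]], 100,
                 tolerance = 1e-9)
  })
})
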
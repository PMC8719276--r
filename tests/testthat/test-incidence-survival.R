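library(data.table)

mk_surface <- function(grid, values, n_draws = 1) {
  draw_surface(grid, matrix(values, nrow(grid), n_draws))
}

single_cell <- data.table::data.table(
  cause = "stomach", location = "L01", year = 2010, age_start = 50,
  age_end = 55, sex = "male")

test_that("incidence back-calculation inverts the MIR identity", {
  m <- mk_surface(single_cell, 20)
  expect_equal(as.numeric(
    incidence_from_mortality(m, mk_surface(single_cell, 0.5))$draws), 40)
  expect_equal(as.numeric(
    incidence_from_mortality(m, mk_surface(single_cell, 1))$draws), 20)

  withr::with_seed(2, {
    g <- data.table::CJ(cause = c("a", "b"), location = "L01",
                        year = 2010:2014, age_start = c(40, 60),
                        sex = "male")
    g[, age_end := age_start + 20]
    mort <- draw_surface(g, matrix(stats::rexp(nrow(g) * 30, 1 / 50),
                                   nrow(g)))
    mir <- draw_surface(g, matrix(stats::runif(nrow(g) * 30, 0.05, 1),
                                  nrow(g)))
    inc <- incidence_from_mortality(mort, mir)
    # algebraic round trip, draw by draw
    expect_lt(max(abs(inc$draws * mir$draws / mort$draws - 1)), 1e-12)
    # I >= M wherever MIR <= 1
    expect_true(all(inc$draws >= mort$draws - 1e-12))
  })

  # a tiny MIR draw is clamped and flagged
  low <- incidence_from_mortality(m, mk_surface(single_cell, 1e-9))
  expect_length(attr(low, "clamped_cells"), 1)
})

test_that("survival interpolates linearly between frontier curves", {
  best <- exp(-0.05 * (1:10))
  worst <- exp(-0.5 * (1:10))
  expect_equal(as.numeric(survival_from_mir(1, best, worst)), worst)
  expect_equal(as.numeric(survival_from_mir(1e-12, best, worst)), best,
               tolerance = 1e-10)
  expect_equal(survival_from_mir(0.5, rep(0.9, 10), rep(0.1, 10))[1, 5],
               0.5)
  s <- survival_from_mir(c(0.2, 0.7), best, worst)
  expect_true(all(diff(s[1, ]) <= 0), all(diff(s[2, ]) <= 0))
  expect_error(survival_from_mir(0.5, worst, best), "frontier")
  expect_error(survival_from_mir(0, best, worst), "mir")
  expect_error(survival_from_mir(1.2, best, worst), "mir")
})

test_that("packaged frontier curves are valid monotone frontiers", {
  fs <- frontier_survival()
  expect_true(all(fs$best >= fs$worst))
  chk <- fs[, list(mono = all(diff(best) <= 0) && all(diff(worst) <= 0)),
            by = "cause"]
  expect_true(all(chk$mono))
  expect_true("default" %in% fs$cause)
})

test_that("steady-state prevalence with perfect survival accumulates 10 cohort-years", {
  g <- data.table::CJ(cause = "stomach", location = "L01",
                      year = 2000:2015, age_start = 0, sex = "male")
  g[, age_end := Inf]
  inc <- draw_surface(g, matrix(100, nrow(g), 5))
  surv <- matrix(1, nrow(g), 10)
  prev <- ten_year_prevalence(inc, surv, background = 0)
  # after 10 elapsed years every year holds 10 x 100 surviving person-years
  expect_equal(as.numeric(prev$draws[prev$grid$year == 2012, ]),
               rep(1000, 5))
  # zero incidence, zero prevalence
  prev0 <- ten_year_prevalence(draw_surface(g, matrix(0, nrow(g), 5)),
                               surv, 0)
  expect_true(all(prev0$draws == 0))
})

test_that("cohort bookkeeping matches a hand-coded ledger oracle", {
  # 3 cohorts of 10/yr for 2005-2007, one age band, survival (0.8, 0.6,
  # 0.5, 0.4, ...), no background mortality
  g <- data.table::CJ(cause = "a", location = "L", year = 2005:2010,
                      age_start = 0, sex = "male")
  g[, age_end := Inf]
  inc_v <- ifelse(g$year <= 2007, 10, 0)
  S <- c(0.8, 0.6, 0.5, 0.4, 0.35, 0.3, 0.25, 0.2, 0.15, 0.1)
  prev <- ten_year_prevalence(draw_surface(g, matrix(inc_v, ncol = 1)),
                              matrix(S, nrow(g), 10, byrow = TRUE), 0)
  # oracle: explicit loop over cohorts and elapsed years
  ledger <- stats::setNames(numeric(6), 2005:2010)
  for (y0 in 2005:2007) {
    for (t in 1:10) {
      y <- y0 + t
      if (y <= 2010) ledger[as.character(y)] <-
          ledger[as.character(y)] + 10 * S[t]
    }
  }
  got <- stats::setNames(as.numeric(prev$draws), prev$grid$year)
  expect_equal(got, ledger)
})

test_that("aging spills cohorts into the next age group proportionally", {
  # one-year-wide age groups make the spill-over exact: a cohort diagnosed
  # in [0,5) moves fully into [5,10) after 5+ years
  g <- data.table::CJ(cause = "a", location = "L", year = 2000:2012,
                      age_start = c(0, 5, 10), sex = "f")
  g[, age_end := age_start + 5]
  inc_v <- ifelse(g$year == 2000 & g$age_start == 0, 100, 0)
  prev <- ten_year_prevalence(draw_surface(g, matrix(inc_v, ncol = 1)),
                              matrix(1, nrow(g), 10), 0)
  d <- data.table::data.table(prev$grid, p = as.numeric(prev$draws))
  # after 2 years: 2/5 of the cohort has crossed into [5,10)
  expect_equal(d[year == 2002 & age_start == 0, p], 60)
  expect_equal(d[year == 2002 & age_start == 5, p], 40)
  # after 7 years: fully inside [5,10) by 2 years, 2/5 into [10,15)
  expect_equal(d[year == 2007 & age_start == 5, p], 60)
  expect_equal(d[year == 2007 & age_start == 10, p], 40)
  # person-years conserved each elapsed year (survival 1, no background)
  tots <- d[, list(tot = sum(p)), by = "year"]
  expect_true(all(tots$tot[tots$year %in% 2001:2010] == 100))
})

test_that("sequela partition reproduces the worked example and conserves person-time", {
  out <- partition_sequelae(100, 12, 40,
                            durations = c(diagnosis_treatment = 0.25,
                                          metastatic = 0.33,
                                          terminal = 0.083))
  expect_equal(out$diagnosis_treatment, 10)
  expect_equal(out$metastatic, 3.96)
  expect_equal(out$terminal, 0.996)
  expect_equal(out$remission, 85.044)
  expect_equal(rowSums(as.matrix(out)), 100)

  # no deaths: terminal and metastatic empty
  z <- partition_sequelae(50, 0, 10)
  expect_equal(z$terminal, 0)
  expect_equal(z$metastatic, 0)

  # conservation holds on random inputs, including the floored regime
  withr::with_seed(4, {
    prev <- stats::rexp(500, 1 / 50)
    deaths <- stats::rexp(500, 1 / 30)
    cases <- stats::rexp(500, 1 / 40)
    ph <- partition_sequelae(prev, deaths, cases)
    expect_true(all(abs(rowSums(as.matrix(ph)) - prev) < 1e-6 * (prev + 1)))
    expect_true(all(as.matrix(ph) >= 0))
  })
})

test_that("YLDs are disability-weighted person-years, linear in both factors", {
  sq <- data.table::data.table(diagnosis_treatment = 100, remission = 0,
                               metastatic = 0, terminal = 0)
  w <- c(diagnosis_treatment = 0.288, remission = 0.049, metastatic = 0.451,
         terminal = 0.54)
  expect_equal(compute_ylds(sq, w), 28.8)
  expect_equal(compute_ylds(sq, w * 0), 0)
  sq2 <- data.table::data.table(diagnosis_treatment = 30, remission = 200,
                                metastatic = 8, terminal = 2)
  expect_equal(compute_ylds(sq2 * 2, w), 2 * compute_ylds(sq2, w))
  expect_equal(compute_ylds(sq2, w, procedure_py = 50,
                            procedure_dw = 0.1),
               compute_ylds(sq2, w) + 5)
})

test_that("procedure-related disability accepts only the five eligible cancers", {
  props <- data.table::data.table(year = 2000:2004, proportion = 1)
  surv <- data.table::data.table(year = 2000:2004, survivors = 100)
  out <- procedure_prevalence("larynx", props, surv, background = 0)
  expect_equal(out$prevalence[out$year == 2004], 500)

  none <- procedure_prevalence("breast",
                               data.table::data.table(year = 2000:2004,
                                                      proportion = 0),
                               surv)
  expect_true(all(none$prevalence == 0))
  # colorectal under its pipeline cause id is accepted
  expect_silent(procedure_prevalence("colon_rectum", props, surv))
  expect_error(procedure_prevalence("stomach", props, surv),
               "bladder, breast, colorectal, larynx, prostate")
})
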
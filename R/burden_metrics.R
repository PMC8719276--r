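#' Reference life table fixture
#'
#' Remaining life expectancy at each age-group midpoint, a synthetic
#' approximation of an aspirational (frontier) life table: strictly
#' decreasing and positive. Used to convert deaths into years of life lost.
#'
#' @param path CSV override (age_start, e_star); default the packaged
#'   fixture for the standard 12 age groups
#' @return `data.table` (age_start, e_star)
#' @export
reference_life_table <- function(path = system.file("extdata",
                                                    "reference_life_table_synthetic.csv",
                                                    package = "oncoburden")) {
  data.table::fread(path)
}

#' World standard population weights fixture
#'
#' Age weights of a world standard population aggregated to the standard 12
#' age groups, normalized to sum to 1; used for age-standardized rates.
#'
#' @param path CSV override (age_start, weight); default the packaged fixture
#' @return `data.table` (age_start, weight), weights normalized
#' @export
standard_population <- function(path = system.file("extdata",
                                                   "standard_population_synthetic.csv",
                                                   package = "oncoburden")) {
  w <- data.table::fread(path)
  w[, weight := weight / sum(weight)]
  w[]
}

#' Years of life lost
#'
#' YLL per cell and draw = deaths x remaining reference life expectancy at
#' the cell's age group.
#'
#' @param deaths `draw_surface` of deaths
#' @param life_table table (age_start, e_star) covering every age group
#' @return `draw_surface` of YLLs
#' @export
compute_ylls <- function(deaths, life_table) {
  lt <- data.table::as.data.table(life_table)
  e <- lt$e_star[match(deaths$grid$age_start, lt$age_start)]
  if (anyNA(e)) {
    stop(sprintf("life table missing age group(s): %s",
                 paste(sort(unique(deaths$grid$age_start[is.na(e)])),
                       collapse = ", ")), call. = FALSE)
  }
  draw_surface(deaths$grid, deaths$draws * e)
}

#' Disability-adjusted life years
#'
#' DALY = YLL + YLD, draw-wise on aligned grids.
#'
#' @param yll,yld aligned `draw_surface`s
#' @return `draw_surface` of DALYs
#' @export
compute_dalys <- function(yll, yld) {
  assert_aligned(yll, yld)
  draw_surface(yll$grid, yll$draws + yld$draws)
}

#' Age-standardized rate
#'
#' `ASR = sum_a w_a x rate_a` with fixed standard-population weights, so the
#' result is invariant to rescaling the observed population. Rates are per
#' 100 000 person-years in and out.
#'
#' @param rates table (age_start, rate) or vector aligned with `std`
#' @param std standard population (age_start, weight)
#' @return the age-standardized rate (scalar)
#' @export
age_standardize <- function(rates, std) {
  std <- data.table::as.data.table(std)
  w <- std$weight / sum(std$weight)
  if (is.data.frame(rates)) {
    r <- data.table::as.data.table(rates)
    m <- match(std$age_start, r$age_start)
    if (anyNA(m)) {
      stop("standard population weights do not cover all age groups",
           call. = FALSE)
    }
    r <- r$rate[m]
  } else {
    if (length(rates) != nrow(std)) {
      stop("rates and standard population weights are misaligned",
           call. = FALSE)
    }
    r <- rates
  }
  if (any(r < 0)) stop("rates must be non-negative", call. = FALSE)
  sum(w * r)
}

#' Percent change between two values (or draw vectors)
#'
#' `100 (v_end - v_start) / v_start`, applied per draw when given draw
#' vectors; summaries (mean and uncertainty interval) are then taken over
#' the draw-level changes, which is the canonical order of operations and
#' differs from the change of point estimates when draws are skewed.
#'
#' @param v_start,v_end positive values, scalars or aligned draw vectors
#' @return percent change(s)
#' @export
percent_change <- function(v_start, v_end) {
  if (any(v_start <= 0)) stop("v_start must be positive", call. = FALSE)
  100 * (v_end - v_start) / v_start
}

#' Annualized rate of change (percent per year)
#'
#' The mean percentage change per year over an interval, log formula:
#' `100 ln(v_end / v_start) / (y_end - y_start)`. A geometric-mean variant
#' `100 ((v_end/v_start)^(1/dt) - 1)` is available behind `method`; the two
#' agree to well under printed precision for the changes reported here.
#'
#' @param v_start,v_end positive values
#' @param y_start,y_end interval years, `y_end > y_start`
#' @param method `"log"` (default) or `"geometric"`
#' @return percent per year
#' @export
#' @examples
#' annualized_rate_of_change(100, 94.1, 2010, 2019)  # about -0.7
annualized_rate_of_change <- function(v_start, v_end, y_start, y_end,
                                      method = c("log", "geometric")) {
  method <- match.arg(method)
  if (any(v_start <= 0) || any(v_end <= 0)) {
    stop("values must be positive", call. = FALSE)
  }
  if (y_end <= y_start) stop("y_end must exceed y_start", call. = FALSE)
  dt <- y_end - y_start
  if (method == "log") 100 * log(v_end / v_start) / dt
  else 100 * ((v_end / v_start)^(1 / dt) - 1)
}

#' Uncertainty interval from draws
#'
#' The 2.5th and 97.5th percentiles of the draw distribution by linear
#' interpolation between order statistics (quantile type 7, the declared
#' convention), with the arithmetic draw mean as the point estimate.
#'
#' @param draws numeric vector of >= 100 draws
#' @param level interval mass (default 0.95)
#' @return named numeric: `lower`, `mean`, `upper`
#' @export
uncertainty_interval <- function(draws, level = 0.95) {
  if (length(draws) < 100) {
    stop("uncertainty intervals require at least 100 draws", call. = FALSE)
  }
  a <- (1 - level) / 2
  q <- stats::quantile(draws, c(a, 1 - a), type = 7, names = FALSE)
  c(lower = q[1], mean = mean(draws), upper = q[2])
}

#' Sociodemographic index from scaled components
#'
#' Geometric mean (cube root of the product) of scaled income per capita,
#' mean years of education, and (inverted) under-25 fertility, each in
#' \[0,1\].
#'
#' @param income,edu,fert scaled components in \[0,1\] (fertility already
#'   inverted so higher = more developed)
#' @return SDI values in \[0,1\]
#' @export
#' @examples
#' compute_sdi(0.2, 0.4, 0.8)  # 0.4
compute_sdi <- function(income, edu, fert) {
  comp <- cbind(income, edu, fert)
  if (any(comp < 0 | comp > 1)) {
    stop("SDI components must lie in [0,1]", call. = FALSE)
  }
  (income * edu * fert)^(1 / 3)
}

#' Assign fixed SDI quintile labels by the final-year value
#'
#' Quintile boundaries at the 20/40/60/80th percentiles of the reference
#' year's location SDI values (or user cutoffs); a location sitting exactly
#' on a boundary goes to the lower quintile (declared tie-break), and a
#' location's label is constant across all years for consistency of
#' comparison over time.
#'
#' @param sdi_panel table (location, year, sdi)
#' @param ref_year reference year fixing the labels (default 2019)
#' @param cutoffs optional 4 ascending interior cutoffs overriding the
#'   percentile boundaries
#' @return the panel with a `quintile` factor column (low, low-middle,
#'   middle, high-middle, high)
#' @export
assign_sdi_quintiles <- function(sdi_panel, ref_year = 2019,
                                 cutoffs = NULL) {
  p <- data.table::as.data.table(sdi_panel)
  ref <- p[year == ref_year]
  missing_loc <- setdiff(unique(p$location), ref$location)
  if (length(missing_loc)) {
    stop(sprintf("missing %d SDI value(s) for location(s): %s", ref_year,
                 paste(missing_loc, collapse = ", ")), call. = FALSE)
  }
  if (is.null(cutoffs)) {
    cutoffs <- stats::quantile(ref$sdi, c(0.2, 0.4, 0.6, 0.8), type = 7,
                               names = FALSE)
  }
  stopifnot(length(cutoffs) == 4, !is.unsorted(cutoffs))
  labels <- c("low", "low-middle", "middle", "high-middle", "high")
  # boundary ties fall to the lower quintile: intervals (-Inf, c1], (c1, c2]...
  lab <- labels[findInterval(ref$sdi, cutoffs, left.open = FALSE,
                             rightmost.closed = FALSE) + 1]
  lab[ref$sdi %in% cutoffs] <-
    labels[match(ref$sdi[ref$sdi %in% cutoffs], cutoffs)]
  key <- setNames(lab, ref$location)
  p[, quintile := factor(key[location], levels = labels)]
  p[]
}

#' Rank cancer groups by absolute burden
#'
#' Descending by count, with configured causes (by default the residual
#' "other malignant neoplasms" group) excluded before ranking; ties share
#' the alphabetically ordered ranks and are flagged.
#'
#' @param counts named numeric vector (cause -> count), one value per cause
#' @param exclude causes excluded from the ranking
#' @return `data.table` (cause, count, rank, tied) sorted by rank
#' @export
rank_cancer_groups <- function(counts,
                               exclude = "other_malignant_neoplasms") {
  counts <- counts[!names(counts) %in% exclude]
  d <- data.table::data.table(cause = names(counts),
                              count = as.numeric(counts))
  data.table::setorderv(d, c("count", "cause"), order = c(-1L, 1L))
  d[, rank := .I]
  d[, tied := duplicated(count) | duplicated(count, fromLast = TRUE)]
  d[]
}

#' YLL and YLD shares of DALYs
#'
#' Draw-wise `100 x YLL / (YLL + YLD)` and its complement, summarized with
#' uncertainty intervals; the two shares sum to 100 in every draw. Zero-DALY
#' input yields missing shares.
#'
#' @param yll,yld aligned draw vectors (or scalars) of YLL and YLD
#' @return list: `yll_share`, `yld_share`, each `(lower, mean, upper)` when
#'   draws are given, plain shares for scalars; `NA` if DALYs are zero
#' @export
yll_yld_shares <- function(yll, yld) {
  daly <- yll + yld
  if (all(daly == 0)) {
    return(list(yll_share = NA_real_, yld_share = NA_real_))
  }
  ys <- 100 * yll / daly
  if (length(ys) >= 100) {
    list(yll_share = uncertainty_interval(ys),
         yld_share = uncertainty_interval(100 - ys))
  } else {
    list(yll_share = ys, yld_share = 100 - ys)
  }
}
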
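#' @import data.table
#' @importFrom stats lm predict quantile rnorm rpois rbinom rnbinom coef vcov
#'   sd setNames na.omit complete.cases
#' @importFrom utils head tail
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", "..keep", "age_end", "age_start", "cases", "cause", "deaths", "haq",
  "icd_code", "location", "mir", "person_years", "population", "sex", "year",
  "value", "ess", "cell_id", "weight", "resid_sm", "covered", "edu", "fert_u25",
  "income", "draw", "phase", "duration_years", "disability_weight", "best",
  "worst", "t_year", "sdi", "quintile", "measure", "mean_val", "lower", "upper",
  "e_star", "rate", "N", "pred", "mir_true", "obs", "i.value", "prop"
))

#' Logit and inverse-logit with clamping
#'
#' MIRs live on a bounded ratio scale; all smoothing happens in logit space.
#' Values are clamped to `[eps, cap - eps*cap]` before the transform so that
#' registration noise pushing a raw MIR to 0 or above the cap cannot produce
#' infinite logits.
#'
#' @param p ratio values in (0, cap]
#' @param cap upper bound of the ratio scale (default 1)
#' @param eps clamp width (default 1e-4)
#' @return logit-scale values
#' @keywords internal
logit_mir <- function(p, cap = 1, eps = 1e-4) {
  x <- pmin(pmax(p / cap, eps), 1 - eps)
  log(x / (1 - x))
}

#' @rdname logit_mir
#' @param x logit-scale values
#' @keywords internal
invlogit_mir <- function(x, cap = 1, eps = 1e-4) {
  p <- cap / (1 + exp(-x))
  pmin(pmax(p, eps * cap), cap)
}

#' Evaluate an expression under a local, named RNG stream
#'
#' Seeds the generator, runs `expr`, and restores the caller's RNG state, so
#' no operation leaks global RNG state. Every stochastic operation in the
#' package takes an explicit seed and runs inside this helper.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a deterministic child seed from a master seed and a stage name
#'
#' One master seed spawns per-stage child seeds so that re-running a single
#' stage reproduces its output from a full-pipeline run. The map is a small
#' multiplicative hash kept below 2^31.
#'
#' @param master master integer seed
#' @param stage character stage name
#' @return integer seed in `[1, 2147483628]`
#' @export
#' @examples
#' derive_seed(42, "registry") != derive_seed(42, "vr")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 65521
  v <- ((abs(as.numeric(master)) %% 2147483629) * 48271 + h * 9349) %%
    2147483629
  as.integer(v) + 1L
}

#' Construct the demographic grid for a world configuration
#'
#' The location x year x age-group x sex (x cause) grid that every surface in
#' the pipeline is defined on, in a fixed canonical row order so draw matrices
#' from different stages align row-for-row.
#'
#' @param config a [world_config()] object
#' @param by_cause include a cause column (one grid block per cancer group)?
#' @return a `data.table` keyed in canonical order
#' @export
demographic_grid <- function(config, by_cause = TRUE) {
  ages <- age_table(config$age_breaks)
  cols <- list(
    location = config$locations,
    year = config$years,
    age_start = ages$age_start,
    sex = c("male", "female")
  )
  if (by_cause) cols <- c(list(cause = config$cancer_groups), cols)
  g <- data.table::as.data.table(do.call(data.table::CJ, c(cols, sorted = FALSE)))
  g <- merge(g, ages, by = "age_start", sort = FALSE)
  ord <- intersect(c("cause", "location", "year", "age_start", "sex"), names(g))
  data.table::setorderv(g, ord)
  data.table::setcolorder(g, c(setdiff(ord, "age_start"),
                               "age_start", "age_end"))
  g[]
}

# age interval table from breaks; terminal interval open-ended (Inf)
age_table <- function(breaks) {
  data.table::data.table(
    age_start = breaks[-length(breaks)],
    age_end = breaks[-1]
  )
}

#' Draw surface: an estimate grid with attached posterior draws
#'
#' The pipeline's uncertainty container: a demographic grid plus a numeric
#' matrix of posterior draws (rows = grid cells, columns = draws). All
#' downstream algebra (scaling, division, summation) is done draw-wise on the
#' matrix so uncertainty propagates through every step.
#'
#' @param grid demographic grid `data.table` (one row per cell)
#' @param draws numeric matrix, `nrow(grid)` x `n_draws`
#' @return an object of class `draw_surface`
#' @export
draw_surface <- function(grid, draws) {
  draws <- as.matrix(draws)
  stopifnot(nrow(grid) == nrow(draws), ncol(draws) >= 1)
  structure(list(grid = data.table::as.data.table(grid), draws = draws),
            class = "draw_surface")
}

#' @export
print.draw_surface <- function(x, ...) {
  cat(sprintf("<draw_surface: %d cells x %d draws>\n",
              nrow(x$draws), ncol(x$draws)))
  invisible(x)
}

#' @rdname draw_surface
#' @param x a `draw_surface`
#' @export
n_draws <- function(x) ncol(x$draws)

#' Point estimate (draw mean) of a draw surface
#' @param x a `draw_surface`
#' @return numeric vector, one mean per grid cell
#' @export
surface_mean <- function(x) rowMeans(x$draws)

# check two surfaces share a grid (same key columns, same order)
assert_aligned <- function(a, b) {
  ka <- intersect(c("cause", "location", "year", "age_start", "sex"),
                  names(a$grid))
  kb <- intersect(c("cause", "location", "year", "age_start", "sex"),
                  names(b$grid))
  if (!identical(ka, kb) || nrow(a$grid) != nrow(b$grid) ||
      !isTRUE(all.equal(a$grid[, ka, with = FALSE], b$grid[, kb, with = FALSE],
                        check.attributes = FALSE))) {
    stop("draw surfaces are not on aligned grids", call. = FALSE)
  }
  if (ncol(a$draws) != ncol(b$draws)) {
    stop("draw surfaces have different draw counts", call. = FALSE)
  }
  invisible(TRUE)
}
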
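#' Back-calculate incidence from mortality and MIR
#'
#' Elementwise and per draw: incidence = mortality / MIR, so wherever
#' MIR <= 1 incidence is at least mortality. MIR draws below `eps` are
#' clamped before division and the affected cells reported in the
#' `"clamped_cells"` attribute.
#'
#' @param mortality `draw_surface` of deaths
#' @param mir `draw_surface` of MIRs on the same grid and draw count
#' @param eps divisor floor (default 1e-3)
#' @return `draw_surface` of incident cases
#' @export
incidence_from_mortality <- function(mortality, mir, eps = 1e-3) {
  assert_aligned(mortality, mir)
  low <- mir$draws < eps
  div <- pmax(mir$draws, eps)
  out <- draw_surface(mortality$grid, mortality$draws / div)
  attr(out, "clamped_cells") <- which(rowSums(low) > 0)
  out
}

#' Relative survival curve from a MIR value
#'
#' Linear interpolation between a best-case (high-resource) and a worst-case
#' (untreated) frontier curve: `S(t) = worst(t) + (1 - mir) (best(t) -
#' worst(t))`. A MIR of 1 returns the worst case, a MIR near 0 the best
#' case; monotone non-increasing frontiers give a monotone result.
#'
#' @param mir MIR value(s) in (0, 1\]
#' @param best best-case survival at t = 1..T, non-increasing, in \[0,1\]
#' @param worst worst-case survival, pointwise <= best
#' @return matrix (length(mir) x T) of survival probabilities
#' @export
#' @examples
#' survival_from_mir(0.5, best = rep(0.9, 10), worst = rep(0.1, 10))  # 0.5
survival_from_mir <- function(mir, best, worst) {
  stopifnot(length(best) == length(worst))
  if (any(worst > best + 1e-12)) {
    stop("frontier violation: worst-case survival exceeds best-case",
         call. = FALSE)
  }
  if (any(mir <= 0 | mir > 1)) {
    stop("mir must lie in (0, 1]", call. = FALSE)
  }
  outer(1 - mir, best - worst) + rep(worst, each = length(mir))
}

#' Frontier survival curves fixture
#'
#' Best-case (high-resource) and worst-case (untreated) 10-year relative
#' survival per cancer group. These are synthetic package fixtures with
#' plausible magnitudes, explicitly not any reference implementation's
#' internal curves; unknown causes fall back to the `"default"` rows.
#'
#' @param path CSV override (cause, t, best, worst); default the packaged
#'   fixture
#' @return `data.table` (cause, t, best, worst)
#' @export
frontier_survival <- function(path = system.file("extdata",
                                                 "frontier_survival_synthetic.csv",
                                                 package = "oncoburden")) {
  data.table::fread(path)
}

#' Sequela durations and disability weights fixture
#'
#' Durations (years) and disability weights for the 4 survival phases:
#' diagnosis/treatment, remission, metastatic, terminal. Remission duration
#' is the remainder of prevalent person-time, so its duration is NA.
#' Synthetic fixture with documented placeholder durations (3 months
#' diagnosis/treatment, 4 months metastatic, 1 month terminal).
#'
#' @param path CSV override; default the packaged fixture
#' @return `data.table` (cause, phase, duration_years, disability_weight)
#' @export
sequela_params <- function(path = system.file("extdata",
                                              "sequela_params_synthetic.csv",
                                              package = "oncoburden")) {
  data.table::fread(path)
}

#' Procedure-related disability fixture
#'
#' Lifetime procedure states for the five cancers with procedure-related
#' disability (bladder, breast, colorectal, larynx, prostate): the modeled
#' proportion of patients undergoing the procedure and its disability
#' weight. Synthetic fixture.
#'
#' @param path CSV override; default the packaged fixture
#' @return `data.table` (cause, procedure, proportion, disability_weight)
#' @export
procedure_params <- function(path = system.file("extdata",
                                                "procedure_params_synthetic.csv",
                                                package = "oncoburden")) {
  data.table::fread(path)
}

#' Ten-year prevalence by cohort bookkeeping
#'
#' Every incident cohort contributes `S(t) x exp(-background x t)` surviving
#' person-years at elapsed years t = 1..10 after diagnosis, with cohorts
#' aged across age-group boundaries by annual steps with proportional
#' spill-over (a cohort uniformly distributed over its age interval moves
#' into the next interval in proportion to the overlap after t years).
#' Prevalence in a cell is the sum over elapsed time of the surviving
#' person-years landing in that cell; cohorts diagnosed before the first
#' modeled year are not reconstructed, so early years carry partial
#' prevalence (steady state is reached 10 years in).
#'
#' @param incidence `draw_surface` of incident cases
#' @param survival matrix (cells x 10) of relative survival `S(t)` per
#'   incidence grid cell, rows aligned with `incidence$grid`
#' @param background per-person background (all-cause) mortality rate per
#'   year, scalar or vector aligned with the grid
#' @param horizon follow-up years (default 10)
#' @return `draw_surface` of prevalent person-years
#' @export
ten_year_prevalence <- function(incidence, survival, background = 0,
                                horizon = 10) {
  g <- incidence$grid
  stopifnot(nrow(survival) == nrow(g), ncol(survival) >= horizon)
  bg <- rep(background, length.out = nrow(g))
  years <- sort(unique(g$year))
  ages <- sort(unique(g$age_start))
  ends <- g$age_end[match(ages, g$age_start)]
  width <- ifelse(is.finite(ends), ends - ages, 5)  # terminal group: 5y span
  n <- nrow(g)
  gkey <- g[, paste(cause, location, sex)]
  lut <- data.table::data.table(slice = gkey, year = g$year,
                                age_start = g$age_start, row = seq_len(n))
  prev <- matrix(0, n, ncol(incidence$draws))
  for (t in seq_len(horizon)) {
    contrib <- incidence$draws * (survival[, t] * exp(-bg * t))
    for (ai in seq_along(ages)) {
      # cohort diagnosed in [a, a + width) occupies [a + t, a + width + t)
      a0 <- ages[ai] + t
      a1 <- ages[ai] + width[ai] + t
      src <- which(g$age_start == ages[ai] & (g$year + t) %in% years)
      if (!length(src)) next
      for (aj in seq_along(ages)) {
        b1 <- if (is.finite(ends[aj])) ends[aj] else a1  # open-ended absorbs
        frac <- (min(a1, b1) - max(a0, ages[aj])) / (a1 - a0)
        if (frac <= 0) next
        dst <- lut[data.table::data.table(slice = gkey[src],
                                          year = g$year[src] + t,
                                          age_start = ages[aj]),
                   row, on = c("slice", "year", "age_start")]
        ok <- !is.na(dst)
        if (any(ok)) {
          prev[dst[ok], ] <- prev[dst[ok], ] +
            frac * contrib[src[ok], , drop = FALSE]
        }
      }
    }
  }
  draw_surface(g, prev)
}

#' Partition prevalent person-years into the four survival phases
#'
#' Terminal person-years are deaths x terminal duration; diagnosis/treatment
#' is incident cases x its duration; metastatic (pre-terminal disseminated
#' disease) is deaths x its duration; remission is the remainder. If the
#' attributed phases exceed total prevalence, they are scaled down
#' proportionally so the sum equals prevalence exactly (remission floored at
#' 0) and the deficit is reported in the `"deficit"` attribute.
#'
#' @param prevalence total prevalent person-years (vector over cells)
#' @param deaths deaths (vector)
#' @param cases incident cases (vector)
#' @param durations named numeric: `diagnosis_treatment`, `metastatic`,
#'   `terminal`, in years
#' @return `data.table` with columns `diagnosis_treatment`, `remission`,
#'   `metastatic`, `terminal`; rows sum to `prevalence`
#' @export
partition_sequelae <- function(prevalence, deaths, cases,
                               durations = c(diagnosis_treatment = 0.25,
                                             metastatic = 1 / 3,
                                             terminal = 1 / 12)) {
  stopifnot(all(durations > 0),
            all(c("diagnosis_treatment", "metastatic", "terminal") %in%
                  names(durations)))
  dx <- cases * durations[["diagnosis_treatment"]]
  met <- deaths * durations[["metastatic"]]
  term <- deaths * durations[["terminal"]]
  fixed <- dx + met + term
  over <- fixed > prevalence & fixed > 0
  scale <- ifelse(over, prevalence / pmax(fixed, 1e-300), 1)
  rem <- pmax(prevalence - fixed * scale, 0)
  out <- data.table::data.table(
    diagnosis_treatment = dx * scale,
    remission = rem,
    metastatic = met * scale,
    terminal = term * scale)
  data.table::setattr(out, "deficit", sum(pmax(fixed - prevalence, 0)))
  out[]
}

#' Years lived with disability from a sequela table
#'
#' YLD = sum over phases of prevalent person-years x phase disability
#' weight, plus any procedure-state person-years x procedure disability
#' weight.
#'
#' @param sequelae phase person-years (`data.table` from
#'   [partition_sequelae()], or matrix with phase columns)
#' @param weights named disability weights in \[0,1) per phase column
#' @param procedure_py optional procedure-state person-years (vector)
#' @param procedure_dw disability weight of the procedure state
#' @return numeric YLD vector
#' @export
compute_ylds <- function(sequelae, weights, procedure_py = 0,
                         procedure_dw = 0) {
  stopifnot(all(weights >= 0), all(weights < 1),
            procedure_dw >= 0, procedure_dw < 1)
  sq <- as.matrix(sequelae)
  miss <- setdiff(colnames(sq), names(weights))
  if (length(miss)) {
    stop(sprintf("no disability weight for phase(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  as.numeric(sq %*% weights[colnames(sq)]) + procedure_py * procedure_dw
}

procedure_cancers <- c("bladder", "breast", "colorectal", "larynx",
                       "prostate")

#' Lifetime procedure-state prevalence
#'
#' A simplified proportion model for procedure-related disability (in place
#' of a full Bayesian meta-regression): the proportion of patients who
#' underwent the procedure, smoothed with a 3-year moving average, times the
#' cumulative surviving post-10-year population under background mortality.
#' Only the five cancers with procedure-related disability are accepted.
#'
#' @param cause cancer group (one of bladder, breast, colorectal
#'   (`colon_rectum`), larynx, prostate)
#' @param proportions table (year, proportion in \[0,1\])
#' @param survivors table (year, survivors): 10-year survivors entering the
#'   post-10-year state that year
#' @param background per-person background mortality rate per year
#' @return `data.table` (year, prevalence)
#' @export
procedure_prevalence <- function(cause, proportions, survivors,
                                 background = 0) {
  norm <- if (cause == "colon_rectum") "colorectal" else cause
  if (!norm %in% procedure_cancers) {
    stop(sprintf(
      "procedure-related disability is modeled only for %s (got '%s')",
      paste(procedure_cancers, collapse = ", "), cause), call. = FALSE)
  }
  p <- data.table::as.data.table(proportions)
  if (any(p$proportion < 0 | p$proportion > 1)) {
    stop("proportions must lie in [0,1]", call. = FALSE)
  }
  data.table::setorderv(p, "year")
  k <- nrow(p)
  sm <- vapply(seq_len(k), function(i) {
    mean(p$proportion[max(1, i - 1):min(k, i + 1)])
  }, numeric(1))
  s <- data.table::as.data.table(survivors)
  data.table::setorderv(s, "year")
  m <- merge(s, data.table::data.table(year = p$year, prop = sm),
             by = "year")
  prev <- vapply(seq_len(nrow(m)), function(i) {
    j <- seq_len(i)
    sum(m$survivors[j] * m$prop[j] * exp(-background * (m$year[i] - m$year[j])))
  }, numeric(1))
  data.table::data.table(year = m$year, prevalence = prev)
}
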
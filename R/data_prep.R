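#' Default ICD-to-cause map for the synthetic cancer groups
#'
#' Longest-prefix patterns over ICD-10 (and numeric ICD-9) codes. Every
#' malignant-neoplasm code (ICD-9 140-209, ICD-10 C00-C96) resolves to a
#' cancer group, to the catch-all "other_malignant_neoplasms", or to the
#' EXCLUDED marker; Kaposi sarcoma ("C46") is EXCLUDED because its deaths are
#' predominantly reassigned to HIV/AIDS in cause-of-death processing.
#'
#' @param cancer_groups cause identifiers the map should resolve to
#' @return `data.table` (pattern, cause)
#' @export
default_cause_map <- function(cancer_groups = c("tracheal_bronchus_lung",
                                                "colon_rectum", "stomach",
                                                "breast", "liver")) {
  ref <- list(
    tracheal_bronchus_lung = c("C33", "C34", "162"),
    colon_rectum = c("C18", "C19", "C20", "C21", "153", "154"),
    stomach = c("C16", "151"),
    breast = c("C50", "174", "175"),
    liver = c("C22", "155")
  )
  rows <- lapply(intersect(cancer_groups, names(ref)), function(cz) {
    data.table::data.table(pattern = ref[[cz]], cause = cz)
  })
  extra <- setdiff(cancer_groups, names(ref))
  if (length(extra)) {
    rows <- c(rows, lapply(extra, function(cz) {
      data.table::data.table(pattern = cause_to_icd(cz), cause = cz)
    }))
  }
  map <- data.table::rbindlist(rows)
  map <- rbind(map, data.table::data.table(pattern = "C46",
                                           cause = "EXCLUDED"))
  map[]
}

# is a normalized code within the malignant-neoplasm ranges?
is_cancer_code <- function(code) {
  icd10 <- grepl("^C[0-9]", code)
  num10 <- suppressWarnings(as.numeric(substr(code[icd10], 2, 3)))
  ok10 <- rep(FALSE, length(code))
  ok10[icd10] <- !is.na(num10) & num10 >= 0 & num10 <= 96
  icd9 <- grepl("^[0-9]", code)
  num9 <- suppressWarnings(as.numeric(sub("^([0-9]{3}).*", "\\1", code[icd9])))
  ok9 <- rep(FALSE, length(code))
  ok9[icd9] <- !is.na(num9) & num9 >= 140 & num9 <= 209
  ok10 | ok9
}

#' Map a single ICD code to a cancer cause
#'
#' Deterministic longest-prefix lookup against a cause map. Codes outside the
#' malignant-neoplasm ranges (ICD-9 140-209, ICD-10 C00-C96) return
#' `"NON_CANCER"`; in-range codes with no specific pattern fall back to
#' `"other_malignant_neoplasms"`; mapped exclusions (Kaposi sarcoma C46)
#' return `"EXCLUDED"`. The unspecified-liver garbage code "C22.9" must be
#' redistributed before mapping; [map_vr_deaths()] handles that separation —
#' this low-level lookup resolves "C22.9" by its "C22" prefix.
#'
#' @param code a syntactically valid ICD-9 or ICD-10 code (dots allowed)
#' @param map a cause map from [default_cause_map()]
#' @return the cause identifier, `"EXCLUDED"`, or `"NON_CANCER"`
#' @export
#' @examples
#' map_icd_to_cause("C46", default_cause_map())  # "EXCLUDED"
#' map_icd_to_cause("B20", default_cause_map())  # "NON_CANCER"
map_icd_to_cause <- function(code, map) {
  stopifnot(length(code) == 1)
  norm <- toupper(gsub("\\.", "", trimws(code)))
  if (!grepl("^[A-Z]?[0-9]{2,4}$", norm)) {
    stop(sprintf("malformed ICD code: '%s'", code), call. = FALSE)
  }
  if (!is_cancer_code(norm)) return("NON_CANCER")
  pats <- toupper(gsub("\\.", "", map$pattern))
  hit <- which(vapply(pats, function(p) startsWith(norm, p), logical(1)))
  if (!length(hit)) return("other_malignant_neoplasms")
  map$cause[hit[which.max(nchar(pats[hit]))]]
}

#' Map a vital-registration death table to cancer causes
#'
#' Separates the unspecified-liver garbage code "C22.9" (flagged for
#' redistribution, not mapped), drops EXCLUDED (Kaposi sarcoma) and
#' NON_CANCER rows while counting their deaths, and maps the rest via
#' [map_icd_to_cause()]. Total deaths are conserved across the returned
#' pieces: mapped + garbage + excluded + non-cancer equal the input.
#'
#' @param vr death table (…, icd_code, deaths)
#' @param map cause map
#' @return list: `mapped` (deaths by cause), `garbage` (C22.9 rows),
#'   `excluded_deaths`, `non_cancer_deaths`
#' @export
map_vr_deaths <- function(vr, map) {
  vr <- data.table::as.data.table(vr)
  norm <- toupper(gsub("\\.", "", trimws(vr$icd_code)))
  is_garbage <- norm == "C229"
  garbage <- vr[is_garbage]
  rest <- vr[!is_garbage]
  codes <- unique(rest$icd_code)
  lut <- vapply(codes, map_icd_to_cause, character(1), map = map)
  rest[, cause := lut[icd_code]]
  excluded <- sum(rest[cause == "EXCLUDED", deaths])
  non_cancer <- sum(rest[cause == "NON_CANCER", deaths])
  mapped <- rest[!cause %in% c("EXCLUDED", "NON_CANCER")]
  mapped[, icd_code := NULL]
  keys <- setdiff(names(mapped), "deaths")
  mapped <- mapped[, .(deaths = sum(deaths)), by = keys]
  list(mapped = mapped[], garbage = garbage[],
       excluded_deaths = excluded, non_cancer_deaths = non_cancer)
}

#' Redistribute unspecified liver-cancer (C22.9) deaths
#'
#' The unspecified code covers both primary liver cancer and metastases from
#' other primaries, so its deaths are split across liver cancer and a set of
#' target cancers that metastasize to the liver, by given weights. Totals are
#' conserved exactly and the garbage bucket is emptied.
#'
#' @param deaths_by_cause table (…, cause, deaths) of mapped deaths
#' @param garbage table of C22.9 rows (same demographic columns, deaths)
#' @param proportions named non-negative weights over liver plus target
#'   cancers, summing to 1 within 1e-9; `NULL` uses each target's share of
#'   mapped deaths in the same demographic cell (data-driven default)
#' @return adjusted deaths-by-cause table with the garbage deaths added
#' @export
redistribute_unspecified_liver <- function(deaths_by_cause, garbage,
                                           proportions = NULL) {
  d <- data.table::as.data.table(deaths_by_cause)
  g <- data.table::as.data.table(garbage)
  if (!nrow(g) || sum(g$deaths) == 0) return(d[])
  keys <- setdiff(intersect(names(d), names(g)), c("deaths", "cause",
                                                   "icd_code"))
  if (!is.null(proportions)) {
    if (any(proportions < 0) || abs(sum(proportions) - 1) > 1e-9) {
      stop("redistribution proportions must be non-negative and sum to 1 within 1e-9",
           call. = FALSE)
    }
    add <- g[, .(garbage_deaths = sum(deaths)), by = keys]
    add <- add[, .(cause = names(proportions),
                   extra = garbage_deaths * unname(proportions)),
               by = keys]
  } else {
    # data-driven: proportional to each cause's mapped share in the cell
    shares <- d[, .(cause, share = deaths / sum(deaths)), by = keys]
    shares[is.nan(share), share := 1 / .N, by = keys]
    add <- merge(g[, .(garbage_deaths = sum(deaths)), by = keys], shares,
                 by = keys, allow.cartesian = TRUE)
    add <- add[, .(extra = garbage_deaths * share), by = c(keys, "cause")]
  }
  out <- merge(d, add, by = c(keys, "cause"), all = TRUE)
  out[is.na(deaths), deaths := 0]
  out[is.na(extra), extra := 0]
  out[, deaths := deaths + extra]
  out[, extra := NULL]
  out[]
}

#' Pool counts over adjacent age groups and years
#'
#' Stabilizes sparse-cell ratios before MIR observation building: for every
#' cell, the count is replaced by the sum over a moving window of adjacent
#' age groups (within `age_window` positions) and years (within
#' `year_window`) for the same cause, location and sex. Summing counts
#' before taking ratios removes most of the ratio noise (and with it the
#' censoring bias of capping noisy ratios at 1) at the cost of some
#' smoothing across age and time.
#'
#' @param tab count table (…, cause, location, year, age_start, sex, and the
#'   value column)
#' @param value_col name of the count column to pool
#' @param age_window age-group positions on each side (default 1)
#' @param year_window years on each side (default 2)
#' @return the table with the value column pooled (other columns preserved)
#' @export
pool_adjacent_counts <- function(tab, value_col, age_window = 1,
                                 year_window = 2) {
  d <- data.table::as.data.table(tab)
  ages <- sort(unique(d$age_start))
  d[, a_i := match(age_start, ages)]
  off <- data.table::CJ(da = -age_window:age_window,
                        dy = -year_window:year_window)
  src <- d[, .(cause, location, sex, a_i, year, v = get(value_col))]
  # windows shrink symmetrically at the range boundaries: a one-sided
  # window at the first or last year would pull a trending series toward
  # its interior and bias the edge ratios
  aw <- pmin(age_window, d$a_i - 1L, length(ages) - d$a_i)
  yw <- pmin(year_window, d$year - min(d$year), max(d$year) - d$year)
  pooled <- numeric(nrow(d))
  for (k in seq_len(nrow(off))) {
    hit <- src[d[, .(cause, location, sex, a_i = a_i + off$da[k],
                     year = year + off$dy[k])],
               v, on = c("cause", "location", "sex", "a_i", "year")]
    ok <- abs(off$da[k]) <= aw & abs(off$dy[k]) <= yw
    pooled <- pooled + ifelse(is.na(hit) | !ok, 0, hit)
  }
  d[, (value_col) := pooled]
  d[, a_i := NULL]
  d[]
}

#' Build MIR observations from matched registry and death tables
#'
#' Only demographic cells present in both the registry incidence table and
#' the mapped mortality table yield observations: MIR = deaths / cases,
#' clamped to (epsilon, cap\]; the effective sample size is the case count.
#' Matched cells with zero cases are skipped with a warning.
#'
#' @param registry registry table (…, cause, cases, person_years)
#' @param deaths mapped death table (…, cause, deaths)
#' @param cap MIR upper bound (default 1)
#' @param eps lower clamp (default 1e-4)
#' @return `data.table` of observations (demographic keys, mir, ess)
#' @export
build_mir_observations <- function(registry, deaths, cap = 1, eps = 1e-4) {
  keys <- setdiff(intersect(names(registry), names(deaths)),
                  c("cases", "deaths", "person_years"))
  obs <- merge(data.table::as.data.table(registry),
               data.table::as.data.table(deaths), by = keys)
  zero <- obs$cases == 0
  if (any(zero)) {
    warning(sprintf("%d matched cells with zero cases skipped", sum(zero)),
            call. = FALSE)
    obs <- obs[!zero]
  }
  obs[, mir := pmin(pmax(deaths / cases, eps), cap)]
  obs[, ess := cases]
  obs[, c("cases", "deaths",
          intersect("person_years", names(obs))) := NULL]
  obs[]
}

#' Stabilized MIR observations via count pooling
#'
#' Matches registry cases with mapped deaths cell by cell, pools both counts
#' over the same moving window of adjacent age groups and years (identical
#' availability for numerator and denominator), and then forms the MIR
#' ratios. This is the smoothing-across-age-and-time pass applied at the
#' count level, where ratio noise and cap-censoring bias are smallest.
#'
#' @inheritParams build_mir_observations
#' @param age_window,year_window pooling window half-widths
#' @return `data.table` of observations (demographic keys, mir, ess)
#' @export
stabilized_mir_observations <- function(registry, deaths, cap = 1,
                                        eps = 1e-4, age_window = 1,
                                        year_window = 2) {
  keys <- setdiff(intersect(names(registry), names(deaths)),
                  c("cases", "deaths", "person_years"))
  m <- merge(data.table::as.data.table(registry),
             data.table::as.data.table(deaths), by = keys)
  m <- pool_adjacent_counts(m, "cases", age_window, year_window)
  m <- pool_adjacent_counts(m, "deaths", age_window, year_window)
  build_mir_observations(m[, c(keys, "cases"), with = FALSE],
                         m[, c(keys, "deaths"), with = FALSE],
                         cap = cap, eps = eps)
}
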
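# Cohort cross-tabulations: event frequencies stratified by patient
# characteristics, and the per-drug characteristics table.

age_bands_fine <- c("18-44", "45-54", "55-64", "65+")
age_bands_coarse <- c("<65", ">=65")

.age_band <- function(age, bands = c("fine", "coarse")) {
  bands <- match.arg(bands)
  if (bands == "fine") {
    cut(age, breaks = c(18, 45, 55, 65, Inf), right = FALSE,
        labels = age_bands_fine)
  } else {
    cut(age, breaks = c(-Inf, 65, Inf), right = FALSE,
        labels = age_bands_coarse)
  }
}

.year_band <- function(year) {
  cut(year, breaks = c(2007, 2010, 2015, 2020, 2024), right = FALSE,
      labels = c("2007-2009", "2010-2014", "2015-2019", "2020-2023"))
}

# half-up rounding for percentage display (IEC round() rounds half to even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stratum label per report for a given axis; NA = missing stratum
.report_strata <- function(rep1, axis, age_bands) {
  switch(axis,
    sex = ifelse(rep1$sex == "unspecified", NA_character_, rep1$sex),
    age_band = as.character(.age_band(rep1$age_years, age_bands)),
    year_band = as.character(.year_band(rep1$reporting_year)),
    reporter = ifelse(rep1$reporter == "unspecified", NA_character_,
                      rep1$reporter),
    indication = ifelse(rep1$indication %in% c("missing"), NA_character_,
                        rep1$indication),
    stop("unknown axis: ", axis, call. = FALSE)
  )
}

#' Cross-tabulate event frequencies by a patient characteristic
#'
#' Counts, for every tracked event PT, the reports in each stratum of
#' `axis`, with percentages over the stratum's report denominator. Reports
#' missing the characteristic form an implicit missing stratum excluded
#' from the percentage denominators. The `outcome` axis tabulates the
#' serious-outcome flags instead of event PTs.
#'
#' @param reports Reports tibble.
#' @param axis One of `"sex"`, `"age_band"`, `"year_band"`, `"reporter"`,
#'   `"indication"`, `"outcome"`.
#' @param age_bands `"coarse"` (<65 / >=65, default) or `"fine"`
#'   (18-44 / 45-54 / 55-64 / 65+); only used for `axis = "age_band"`.
#' @return A tibble (item, stratum, count, percent) with a `denominators`
#'   attribute (tibble stratum/denominator). Percentages are half-up
#'   rounded to one decimal.
#' @export
crosstab <- function(reports, axis, age_bands = "coarse") {
  x <- tibble::as_tibble(reports)
  per <- x |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      drug = .data$drug[1], sex = .data$sex[1],
      age_years = .data$age_years[1],
      reporting_year = .data$reporting_year[1],
      reporter = .data$reporter[1], indication = .data$indication[1],
      outcomes = .data$outcomes[1],
      events = list(unique(.data$event_pt)), .groups = "drop")

  if (axis == "outcome") {
    oc <- outcomes_to_list(per$outcomes)
    strata <- pv_levels$outcome
    denom <- vapply(strata, function(s) {
      sum(vapply(oc, function(v) s %in% v, logical(1)))
    }, numeric(1))
    in_stratum <- function(s) vapply(oc, function(v) s %in% v, logical(1))
  } else {
    lab <- .report_strata(per, axis, age_bands)
    strata <- switch(axis,
      sex = c("female", "male"),
      age_band = if (age_bands == "fine") age_bands_fine else age_bands_coarse,
      year_band = levels(.year_band(2007L)),
      reporter = c("consumer", "healthcare_professional"),
      indication = c("diabetes_mellitus", "obesity", "weight_loss", "other"))
    denom <- vapply(strata, function(s) sum(!is.na(lab) & lab == s),
                    numeric(1))
    in_stratum <- function(s) !is.na(lab) & lab == s
  }

  items <- sort(setdiff(unique(unlist(per$events)), other_event_pt))
  rows <- list()
  for (s in strata) {
    sel <- in_stratum(s)
    for (it in items) {
      cnt <- sum(sel & vapply(per$events, function(v) it %in% v, logical(1)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        item = it, stratum = s, count = cnt,
        percent = if (denom[[s]] > 0) {
          round_half_up(100 * cnt / denom[[s]], 1)
        } else NA_real_)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "denominators") <- tibble::tibble(
    stratum = strata, denominator = unname(denom))
  attr(out, "axis") <- axis
  out
}

#' Per-drug cohort characteristics table
#'
#' One row per characteristic level and drug (plus an `"all"` column
#' pooling the four drugs): sex, fine age bands, reporting-year bands,
#' reporter type, indication and serious outcomes, with percentages over
#' the per-drug report totals (missing values excluded from denominators
#' section-wise).
#'
#' @param reports Reports tibble.
#' @return Tidy tibble (section, level, drug, count, percent).
#' @export
cohort_table <- function(reports) {
  x <- tibble::as_tibble(reports)
  per <- x |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(drug = .data$drug[1], sex = .data$sex[1],
                     age_years = .data$age_years[1],
                     reporting_year = .data$reporting_year[1],
                     reporter = .data$reporter[1],
                     indication = .data$indication[1],
                     outcomes = .data$outcomes[1], .groups = "drop")
  per$age_band <- as.character(.age_band(per$age_years, "fine"))
  per$year_band <- as.character(.year_band(per$reporting_year))
  oc <- outcomes_to_list(per$outcomes)

  sections <- list(
    sex = list(values = per$sex, levels = c("female", "male", "unspecified"),
               missing_excluded = FALSE),
    age_band = list(values = per$age_band, levels = age_bands_fine,
                    missing_excluded = TRUE),
    year_band = list(values = per$year_band,
                     levels = levels(.year_band(2007L)),
                     missing_excluded = TRUE),
    reporter = list(values = per$reporter,
                    levels = c("consumer", "healthcare_professional"),
                    missing_excluded = TRUE),
    indication = list(values = per$indication,
                      levels = c("diabetes_mellitus", "obesity",
                                 "weight_loss"),
                      missing_excluded = TRUE)
  )
  drugs <- c(sort(unique(per$drug)), "all")
  rows <- list()
  for (d in drugs) {
    sel_d <- if (d == "all") rep(TRUE, nrow(per)) else per$drug == d
    n_d <- sum(sel_d)
    for (sec in names(sections)) {
      s <- sections[[sec]]
      for (lev in s$levels) {
        cnt <- sum(sel_d & !is.na(s$values) & s$values == lev)
        rows[[length(rows) + 1]] <- tibble::tibble(
          section = sec, level = lev, drug = d, count = cnt,
          percent = if (n_d > 0) round_half_up(100 * cnt / n_d, 1) else NA_real_)
      }
    }
    for (o in pv_levels$outcome) {
      cnt <- sum(sel_d & vapply(oc, function(v) o %in% v, logical(1)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        section = "outcome", level = o, drug = d, count = cnt,
        percent = if (n_d > 0) round_half_up(100 * cnt / n_d, 1) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}
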
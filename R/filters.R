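# Inclusion/exclusion pipeline: deduplication followed by a fixed sequence
# of filters, every stage recorded in an attrition log.

#' Deduplicate spontaneous reports
#'
#' Keeps, for each `case_id`, only the rows of its highest `case_version`
#' (later versions supersede earlier submissions of the same case), then
#' collapses exact full-record duplicates to a single row. Order-invariant:
#' the retained set does not depend on input row order.
#'
#' @param x Reports tibble.
#' @param key `"case_version"` (default) or `"full_record"` to skip the
#'   version rule and only drop identical rows.
#' @return Deduplicated reports, sorted by report id, drug and event PT.
#' @export
deduplicate_reports <- function(x, key = c("case_version", "full_record")) {
  key <- match.arg(key)
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(x)
  if (key == "case_version") {
    x <- x |>
      dplyr::group_by(.data$case_id) |>
      dplyr::filter(.data$case_version == max(.data$case_version)) |>
      dplyr::ungroup()
  }
  x |>
    dplyr::distinct(dplyr::across(dplyr::all_of(report_columns)),
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$report_id, .data$drug, .data$event_pt)
}

#' Filtering configuration
#'
#' Captures the study inclusion rules: primary-suspect role, the four
#' retained drugs, gastrointestinal events only, US reports, exclusion of
#' multi-drug (combination) reports, completeness requirements and the
#' study window.
#'
#' @param required_role Role code a row must carry (default
#'   `"primary_suspect"`); `NULL` disables the stage.
#' @param drugs Drugs retained (default the four class members).
#' @param soc_whitelist System organ classes retained (default
#'   gastrointestinal); `NULL` disables.
#' @param countries Reporter countries retained (default `"US"`); `NULL`
#'   disables.
#' @param exclude_combination_reports Drop whole reports whose suspect-drug
#'   set (primary or secondary suspect) contains more than one distinct
#'   drug (default `TRUE`).
#' @param drop_missing Fields whose missingness excludes a row (default
#'   drug, event PT, country).
#' @param year_range Length-2 inclusive calendar-year window (default
#'   `c(2007, 2023)`); `NULL` disables.
#' @param dedup_key Passed to [deduplicate_reports()].
#' @return A list of class `pv_filter_config`.
#' @export
filter_config <- function(required_role = "primary_suspect",
                          drugs = glp1_drugs(),
                          soc_whitelist = "gastrointestinal",
                          countries = "US",
                          exclude_combination_reports = TRUE,
                          drop_missing = c("drug", "event_pt", "country"),
                          year_range = c(2007, 2023),
                          dedup_key = "case_version") {
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2, year_range[1] <= year_range[2])
  }
  structure(list(
    required_role = required_role, drugs = drugs,
    soc_whitelist = soc_whitelist, countries = countries,
    exclude_combination_reports = isTRUE(exclude_combination_reports),
    drop_missing = drop_missing, year_range = year_range,
    dedup_key = dedup_key
  ), class = "pv_filter_config")
}

#' Apply the inclusion/exclusion pipeline
#'
#' Stages run in a fixed order -- deduplication, role code, drug set, SOC
#' whitelist, country, combination-report exclusion, missing-field
#' exclusion, year range -- and each stage's attrition is logged. The
#' combination flag is computed on the deduplicated input (before the role
#' filter discards the secondary-suspect rows that reveal multi-drug
#' reports). A configuration that excludes everything yields an empty
#' result with a complete log, not an error. Idempotent.
#'
#' @param x Reports tibble.
#' @param config A [filter_config()].
#' @return A list with `reports` (retained rows) and `log` (tibble of
#'   stage / reports_in / reports_excluded / reports_out).
#' @export
apply_filters <- function(x, config = filter_config()) {
  stopifnot(inherits(config, "pv_filter_config"))
  x <- tibble::as_tibble(x)
  log <- list()
  stage <- function(name, before, after) {
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = name, reports_in = nrow(before),
      reports_excluded = nrow(before) - nrow(after),
      reports_out = nrow(after))
    after
  }

  cur <- stage("deduplicate", x, deduplicate_reports(x, config$dedup_key))

  # suspect-drug multiplicity per report, measured before role filtering
  combo_ids <- if (config$exclude_combination_reports) {
    cur |>
      dplyr::filter(.data$role_code %in% c("primary_suspect",
                                           "secondary_suspect")) |>
      dplyr::group_by(.data$report_id) |>
      dplyr::summarise(k = dplyr::n_distinct(.data$drug), .groups = "drop") |>
      dplyr::filter(.data$k > 1) |>
      dplyr::pull(.data$report_id)
  } else {
    character(0)
  }

  if (!is.null(config$required_role)) {
    cur <- stage("role_code", cur,
                 dplyr::filter(cur, .data$role_code %in% config$required_role))
  }
  cur <- stage("drug", cur, dplyr::filter(cur, .data$drug %in% config$drugs))
  if (!is.null(config$soc_whitelist)) {
    cur <- stage("soc", cur,
                 dplyr::filter(cur, .data$event_soc %in% config$soc_whitelist |
                                 .data$event_pt == other_event_pt))
  }
  if (!is.null(config$countries)) {
    cur <- stage("country", cur,
                 dplyr::filter(cur, .data$country %in% config$countries))
  }
  if (config$exclude_combination_reports) {
    cur <- stage("combination", cur,
                 dplyr::filter(cur, !(.data$report_id %in% combo_ids)))
  }
  if (length(config$drop_missing) > 0) {
    keep <- rep(TRUE, nrow(cur))
    for (f in intersect(config$drop_missing, names(cur))) {
      v <- cur[[f]]
      keep <- keep & !is.na(v) & (!is.character(v) | nzchar(v))
    }
    cur <- stage("missing_fields", cur, cur[keep, , drop = FALSE])
  }
  if (!is.null(config$year_range)) {
    cur <- stage("year_range", cur,
                 dplyr::filter(cur, !is.na(.data$reporting_year),
                               .data$reporting_year >= config$year_range[1],
                               .data$reporting_year <= config$year_range[2]))
  }

  log <- dplyr::bind_rows(log)
  class(log) <- c("pv_filter_log", class(log))
  list(reports = cur, log = log)
}

#' Serialize an attrition log
#'
#' @param log The `log` element returned by [apply_filters()].
#' @param path Destination; `.json` gets a JSON array, anything else a
#'   human-readable text rendering.
#' @return `path`, invisibly.
#' @export
write_filter_log <- function(log, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(log), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    writeLines(c("attrition log", sprintf(
      "%-16s in=%-8d excluded=%-8d out=%d",
      log$stage, log$reports_in, log$reports_excluded, log$reports_out)),
      path)
  }
  invisible(path)
}

#' @export
print.pv_filter_log <- function(x, ...) {
  cat("attrition log:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-16s in=%-8d excluded=%-8d out=%d\n", x$stage[i],
                x$reports_in[i], x$reports_excluded[i], x$reports_out[i]))
  }
  invisible(x)
}
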
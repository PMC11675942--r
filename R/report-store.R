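# Normalized report table: one row per report-drug-event, the exchange
# format every pipeline stage consumes and produces.

report_columns <- c(
  "report_id", "case_id", "case_version", "drug", "role_code", "event_pt",
  "event_soc", "sex", "age_years", "reporting_year", "reporter", "country",
  "indication", "outcomes"
)

# placeholder PT used for reports that carry none of the tracked events;
# keeps zero-event reports in the denominators (b/d cells)
other_event_pt <- "other_gi_event"

#' Validate a collection of spontaneous reports
#'
#' Checks the normalized report table contract: all mandatory columns
#' present, ages (when recorded) within 0-130 years, reporting years within
#' 2005-2030, and enum fields restricted to their vocabularies.
#'
#' @param x A data frame of reports (one row per report-drug-event).
#' @return `x`, invisibly coerced to a tibble, or an error.
#' @export
validate_reports <- function(x) {
  missing_cols <- setdiff(report_columns, names(x))
  if (length(missing_cols) > 0) {
    stop("reports are missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  age <- x$age_years
  if (any(!is.na(age) & (age < 0 | age > 130))) {
    stop("age_years outside [0, 130]", call. = FALSE)
  }
  yr <- x$reporting_year
  if (any(!is.na(yr) & (yr < 2005 | yr > 2030))) {
    stop("reporting_year outside [2005, 2030]", call. = FALSE)
  }
  for (f in c("drug", "role_code", "sex", "reporter", "indication")) {
    bad <- !is.na(x[[f]]) & !(x[[f]] %in% pv_levels[[f]])
    if (any(bad)) {
      stop("invalid ", f, " value(s): ",
           paste(unique(x[[f]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(x)
}

# split/join helpers for the outcomes set column (";"-separated, sorted)
outcomes_to_list <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(v) sort(v[nzchar(v)]))
}
outcomes_to_string <- function(lst) {
  vapply(lst, function(v) paste(sort(unique(v)), collapse = ";"), character(1))
}

#' Read a normalized report table
#'
#' Reads a delimited text file (comma by default, tab accepted) holding one
#' row per report-drug-event. Enum fields are canonicalised: values not in
#' the vocabulary -- after applying any `dialect` recodings such as
#' `list(sex = c(F = "female"))` -- fall back to `"other"`/`"unspecified"`
#' and are counted in the attached ingest log. Unparseable ages or years
#' become missing; the row is retained.
#'
#' @param path File to read.
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (`.tsv` = tab, otherwise comma).
#' @param dialect Named list of per-field recode vectors applied before
#'   vocabulary matching, e.g. `list(sex = c(F = "female", M = "male"))`.
#' @return A tibble of reports with an `ingest_log` attribute (tibble of
#'   field/issue/count).
#' @export
read_reports <- function(path, delim = NULL, dialect = list()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"),
    show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(report_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  log <- list()
  note <- function(field, issue, n) {
    if (n > 0) log[[length(log) + 1]] <<- tibble::tibble(
      field = field, issue = issue, n = as.integer(n))
  }

  recode <- function(x, field) {
    map <- dialect[[field]]
    if (!is.null(map)) {
      hit <- x %in% names(map)
      x[hit] <- unname(map[x[hit]])
    }
    x
  }
  num_field <- function(x, field, lo, hi) {
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & (is.na(v) | v < lo | v > hi)
    note(field, "unparseable_or_out_of_range", sum(bad))
    v[bad] <- NA_real_
    v
  }

  out <- tibble::tibble(
    report_id = raw$report_id,
    case_id = raw$case_id,
    case_version = {
      v <- suppressWarnings(as.integer(raw$case_version))
      v[is.na(v)] <- 1L
      v
    },
    drug = NA_character_, role_code = NA_character_,
    event_pt = raw$event_pt, event_soc = raw$event_soc,
    sex = NA_character_,
    age_years = num_field(recode(raw$age_years, "age_years"), "age_years", 0, 130),
    reporting_year = {
      y <- num_field(raw$reporting_year, "reporting_year", 2005, 2030)
      as.integer(y)
    },
    reporter = NA_character_, country = toupper(trimws(raw$country)),
    indication = NA_character_,
    outcomes = ifelse(is.na(raw$outcomes), "", raw$outcomes)
  )
  for (f in c("drug", "role_code", "sex", "reporter", "indication")) {
    fallback <- switch(f, drug = "other", role_code = "concomitant",
                       indication = "other", "unspecified")
    m <- .match_level(recode(raw[[f]], f), pv_levels[[f]], fallback)
    note(f, "mapped_to_fallback", m$n_mapped)
    out[[f]] <- m$value
  }
  out$outcomes <- outcomes_to_string(outcomes_to_list(out$outcomes))
  validate_reports(out)
  attr(out, "ingest_log") <- if (length(log) > 0) {
    dplyr::bind_rows(log)
  } else {
    tibble::tibble(field = character(), issue = character(), n = integer())
  }
  out
}

#' Write a normalized report table
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(x, f))` returns
#' the same report set field-for-field.
#'
#' @param x Reports tibble.
#' @param path Destination file.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_reports <- function(x, path, delim = ",") {
  x <- validate_reports(x)
  readr::write_delim(x[report_columns], path, delim = delim, na = "")
  invisible(path)
}
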
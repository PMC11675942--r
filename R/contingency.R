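# 2x2 contingency tables for drug x event pairs against the pooled
# within-class comparator:
#
#               event   other events
#   target drug   a         b          a+b = target report total
#   comparator    c         d          c+d = comparator report total

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Nonnegative counts: target drug with/without the event,
#'   comparator pool with/without the event.
#' @param drug,event Labels.
#' @param unit Counting unit the cells were derived under.
#' @return An object of class `pv_2x2`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              event = NA_character_, unit = "report") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells))) stop("2x2 cells must not be missing", call. = FALSE)
  if (any(cells < 0)) stop("2x2 cells must be nonnegative", call. = FALSE)
  n <- sum(cells)
  if (n <= 0) stop("2x2 table is empty (N = 0)", call. = FALSE)
  structure(list(drug = drug, event = event, a = a, b = b, c = c, d = d,
                 N = n, unit = unit), class = "pv_2x2")
}

#' Build a 2x2 table from report-level data
#'
#' `a` counts the target drug's reports carrying the event, `b` its
#' remaining reports; `c` and `d` are the same over the pooled comparator
#' drugs. The default counting unit is the report: a report mentioning the
#' event on several rows counts once, and its presence in one event's `a`
#' cell does not remove it from another event's. `unit = "row"` counts
#' report-drug-event rows instead.
#'
#' @param reports Reports tibble (normally post-[apply_filters()]).
#' @param drug Target drug.
#' @param event Target event PT.
#' @param comparator Drugs pooled as the comparator; defaults to the other
#'   retained class members. Must exclude the target.
#' @param unit `"report"` (default) or `"row"`.
#' @return A `pv_2x2`.
#' @export
contingency_from_reports <- function(reports, drug, event,
                                     comparator = setdiff(glp1_drugs(), drug),
                                     unit = c("report", "row")) {
  unit <- match.arg(unit)
  if (length(comparator) == 0) stop("comparator is empty", call. = FALSE)
  if (drug %in% comparator) {
    stop("target drug must not be in the comparator pool", call. = FALSE)
  }
  x <- dplyr::filter(reports, .data$drug %in% c(!!drug, !!comparator))
  if (unit == "report") {
    per <- x |>
      dplyr::group_by(.data$report_id, .data$drug) |>
      dplyr::summarise(has = any(.data$event_pt == !!event),
                       .groups = "drop")
    tgt <- per$drug == drug
    a <- sum(per$has[tgt]); b <- sum(!per$has[tgt])
    cc <- sum(per$has[!tgt]); d <- sum(!per$has[!tgt])
  } else {
    tgt <- x$drug == drug
    hit <- x$event_pt == event
    a <- sum(tgt & hit); b <- sum(tgt & !hit)
    cc <- sum(!tgt & hit); d <- sum(!tgt & !hit)
  }
  contingency_table(a, b, cc, d, drug = drug, event = event, unit = unit)
}

#' Build a 2x2 table from the packaged count fixture
#'
#' `a` is the fixture's case count for the pair, `b` the drug's report
#' total minus `a`; `c` and `d` pool the other three drugs. Any missing
#' case count among the four drugs is an error naming the pair -- the
#' fixture never imputes.
#'
#' @param fixture A [count_fixture()].
#' @param drug,event Target pair.
#' @param use_corrections Apply the packaged count corrections (erratum
#'   repairs) to comparator cells (default `TRUE`; the target drug's own
#'   printed count is always used as printed).
#' @return A `pv_2x2`.
#' @export
contingency_from_fixture <- function(fixture, drug, event,
                                     use_corrections = TRUE) {
  stopifnot(inherits(fixture, "pv_count_fixture"))
  if (!drug %in% fixture$drugs) stop("unknown drug: ", drug, call. = FALSE)
  cs_raw <- fixture_cases(fixture, event, use_corrections = FALSE)
  cs <- fixture_cases(fixture, event, use_corrections = use_corrections)
  miss <- names(cs)[is.na(cs)]
  if (length(miss) > 0) {
    stop(sprintf("fixture lacks case counts for event '%s', drug(s) %s",
                 event, paste(miss, collapse = ", ")), call. = FALSE)
  }
  tot <- fixture$drug_totals
  a <- unname(cs_raw[drug])
  b <- unname(tot[drug]) - a
  comp <- setdiff(fixture$drugs, drug)
  cc <- sum(cs[comp])
  d <- sum(tot[comp]) - cc
  contingency_table(a, b, cc, d, drug = drug, event = event, unit = "report")
}

#' Swap target and comparator of a 2x2 table
#'
#' Maps (a, b, c, d) to (c, d, a, b); disproportionality statistics of the
#' swapped table are the reciprocals of the originals.
#'
#' @param table A `pv_2x2`.
#' @return A `pv_2x2`.
#' @export
swap_comparator <- function(table) {
  contingency_table(table$c, table$d, table$a, table$b,
                    drug = paste0("not_", table$drug), event = table$event,
                    unit = table$unit)
}

#' @export
print.pv_2x2 <- function(x, ...) {
  cat(sprintf("2x2 [%s x %s] (%s-level)\n", x$drug, x$event, x$unit))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c(x$drug, "comparator"),
                              c(x$event, "other")))
  print(m)
  invisible(x)
}

#' @export
as.data.frame.pv_2x2 <- function(x, ...) {
  data.frame(drug = x$drug, event = x$event, a = x$a, b = x$b, c = x$c,
             d = x$d, N = x$N, unit = x$unit)
}
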
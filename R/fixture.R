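# The packaged count fixture: per-drug GI report totals and per-event case
# counts printed by the published study, with its printed statistics and a
# curated list of cells known not to reproduce from those counts.

#' Load the packaged published-count fixture
#'
#' Returns the per-drug gastrointestinal report totals (4401 / 4126 / 4075 /
#' 3966 for exenatide, liraglutide, dulaglutide, semaglutide; 16,568 in
#' total), the per-event per-drug case counts, the printed ROR/PRR/IC025 and
#' adjusted-regression values, a correction list (the semaglutide vomiting
#' count erratum), and the known-discrepancy table consulted by
#' [reproduce_signal_table()].
#'
#' @param path Fixture JSON; defaults to the copy installed with the
#'   package.
#' @return A list of class `pv_count_fixture` with elements `drugs`,
#'   `drug_totals` (named numeric), `total_reports`, `cases` (tibble event
#'   x drug, `kind`, `provenance`), `printed` (long tibble event/drug/stat/
#'   value), `corrections`, `discrepancies`.
#' @export
count_fixture <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "paper_counts.json", package = "glp1pv",
                        mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path)
  drugs <- unlist(raw$drugs)
  totals <- unlist(raw$drug_totals)[drugs]

  cases <- dplyr::bind_rows(lapply(raw$events, function(e) {
    cs <- lapply(drugs, function(d) {
      v <- e$cases[[d]]
      if (is.null(v)) NA_real_ else as.numeric(v)
    })
    names(cs) <- drugs
    tibble::as_tibble(c(list(event = e$event, kind = e$kind), cs,
                        list(provenance = e$provenance)))
  }))

  printed <- dplyr::bind_rows(lapply(raw$events, function(e) {
    dplyr::bind_rows(lapply(drugs, function(d) {
      p <- e$printed[[d]]
      tibble::tibble(event = e$event, drug = d,
                     stat = names(p),
                     printed = vapply(p, function(v) {
                       if (is.null(v)) NA_real_ else as.numeric(v)
                     }, numeric(1)))
    }))
  }))

  disc <- dplyr::bind_rows(lapply(raw$known_discrepancies, tibble::as_tibble))
  corr <- dplyr::bind_rows(lapply(raw$corrections, tibble::as_tibble))

  fix <- structure(list(
    drugs = drugs, drug_totals = totals,
    total_reports = as.integer(raw$total_reports),
    cases = cases, printed = printed,
    corrections = corr, discrepancies = disc,
    description = raw$description
  ), class = "pv_count_fixture")
  validate_fixture(fix)
  fix
}

validate_fixture <- function(fix) {
  stopifnot(identical(unname(fix$drugs), glp1_drugs()))
  if (sum(fix$drug_totals) != fix$total_reports) {
    stop("fixture drug totals do not sum to the recorded report total",
         call. = FALSE)
  }
  invisible(fix)
}

# case count for (event, drug); optionally with the packaged corrections
# applied (used for comparator cells tainted by a printed erratum)
fixture_cases <- function(fix, event, use_corrections = FALSE) {
  row <- fix$cases[fix$cases$event == event, , drop = FALSE]
  if (nrow(row) != 1) stop("event not in fixture: ", event, call. = FALSE)
  cs <- unlist(row[fix$drugs])
  if (use_corrections && nrow(fix$corrections) > 0) {
    hits <- fix$corrections[fix$corrections$event == event, , drop = FALSE]
    for (i in seq_len(nrow(hits))) {
      cs[hits$drug[i]] <- hits$corrected_cases[i]
    }
  }
  cs
}

#' @export
print.pv_count_fixture <- function(x, ...) {
  cat("packaged count fixture:", x$total_reports, "reports over",
      length(x$drugs), "drugs,", nrow(x$cases), "events\n")
  cat("  totals:", paste(sprintf("%s=%d", x$drugs,
                                 as.integer(x$drug_totals)),
                         collapse = ", "), "\n")
  cat("  known-discrepancy rules:", nrow(x$discrepancies), "\n")
  invisible(x)
}
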
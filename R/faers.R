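# Minimal reader for the quarterly FAERS ASCII dialect: "$"-delimited
# DEMO/DRUG/REAC/OUTC/INDI files sharing a primaryid key. Only the columns
# the pipeline needs are interpreted; unknown columns are ignored.

.faers_files <- c("DEMO", "DRUG", "REAC", "OUTC", "INDI")

.read_dollar <- function(dir, stem) {
  hits <- list.files(dir, pattern = paste0("^", stem, ".*\\.(txt|TXT)$"),
                     full.names = TRUE)
  if (length(hits) == 0) {
    stop("FAERS directory is missing a ", stem, " file: ", dir, call. = FALSE)
  }
  raw <- readr::read_delim(hits[[1]], delim = "$",
                           col_types = readr::cols(.default = readr::col_character()),
                           na = c("", "NA"), show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- tolower(names(raw))
  raw
}

# FAERS age units -> years
.age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(ifelse(is.na(age_cod), "YR", age_cod))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, DY = 1 / 365.25, WK = 1 / 52.1775)
  m <- unname(mult[cod])
  out <- v * m
  out[is.na(m)] <- NA_real_
  out[!is.na(out) & (out < 0 | out > 130)] <- NA_real_
  out
}

.outc_map <- c(DS = "disability", LT = "life_threatening",
               HO = "hospitalization", DE = "death")
.occp_map <- c(CN = "consumer", MD = "healthcare_professional",
               PH = "healthcare_professional", OT = "healthcare_professional",
               HP = "healthcare_professional", LW = "unspecified")
.role_map <- c(PS = "primary_suspect", SS = "secondary_suspect",
               C = "concomitant", I = "interacting")

.indi_normalize <- function(x) {
  key <- tolower(trimws(x))
  out <- rep("other", length(key))
  out[grepl("diabetes", key)] <- "diabetes_mellitus"
  out[grepl("obesity", key)] <- "obesity"
  out[grepl("weight", key)] <- "weight_loss"
  out[is.na(x)] <- "missing"
  out
}

#' Read a directory of FAERS-style ASCII quarter files
#'
#' Joins "$"-delimited DEMO, DRUG, REAC, OUTC and INDI files on `primaryid`
#' and emits one report row per (case, drug row, reaction PT) combination.
#' Outcome codes and indications are aggregated per case; DRUG/REAC/OUTC/INDI
#' rows without a DEMO match are dropped and counted in the `orphans`
#' attribute. Output ordering is deterministic: sorted by report id, drug
#' and event PT. Duplicate case versions are retained here and resolved by
#' [deduplicate_reports()].
#'
#' @param dir Directory holding the five files (name stem match, e.g.
#'   `DEMO23Q1.txt`).
#' @param gi_pts Character vector of preferred terms assigned to the
#'   gastrointestinal system organ class; all other PTs get SOC `"other"`.
#' @return A tibble of reports (see [validate_reports()]) with attributes
#'   `orphans` (named count of unmatched rows per file).
#' @export
read_faers_ascii <- function(dir, gi_pts = gi_pt_list()) {
  if (!dir.exists(dir)) stop("directory not found: ", dir, call. = FALSE)
  demo <- .read_dollar(dir, "DEMO")
  drug <- .read_dollar(dir, "DRUG")
  reac <- .read_dollar(dir, "REAC")
  outc <- .read_dollar(dir, "OUTC")
  indi <- .read_dollar(dir, "INDI")

  need <- function(df, cols, stem) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      stop(stem, " file is missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  need(demo, c("primaryid", "caseid", "caseversion"), "DEMO")
  need(drug, c("primaryid", "drugname", "role_cod"), "DRUG")
  need(reac, c("primaryid", "pt"), "REAC")
  need(outc, c("primaryid", "outc_cod"), "OUTC")
  need(indi, c("primaryid", "indi_pt"), "INDI")

  ids <- demo$primaryid
  orphans <- c(
    DRUG = sum(!(drug$primaryid %in% ids)),
    REAC = sum(!(reac$primaryid %in% ids)),
    OUTC = sum(!(outc$primaryid %in% ids)),
    INDI = sum(!(indi$primaryid %in% ids))
  )

  outc_agg <- outc |>
    dplyr::filter(.data$primaryid %in% ids) |>
    dplyr::mutate(outcome = unname(.outc_map[toupper(.data$outc_cod)])) |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(outcomes = paste(sort(unique(.data$outcome)),
                                      collapse = ";"), .groups = "drop")
  indi_agg <- indi |>
    dplyr::filter(.data$primaryid %in% ids) |>
    dplyr::mutate(ind = .indi_normalize(.data$indi_pt)) |>
    dplyr::group_by(.data$primaryid) |>
    dplyr::summarise(indication = .data$ind[order(match(
      .data$ind, pv_levels$indication))][1], .groups = "drop")

  demo2 <- tibble::tibble(
    primaryid = demo$primaryid,
    case_id = demo$caseid,
    case_version = {
      v <- suppressWarnings(as.integer(demo$caseversion))
      v[is.na(v)] <- 1L
      v
    },
    sex = dplyr::case_match(toupper(demo$sex %||% NA_character_),
                            "F" ~ "female", "M" ~ "male",
                            .default = "unspecified"),
    age_years = .age_to_years(demo$age %||% NA_character_,
                              demo$age_cod %||% NA_character_),
    reporting_year = {
      y <- suppressWarnings(as.integer(substr(demo$fda_dt %||% "", 1, 4)))
      y[!is.na(y) & (y < 2005 | y > 2030)] <- NA_integer_
      y
    },
    reporter = dplyr::coalesce(
      unname(.occp_map[toupper(demo$occp_cod %||% NA_character_)]),
      "unspecified"),
    country = toupper(demo$reporter_country %||% NA_character_)
  )

  drug2 <- drug |>
    dplyr::filter(.data$primaryid %in% ids) |>
    dplyr::transmute(
      primaryid = .data$primaryid,
      drug = normalize_drug_name(.data$drugname),
      role_code = dplyr::coalesce(
        unname(.role_map[toupper(.data$role_cod)]), "concomitant"))
  reac2 <- reac |>
    dplyr::filter(.data$primaryid %in% ids) |>
    dplyr::transmute(
      primaryid = .data$primaryid,
      event_pt = tolower(gsub("\\s+", "_", trimws(.data$pt))))

  out <- drug2 |>
    dplyr::inner_join(reac2, by = "primaryid",
                      relationship = "many-to-many") |>
    dplyr::inner_join(demo2, by = "primaryid") |>
    dplyr::left_join(outc_agg, by = "primaryid") |>
    dplyr::left_join(indi_agg, by = "primaryid") |>
    dplyr::mutate(
      report_id = .data$primaryid,
      event_soc = ifelse(.data$event_pt %in% gi_pts, "gastrointestinal",
                         "other"),
      outcomes = dplyr::coalesce(.data$outcomes, ""),
      indication = dplyr::coalesce(.data$indication, "missing")
    ) |>
    dplyr::select(dplyr::all_of(report_columns)) |>
    dplyr::arrange(.data$report_id, .data$drug, .data$event_pt)

  validate_reports(out)
  attr(out, "orphans") <- orphans
  out
}

#' Default gastrointestinal preferred-term list
#'
#' Flat stand-in for the MedDRA gastrointestinal system organ class: the
#' preferred terms tracked by the analysis. User-configurable wherever it
#' is consumed.
#'
#' @return Character vector of PT strings.
#' @export
gi_pt_list <- function() {
  c("nausea", "vomiting", "abdominal_discomfort", "abdominal_pain",
    "pancreatitis", "constipation", "diarrhea", "gi_hemorrhage",
    "dyspepsia", "flatulence", "delayed_gastric_emptying", "gastritis",
    "gerd", "intestinal_obstruction", "cholecystitis", "peptic_ulcer",
    "anal_fissure", "inflammatory_bowel_disease", other_event_pt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
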
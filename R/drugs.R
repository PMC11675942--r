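# Controlled vocabularies for spontaneous-report fields, plus drug-name
# normalization covering the US generic and brand names of the GLP-1 RA class.

pv_levels <- list(
  drug = c("exenatide", "liraglutide", "dulaglutide", "semaglutide",
           "albiglutide", "lixisenatide", "other"),
  role_code = c("primary_suspect", "secondary_suspect", "concomitant",
                "interacting"),
  sex = c("female", "male", "unspecified"),
  reporter = c("consumer", "healthcare_professional", "unspecified"),
  indication = c("diabetes_mellitus", "obesity", "weight_loss", "other",
                 "missing"),
  outcome = c("disability", "life_threatening", "hospitalization", "death")
)

#' The four GLP-1 receptor agonists retained for analysis
#'
#' Exenatide, liraglutide, dulaglutide and semaglutide: the class members
#' with enough US spontaneous reports to support within-class
#' disproportionality. Albiglutide (withdrawn 2017) and lixisenatide are
#' recognised by the name normaliser but excluded by the default filters.
#'
#' @return Character vector of the four retained drug names.
#' @export
glp1_drugs <- function() {
  c("exenatide", "liraglutide", "dulaglutide", "semaglutide")
}

# brand -> generic lookup (case-insensitive, whitespace-collapsed)
.drug_synonyms <- c(
  exenatide = "exenatide", byetta = "exenatide", bydureon = "exenatide",
  liraglutide = "liraglutide", victoza = "liraglutide", saxenda = "liraglutide",
  dulaglutide = "dulaglutide", trulicity = "dulaglutide",
  lixisenatide = "lixisenatide", adlyxin = "lixisenatide", soliqua = "lixisenatide",
  semaglutide = "semaglutide", ozempic = "semaglutide", rybelsus = "semaglutide",
  wegovy = "semaglutide",
  albiglutide = "albiglutide", tanzeum = "albiglutide"
)

#' Normalize free-text drug names to the GLP-1 RA vocabulary
#'
#' Trims, collapses internal whitespace and lower-cases the input, then maps
#' generic and US brand names to their generic; anything unrecognised maps
#' to `"other"`.
#'
#' @param x Character vector of drug names as reported.
#' @return Character vector over the drug vocabulary.
#' @examples
#' normalize_drug_name(c("OZEMPIC", " Byetta ", "metformin"))
#' @export
normalize_drug_name <- function(x) {
  key <- tolower(gsub("\\s+", " ", trimws(as.character(x))))
  out <- unname(.drug_synonyms[key])
  out[is.na(out) & !is.na(x) & nzchar(key)] <- "other"
  out
}

#' CTCAE severity grades of the serious-outcome flags
#'
#' Serious adverse outcomes captured on spontaneous reports, graded on the
#' Common Terminology Criteria for Adverse Events scale: disability and
#' hospitalization are grade 3, life-threatening conditions grade 4, and
#' death grade 5.
#'
#' @return A tibble with columns `outcome` and `ctcae_grade`.
#' @export
outcome_grades <- function() {
  tibble::tibble(
    outcome = c("disability", "hospitalization", "life_threatening", "death"),
    ctcae_grade = c(3L, 3L, 4L, 5L)
  )
}

# map a vector onto a vocabulary; unknown non-missing values fall back to
# `fallback` and are counted by the caller
.match_level <- function(x, levels, fallback) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  x[bad] <- fallback
  list(value = x, n_mapped = sum(bad))
}
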
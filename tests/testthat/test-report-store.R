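test_that("normalized table round-trips field-for-field", {
  x <- make_small_cohort()
  x$outcomes[1] <- "death;hospitalization"
  x$age_years[2] <- NA_real_
  f <- withr::local_tempfile(fileext = ".csv")
  write_reports(x, f)
  y <- read_reports(f)
  attr(y, "ingest_log") <- NULL
  expect_equal(as.data.frame(y), as.data.frame(x))
  # and the re-serialization is byte-stable
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_reports(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("dialect recodes and bad values are logged, rows retained", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste(glp1pv:::report_columns, collapse = ","),
    "R1,C1,1,exenatide,primary_suspect,nausea,gastrointestinal,F,-5,2018,consumer,US,diabetes_mellitus,",
    "R2,C2,1,mystery_drug,primary_suspect,nausea,gastrointestinal,male,44,not_a_year,consumer,US,diabetes_mellitus,"
  ), f)
  x <- read_reports(f, dialect = list(sex = c(F = "female")))
  expect_equal(nrow(x), 2)
  expect_equal(x$sex, c("female", "male"))
  expect_true(is.na(x$age_years[1]))       # -5 out of range -> missing
  expect_true(is.na(x$reporting_year[2]))
  expect_equal(x$drug[2], "other")         # unknown enum -> fallback
  log <- attr(x, "ingest_log")
  expect_true(sum(log$n[log$field == "age_years"]) == 1)
  expect_true(sum(log$n[log$field == "drug"]) == 1)
})

test_that("a missing mandatory column is a hard error naming it", {
  f <- withr::local_tempfile(fileext = ".csv")
  x <- make_small_cohort()
  readr::write_csv(x[setdiff(names(x), "country")], f)
  expect_error(read_reports(f), "country")
})

test_that("report invariants are enforced", {
  x <- make_report("R1")
  expect_silent(validate_reports(x))
  bad <- x; bad$age_years <- 150
  expect_error(validate_reports(bad), "age_years")
  bad <- x; bad$reporting_year <- 1999L
  expect_error(validate_reports(bad), "reporting_year")
  bad <- x; bad$sex <- "banana"
  expect_error(validate_reports(bad), "sex")
})

test_that("drug-name normalization maps brands and unknowns", {
  expect_equal(
    normalize_drug_name(c("BYETTA", "Bydureon", "VICTOZA", "saxenda",
                          "TRULICITY", "ADLYXIN", "Soliqua", "OZEMPIC",
                          "rybelsus", "WEGOVY", " semaglutide ", "aspirin")),
    c("exenatide", "exenatide", "liraglutide", "liraglutide", "dulaglutide",
      "lixisenatide", "lixisenatide", "semaglutide", "semaglutide",
      "semaglutide", "semaglutide", "other"))
})

test_that("outcome grades follow the CTCAE mapping", {
  g <- outcome_grades()
  expect_equal(setNames(g$ctcae_grade, g$outcome),
               c(disability = 3L, hospitalization = 3L,
                 life_threatening = 4L, death = 5L))
})

test_that("deduplication keeps max case version and collapses exact dups", {
  v1 <- make_report("R1", case_id = "C1", case_version = 1L,
                    event_pt = "nausea")
  v2a <- make_report("R2", case_id = "C1", case_version = 2L,
                     event_pt = "nausea")
  v2b <- make_report("R2", case_id = "C1", case_version = 2L,
                     event_pt = "vomiting")
  x <- dplyr::bind_rows(v1, v2a, v2b, v2b, v2b)
  out <- deduplicate_reports(x)
  expect_equal(nrow(out), 2)
  expect_true(all(out$case_version == 2L))
  # full-record mode keeps both versions but drops exact repeats
  out2 <- deduplicate_reports(x, key = "full_record")
  expect_equal(nrow(out2), 3)
})

test_that("deduplication is order-invariant and idempotent", {
  x <- dplyr::bind_rows(
    make_small_cohort(),
    make_report("R01b", case_id = "R01", case_version = 2L),
    make_report("R05", event_pt = "pancreatitis", drug = "exenatide"))
  base <- deduplicate_reports(x)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- x[sample(nrow(x)), ]
    expect_equal(deduplicate_reports(perm), base)
  }
  expect_equal(deduplicate_reports(base), base)
})

test_that("FAERS-dialect reader joins, maps codes and orders output", {
  dir <- write_mini_faers()
  x <- read_faers_ascii(dir)
  # 6 DEMO rows, 5 unique cases after dedup
  expect_equal(length(unique(x$case_id)), 5)
  expect_equal(nrow(deduplicate_reports(x) |>
                      dplyr::distinct(case_id)), 5)
  # case 2001: 2 suspect drugs x 3 PTs -> 6 rows before filtering
  expect_equal(sum(x$report_id == "2001"), 6)
  # orphan REAC row excluded and counted
  expect_false(any(x$report_id == "9999"))
  expect_equal(unname(attr(x, "orphans")["REAC"]), 1)
  # age units: 680 months -> years; decade code -> years
  expect_equal(x$age_years[x$report_id == "2001"][1], 680 / 12)
  expect_equal(x$age_years[x$report_id == "3001"][1], 60)
  # outcome codes aggregated per case
  expect_equal(x$outcomes[x$report_id == "2001"][1],
               "death;hospitalization")
  # deterministic: same directory read twice gives identical output
  expect_identical(x, read_faers_ascii(dir))
})

test_that("filter pipeline stages, conservation and hand-enumerated result", {
  dir <- write_mini_faers()
  x <- read_faers_ascii(dir)
  res <- apply_filters(x, filter_config())
  log <- res$log
  # conservation at every stage and chaining between stages
  expect_equal(log$reports_out, log$reports_in - log$reports_excluded)
  expect_equal(log$reports_in[-1], log$reports_out[-nrow(log)])
  expect_equal(log$stage[1], "deduplicate")
  # hand enumeration: C1v2 exenatide nausea, C3 liraglutide diarrhea,
  # C5 semaglutide nausea survive; the combination case and the
  # non-US case are excluded
  expect_equal(nrow(res$reports), 3)
  expect_setequal(res$reports$report_id, c("1002", "3001", "5001"))
  expect_equal(log$reports_excluded[log$stage == "combination"], 3)
  expect_equal(log$reports_excluded[log$stage == "country"], 1)
})

test_that("role filter excludes concomitant rows; empty configs are legal", {
  x <- make_small_cohort()
  res <- apply_filters(x, filter_config())
  expect_equal(res$log$reports_excluded[res$log$stage == "role_code"], 4)
  # all reports CA but config wants US -> 0 retained, complete log
  x_ca <- dplyr::mutate(x, country = "CA")
  res2 <- apply_filters(x_ca, filter_config())
  expect_equal(nrow(res2$reports), 0)
  expect_true(all(c("country", "year_range") %in% res2$log$stage))
  # config excluding all drugs -> empty result, not an error
  res3 <- apply_filters(x, filter_config(drugs = character(0)))
  expect_equal(nrow(res3$reports), 0)
})

test_that("filtering is idempotent and monotone in the configuration", {
  dir <- write_mini_faers()
  x <- read_faers_ascii(dir)
  cfg <- filter_config()
  once <- apply_filters(x, cfg)
  twice <- apply_filters(once$reports, cfg)
  expect_equal(twice$reports, once$reports)
  # adding constraints never increases the retained count
  base <- nrow(apply_filters(x, filter_config(
    countries = NULL, year_range = NULL,
    exclude_combination_reports = FALSE))$reports)
  tighter <- list(
    filter_config(countries = NULL, year_range = NULL),
    filter_config(year_range = NULL),
    filter_config(),
    filter_config(year_range = c(2019, 2023)),
    filter_config(drugs = "exenatide"))
  prev <- base
  for (cfg in tighter) {
    n <- nrow(apply_filters(x, cfg)$reports)
    expect_lte(n, base)
  }
})

test_that("attrition log serializes to JSON and text", {
  res <- apply_filters(make_small_cohort(), filter_config())
  fj <- withr::local_tempfile(fileext = ".json")
  ft <- withr::local_tempfile(fileext = ".txt")
  write_filter_log(res$log, fj)
  write_filter_log(res$log, ft)
  parsed <- jsonlite::read_json(fj, simplifyVector = TRUE)
  expect_equal(parsed$stage, res$log$stage)
  expect_equal(parsed$reports_out, res$log$reports_out)
  expect_true(any(grepl("deduplicate", readLines(ft))))
})
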
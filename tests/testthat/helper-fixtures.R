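# Shared in-code fixtures: a small hand-built report set and a miniature
# FAERS-dialect directory written to a tempdir at test time.

make_report <- function(report_id, drug = "exenatide", event_pt = "nausea",
                        case_id = report_id, case_version = 1L,
                        role_code = "primary_suspect",
                        event_soc = "gastrointestinal", sex = "female",
                        age_years = 55, reporting_year = 2018L,
                        reporter = "consumer", country = "US",
                        indication = "diabetes_mellitus", outcomes = "") {
  tibble::tibble(report_id = report_id, case_id = case_id,
                 case_version = case_version, drug = drug,
                 role_code = role_code, event_pt = event_pt,
                 event_soc = event_soc, sex = sex, age_years = age_years,
                 reporting_year = reporting_year, reporter = reporter,
                 country = country, indication = indication,
                 outcomes = outcomes)
}

# ten reports, 4 concomitant, mixed drugs/sexes; used by filter tests
make_small_cohort <- function() {
  dplyr::bind_rows(
    make_report("R01", drug = "exenatide", sex = "female"),
    make_report("R02", drug = "liraglutide", sex = "female"),
    make_report("R03", drug = "dulaglutide", sex = "male"),
    make_report("R04", drug = "semaglutide", sex = "female"),
    make_report("R05", drug = "exenatide", event_pt = "pancreatitis",
                sex = "female"),
    make_report("R06", drug = "semaglutide", event_pt = "vomiting",
                sex = "female"),
    make_report("R07", drug = "exenatide", role_code = "concomitant",
                sex = "male"),
    make_report("R08", drug = "liraglutide", role_code = "concomitant",
                sex = "male"),
    make_report("R09", drug = "dulaglutide", role_code = "concomitant",
                sex = "male"),
    make_report("R10", drug = "semaglutide", role_code = "concomitant",
                sex = "female")
  )
}

# expand a 2x2 (a, b, c, d) into report rows: target drug vs a single
# comparator drug; used by the regression and statistic tests
expand_2x2 <- function(a, b, c, d, event = "pancreatitis",
                       target = "exenatide", comp = "liraglutide") {
  n <- a + b + c + d
  tibble::tibble(
    report_id = sprintf("X%06d", seq_len(n)),
    case_id = sprintf("X%06d", seq_len(n)),
    case_version = 1L,
    drug = rep(c(target, comp), c(a + b, c + d)),
    role_code = "primary_suspect",
    event_pt = c(rep(event, a), rep(glp1pv:::other_event_pt, b),
                 rep(event, c), rep(glp1pv:::other_event_pt, d)),
    event_soc = "gastrointestinal", sex = "unspecified",
    age_years = NA_real_, reporting_year = 2018L,
    reporter = "unspecified", country = "US", indication = "missing",
    outcomes = "")
}

# Miniature FAERS quarter: 6 cases, one of them in two versions, one case
# with 2 suspect drugs x 3 PTs, one orphan REAC row. Returns the dir.
write_mini_faers <- function(dir = tempfile("faers")) {
  dir.create(dir)
  w <- function(stem, lines) {
    writeLines(lines, file.path(dir, paste0(stem, "24Q1.txt")))
  }
  w("DEMO", c(
    "primaryid$caseid$caseversion$age$age_cod$sex$occp_cod$reporter_country$fda_dt",
    "1001$C1$1$55$YR$F$CN$US$20180105",
    "1002$C1$2$55$YR$F$CN$US$20180610",  # later version of case C1
    "2001$C2$1$680$MON$M$MD$US$20190301",
    "3001$C3$1$6$DEC$F$CN$US$20200215",
    "4001$C4$1$47$YR$M$MD$CA$20200830",
    "5001$C5$1$$YR$UNK$CN$US$20210501"))
  w("DRUG", c(
    "primaryid$drugname$role_cod",
    "1001$BYETTA$PS",
    "1002$BYETTA$PS",
    "2001$OZEMPIC$PS",
    "2001$metformin$SS",    # combination report: 2 suspect drugs
    "3001$Victoza$PS",
    "4001$TRULICITY$PS",
    "5001$WEGOVY$PS"))
  w("REAC", c(
    "primaryid$pt",
    "1001$Nausea",
    "1002$Nausea",
    "2001$Nausea", "2001$Vomiting", "2001$Pancreatitis",
    "3001$Diarrhea",
    "4001$Constipation",
    "5001$Nausea",
    "9999$Nausea"))          # orphan row, no DEMO match
  w("OUTC", c(
    "primaryid$outc_cod",
    "2001$HO", "2001$DE"))
  w("INDI", c(
    "primaryid$indi_pt",
    "1001$Diabetes mellitus",
    "1002$Diabetes mellitus",
    "2001$Weight loss",
    "3001$Type 2 diabetes mellitus",
    "4001$Diabetes mellitus"))
  dir
}

fixture_cached <- local({
  fix <- NULL
  function() {
    if (is.null(fix)) fix <<- count_fixture()
    fix
  }
})
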
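# Synthetic spontaneous-report generator. Reproduces the statistical
# structure of the analyzed cohort -- four drugs with fixed report shares,
# per-event baseline reporting probabilities with drug-specific
# reporting-rate multipliers, the observed sex/age/outcome marginals --
# so that every pipeline stage is testable and the multipliers are a known
# ground truth for parameter recovery.
#
# The multiplier theta acts on the reporting ODDS:
#   p(drug, event) = theta q / (1 - q + theta q),  q = baseline,
# so the reporting odds ratio of the generated 2x2 is exactly theta, which
# is the estimand of the disproportionality statistics.

.approval_year <- c(exenatide = 2005, liraglutide = 2010, dulaglutide = 2014,
                    semaglutide = 2017, albiglutide = 2014,
                    lixisenatide = 2016)

# pooled observed event frequencies of the analyzed cohort; the generator's
# default baseline rates
default_event_baseline <- function() {
  c(nausea = 0.44, vomiting = 0.23, abdominal_pain = 0.16,
    pancreatitis = 0.17, diarrhea = 0.21, constipation = 0.087,
    delayed_gastric_emptying = 0.061, dyspepsia = 0.053,
    flatulence = 0.041, cholecystitis = 0.0064)
}

#' Synthetic-cohort configuration
#'
#' Defaults are the analyzed cohort's marginals: 16,568 reports split
#' 26.6 / 24.9 / 24.6 / 23.9% over the four drugs, 62% female, age-band
#' shares 10 / 19.8 / 32 / 38.2% over 18-44 / 45-54 / 55-64 / 65+, pooled
#' observed event frequencies as baselines, unit multipliers (no signal),
#' and the observed serious-outcome rates.
#'
#' @param n_reports Number of reports.
#' @param drug_shares Named probability vector over the four drugs (sums
#'   to 1).
#' @param event_baseline Named per-report event probabilities for the
#'   comparator (multiplier 1) condition.
#' @param rate_multiplier Named list: `list(exenatide = c(pancreatitis =
#'   2))` sets theta for (drug, event) pairs; unset pairs are 1.
#' @param female_share,age_shares,outcome_probs Demographic and outcome
#'   marginals (named vectors).
#' @param confounding `NULL`, or a list with any of `age_slope` (log-odds
#'   per year of age, centered at 60, applied to every event), `sex_slope`
#'   (log-odds for male), and `drug_age_bias` (named per-drug log-odds per
#'   year tilting drug assignment by age). When set, event probabilities
#'   are logit-linear and the adjusted regression's drug coefficient -- not
#'   the crude ROR -- recovers ln(theta).
#' @param seed RNG seed; generation is reproducible given the seed.
#' @return A list of class `pv_syn_config`.
#' @export
synthetic_config <- function(n_reports = 16568,
                             drug_shares = c(exenatide = 0.266,
                                             liraglutide = 0.249,
                                             dulaglutide = 0.246,
                                             semaglutide = 0.239),
                             event_baseline = default_event_baseline(),
                             rate_multiplier = list(),
                             female_share = 0.62,
                             age_shares = c(`18-44` = 0.10, `45-54` = 0.198,
                                            `55-64` = 0.32, `65+` = 0.382),
                             outcome_probs = c(disability = 0.008,
                                               life_threatening = 0.012,
                                               hospitalization = 0.203,
                                               death = 0.012),
                             confounding = NULL,
                             seed = 1L) {
  stopifnot(n_reports >= 1,
            abs(sum(drug_shares) - 1) < 1e-12,
            abs(sum(age_shares) - 1) < 1e-12,
            all(event_baseline > 0), all(event_baseline < 1),
            female_share >= 0, female_share <= 1,
            all(outcome_probs >= 0), all(outcome_probs <= 1))
  for (d in names(rate_multiplier)) {
    th <- rate_multiplier[[d]]
    if (any(th <= 0)) stop("rate multipliers must be positive", call. = FALSE)
    if (!d %in% names(drug_shares)) stop("unknown drug in rate_multiplier: ",
                                         d, call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports),
                 drug_shares = drug_shares,
                 event_baseline = event_baseline,
                 rate_multiplier = rate_multiplier,
                 female_share = female_share, age_shares = age_shares,
                 outcome_probs = outcome_probs, confounding = confounding,
                 seed = as.integer(seed)), class = "pv_syn_config")
}

.theta <- function(config, drug, event) {
  th <- config$rate_multiplier[[drug]]
  if (is.null(th) || !(event %in% names(th))) 1 else unname(th[event])
}

#' Generate a synthetic report collection
#'
#' Each report draws a drug, sex, age, reporting year (uniform over the
#' drug's post-approval study years), reporter, indication and outcome
#' flags, then each tracked event independently with the configured odds.
#' Reports with none of the tracked events are retained under the
#' placeholder PT (they populate the b / d cells). Deterministic given the
#' config seed.
#'
#' @param config A [synthetic_config()].
#' @return Reports tibble (one row per report-event); attribute `config`
#'   carries the generating configuration.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "pv_syn_config"))
  set.seed(config$seed)
  n <- config$n_reports
  drugs <- names(config$drug_shares)
  events <- names(config$event_baseline)
  conf <- config$confounding

  # demographics first (drug assignment may depend on age)
  age_band <- sample(names(config$age_shares), n, replace = TRUE,
                     prob = config$age_shares)
  lo <- c(`18-44` = 18, `45-54` = 45, `55-64` = 55, `65+` = 65)[age_band]
  hi <- c(`18-44` = 45, `45-54` = 55, `55-64` = 65, `65+` = 90)[age_band]
  age <- floor(runif(n, lo, hi))
  male <- runif(n) >= config$female_share
  age_c <- age - 60

  if (!is.null(conf$drug_age_bias)) {
    bias <- rep(0, length(drugs)); names(bias) <- drugs
    bias[names(conf$drug_age_bias)] <- conf$drug_age_bias
    # per-report multinomial via the Gumbel-max trick
    lw <- outer(rep(1, n), log(config$drug_shares)) +
      outer(age_c, bias)
    g <- matrix(-log(-log(runif(n * length(drugs)))), n)
    drug_idx <- max.col(lw + g)
  } else {
    drug_idx <- sample(length(drugs), n, replace = TRUE,
                       prob = config$drug_shares)
  }
  drug <- drugs[drug_idx]

  year <- {
    a <- pmax(.approval_year[drug], 2007)
    floor(runif(n, a, 2024))
  }
  reporter <- sample(c("consumer", "healthcare_professional"), n,
                     replace = TRUE, prob = c(0.65, 0.35))
  indication <- sample(c("diabetes_mellitus", "weight_loss", "obesity"), n,
                       replace = TRUE, prob = c(0.90, 0.07, 0.03))

  # event draws: logit p = logit(q) + ln theta (+ confounding terms)
  ymat <- matrix(0L, n, length(events), dimnames = list(NULL, events))
  for (e in events) {
    lth <- log(vapply(drugs, function(d) .theta(config, d, e), numeric(1)))
    eta <- qlogis(config$event_baseline[[e]]) + lth[drug_idx]
    if (!is.null(conf)) {
      eta <- eta + (conf$age_slope %||% 0) * age_c +
        (conf$sex_slope %||% 0) * male
    }
    ymat[, e] <- rbinom(n, 1, plogis(eta))
  }

  oc_str <- character(n)
  for (o in sort(names(config$outcome_probs))) {
    hit <- rbinom(n, 1, config$outcome_probs[[o]]) == 1
    oc_str[hit] <- ifelse(nzchar(oc_str[hit]), paste0(oc_str[hit], ";", o), o)
  }

  base <- tibble::tibble(
    report_id = sprintf("S%07d", seq_len(n)),
    case_id = sprintf("C%07d", seq_len(n)),
    case_version = 1L, drug = drug, role_code = "primary_suspect",
    event_soc = "gastrointestinal", sex = ifelse(male, "male", "female"),
    age_years = age, reporting_year = as.integer(year),
    reporter = reporter, country = "US", indication = indication,
    outcomes = oc_str)

  hits <- which(ymat == 1L, arr.ind = TRUE)
  ev_rows <- base[hits[, 1], ]
  ev_rows$event_pt <- events[hits[, 2]]
  none <- which(rowSums(ymat) == 0)
  zero_rows <- base[none, ]
  zero_rows$event_pt <- other_event_pt

  out <- dplyr::bind_rows(ev_rows, zero_rows) |>
    dplyr::select(dplyr::all_of(report_columns)) |>
    dplyr::arrange(.data$report_id, .data$event_pt)
  validate_reports(out)
  attr(out, "config") <- config
  out
}

#' Expected 2x2 cell means under a synthetic configuration
#'
#' Closed form for the no-confounding model: with s_d the drug share, q_e
#' the baseline and p_de the configured odds-shifted probability,
#' E(a) = n s_d p_de, E(a + b) = n s_d, and the comparator cells pool the
#' remaining drugs. Used to validate [generate_reports()] against its own
#' generative model.
#'
#' @param config A [synthetic_config()] (confounding must be `NULL`).
#' @return Tibble: drug, event, ea, eb, ec, ed.
#' @export
expected_tables <- function(config) {
  stopifnot(inherits(config, "pv_syn_config"))
  if (!is.null(config$confounding)) {
    stop("closed-form expectations require confounding = NULL", call. = FALSE)
  }
  n <- config$n_reports
  drugs <- names(config$drug_shares)
  rows <- list()
  for (e in names(config$event_baseline)) {
    q <- config$event_baseline[[e]]
    p <- vapply(drugs, function(d) {
      th <- .theta(config, d, e)
      th * q / (1 - q + th * q)
    }, numeric(1))
    for (d in drugs) {
      s <- config$drug_shares
      ea <- n * s[[d]] * p[[d]]
      eb <- n * s[[d]] - ea
      others <- setdiff(drugs, d)
      ec <- n * sum(s[others] * p[others])
      ed <- n * sum(s[others]) - ec
      rows[[length(rows) + 1]] <- tibble::tibble(
        drug = d, event = e, ea = ea, eb = eb, ec = ec, ed = ed)
    }
  }
  dplyr::bind_rows(rows)
}

#' Expand fixture counts for one event into report rows
#'
#' Inverse of the counting step: for each drug, emits exactly `a` reports
#' carrying the event and `total - a` carrying the placeholder PT, with
#' unspecified demographics, so that re-counting reproduces the fixture
#' cell-for-cell and the expansion totals 16,568 rows.
#'
#' @param fixture A [count_fixture()].
#' @param event Event PT present in the fixture for all four drugs.
#' @param use_corrections Apply packaged count corrections.
#' @return Reports tibble.
#' @export
expand_fixture <- function(fixture, event, use_corrections = FALSE) {
  stopifnot(inherits(fixture, "pv_count_fixture"))
  cs <- fixture_cases(fixture, event, use_corrections = use_corrections)
  if (any(is.na(cs))) {
    stop(sprintf("fixture lacks case counts for event '%s', drug(s) %s",
                 event, paste(names(cs)[is.na(cs)], collapse = ", ")),
         call. = FALSE)
  }
  tot <- fixture$drug_totals
  rows <- lapply(fixture$drugs, function(d) {
    a <- cs[[d]]
    tibble::tibble(drug = d,
                   event_pt = c(rep(event, a),
                                rep(other_event_pt, tot[[d]] - a)))
  })
  out <- dplyr::bind_rows(rows)
  n <- nrow(out)
  tibble::tibble(
    report_id = sprintf("F%07d", seq_len(n)),
    case_id = sprintf("F%07d", seq_len(n)),
    case_version = 1L, drug = out$drug, role_code = "primary_suspect",
    event_pt = out$event_pt, event_soc = "gastrointestinal",
    sex = "unspecified", age_years = NA_real_,
    reporting_year = NA_integer_, reporter = "unspecified", country = "US",
    indication = "missing", outcomes = "")[, report_columns]
}

#' Read a synthetic configuration from JSON or YAML
#'
#' @param path `.json` or `.yaml`/`.yml` file whose fields mirror
#'   [synthetic_config()] arguments.
#' @return A `pv_syn_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("yaml package required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  for (f in c("n_reports", "female_share", "seed")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  for (f in c("drug_shares", "event_baseline", "age_shares",
              "outcome_probs")) {
    if (!is.null(raw[[f]])) args[[f]] <- unlist(raw[[f]])
  }
  if (!is.null(raw$rate_multiplier)) {
    args$rate_multiplier <- lapply(raw$rate_multiplier, unlist)
  }
  if (!is.null(raw$confounding)) {
    cf <- raw$confounding
    args$confounding <- list(
      age_slope = cf$age_slope %||% 0, sex_slope = cf$sex_slope %||% 0,
      drug_age_bias = if (!is.null(cf$drug_age_bias)) unlist(cf$drug_age_bias))
  }
  do.call(synthetic_config, args)
}
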
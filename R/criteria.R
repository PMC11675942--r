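# Combined signal evaluation: the per-method positivity rules and the
# one-row-per-pair signal table.

#' Signal-positivity criteria
#'
#' Literature-standard thresholds: ROR positive when its CI lower bound
#' exceeds 1 with at least `min_cases` cases; PRR positive when PRR >= 2,
#' chi-square >= 4 and a >= 3; IC positive when IC025 > 0; the adjusted
#' regression positive when beta > 0 with p < 0.05.
#'
#' @param min_cases Minimum case count for the ROR rule (default 3).
#' @param prr_threshold,chi2_threshold PRR rule thresholds (defaults 2, 4).
#' @param prr_min_cases Minimum cases for the PRR rule (default 3).
#' @param mlr_alpha Significance level for the regression rule (default
#'   0.05).
#' @param ic_variant Which IC variant drives the IC flag:
#'   `"noren_shrinkage"` (default) or `"bate_prior"`.
#' @return A list of class `pv_criteria`.
#' @export
signal_criteria <- function(min_cases = 3, prr_threshold = 2,
                            chi2_threshold = 4, prr_min_cases = 3,
                            mlr_alpha = 0.05,
                            ic_variant = c("noren_shrinkage", "bate_prior")) {
  stopifnot(min_cases > 0, prr_threshold > 0, chi2_threshold > 0,
            prr_min_cases > 0, mlr_alpha > 0)
  structure(list(min_cases = min_cases, prr_threshold = prr_threshold,
                 chi2_threshold = chi2_threshold,
                 prr_min_cases = prr_min_cases, mlr_alpha = mlr_alpha,
                 ic_variant = match.arg(ic_variant)),
            class = "pv_criteria")
}

#' Evaluate all four signal methods on one drug x event pair
#'
#' Computes ROR, PRR, chi-square and both IC variants from the table,
#' applies the positivity criteria, and attaches the adjusted-regression
#' coefficient when supplied. Non-estimable statistics yield a `FALSE`
#' flag with a reason code rather than an error.
#'
#' @param table A `pv_2x2`.
#' @param criteria A [signal_criteria()].
#' @param beta,beta_p Adjusted logistic-regression coefficient (log-odds)
#'   and Wald p-value for the pair, when a report-level fit is available.
#' @return One-row tibble of class `pv_signal_result`: counts, all
#'   statistics, per-method flags, `n_methods_positive`, and a `;`-joined
#'   `reasons` column for negative flags caused by non-estimability.
#' @export
evaluate_signal <- function(table, criteria = signal_criteria(),
                            beta = NA_real_, beta_p = NA_real_) {
  stopifnot(inherits(table, "pv_2x2"), inherits(criteria, "pv_criteria"))
  r <- ror(table)
  p <- prr(table)
  x2 <- chi_square(table)
  icn <- ic_noren(table)
  icb <- ic_bate(table)
  ic_used <- if (criteria$ic_variant == "noren_shrinkage") icn else icb

  reasons <- character(0)
  flag_ror <- isTRUE(r$estimable && !r$corrected &&
                       r$ci_low > 1 && table$a >= criteria$min_cases)
  if (!r$estimable || r$corrected) reasons <- c(reasons, "ror:non_estimable")
  else if (table$a < criteria$min_cases) reasons <- c(reasons, "ror:min_cases")

  flag_prr <- isTRUE(p$estimable && !p$corrected && !is.na(x2) &&
                       p$estimate >= criteria$prr_threshold &&
                       x2 >= criteria$chi2_threshold &&
                       table$a >= criteria$prr_min_cases)
  if (!p$estimable || p$corrected || is.na(x2)) {
    reasons <- c(reasons, "prr:non_estimable")
  } else if (table$a < criteria$prr_min_cases) {
    reasons <- c(reasons, "prr:min_cases")
  }

  flag_ic <- isTRUE(ic_used$ic025 > 0)
  flag_mlr <- isTRUE(!is.na(beta) && !is.na(beta_p) && beta > 0 &&
                       beta_p < criteria$mlr_alpha)
  if (is.na(beta) || is.na(beta_p)) reasons <- c(reasons, "mlr:not_fitted")

  out <- tibble::tibble(
    drug = table$drug, event = table$event,
    a = table$a, b = table$b, c = table$c, d = table$d, n = table$N,
    ror = r$estimate, ror_lo = r$ci_low, ror_hi = r$ci_high,
    prr = p$estimate, prr_lo = p$ci_low, prr_hi = p$ci_high,
    chi2 = x2,
    ic = icn$ic, ic025 = icn$ic025,
    ic_bate = icb$ic, ic025_bate = icb$ic025,
    beta = beta, beta_p = beta_p,
    flag_ror = flag_ror, flag_prr = flag_prr, flag_ic = flag_ic,
    flag_mlr = flag_mlr,
    n_methods_positive = sum(flag_ror, flag_prr, flag_ic, flag_mlr),
    corrected = r$corrected,
    reasons = paste(reasons, collapse = ";"))
  class(out) <- c("pv_signal_result", class(out))
  out
}

#' Signal table over drug x event pairs
#'
#' Runs [evaluate_signal()] for every combination, building the tables from
#' report-level data. Adjusted-regression coefficients are merged in when
#' `fits` (a [batch_fit()] result) is given.
#'
#' @param reports Reports tibble.
#' @param drugs,events Pairs to evaluate; defaults: the four retained drugs
#'   and every observed PT except the placeholder.
#' @param criteria A [signal_criteria()].
#' @param fits Optional [batch_fit()] output supplying beta / beta_p.
#' @param unit Counting unit, see [contingency_from_reports()].
#' @return Tibble with one row per drug x event.
#' @export
signal_table <- function(reports, drugs = glp1_drugs(), events = NULL,
                         criteria = signal_criteria(), fits = NULL,
                         unit = "report") {
  if (is.null(events)) {
    events <- sort(setdiff(unique(reports$event_pt), other_event_pt))
  }
  rows <- list()
  for (d in drugs) {
    for (e in events) {
      tab <- contingency_from_reports(reports, d, e,
                                      comparator = setdiff(drugs, d),
                                      unit = unit)
      beta <- beta_p <- NA_real_
      if (!is.null(fits)) {
        ft <- fits$summary
        hit <- ft[ft$drug == d & ft$event == e, , drop = FALSE]
        if (nrow(hit) == 1 && isTRUE(hit$converged)) {
          beta <- hit$beta
          beta_p <- hit$p
        }
      }
      rows[[length(rows) + 1]] <- evaluate_signal(tab, criteria, beta, beta_p)
    }
  }
  dplyr::bind_rows(rows)
}
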
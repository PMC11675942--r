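# Disproportionality statistics on a 2x2 table. Symbols: a = target drug
# with the event, b = target drug other events, c / d the same over the
# pooled comparator, N = a+b+c+d, E = (a+b)(a+c)/N the expected count of
# the pair under independence.

# normal quantile for two-sided CIs; the conventional 1.96 at the default
# 95% level (the value published signal tables are computed with), the
# exact quantile otherwise
.z_quantile <- function(level) {
  if (abs(level - 0.95) < 1e-12) 1.96 else qnorm(1 - (1 - level) / 2)
}

# Haldane-Anscombe continuity handling: +0.5 to all four cells when any is
# zero. Applied to the ratio statistics only; results carry a flag.
.zero_rule <- function(table, zero_cell) {
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- FALSE
  if (zero_cell == "haldane" && any(cells == 0)) {
    cells <- cells + 0.5
    corrected <- TRUE
  }
  list(a = cells[1], b = cells[2], c = cells[3], d = cells[4],
       corrected = corrected, estimable = all(cells > 0))
}

.ci_result <- function(est, lo, hi, level, corrected, estimable) {
  structure(list(estimate = est, ci_low = lo, ci_high = hi, level = level,
                 corrected = corrected, estimable = estimable),
            class = "pv_ci")
}

#' Reporting odds ratio
#'
#' ROR = (a d) / (b c), the odds of the event among the target drug's
#' reports relative to the pooled comparator, with the delta-method
#' confidence interval exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d)).
#' Tables with a zero cell get the Haldane-Anscombe +0.5 correction (all
#' four cells) and are flagged `corrected`; if a cell is still zero the
#' result is flagged non-estimable.
#'
#' @param table A `pv_2x2`.
#' @param level Confidence level (default 0.95).
#' @param zero_cell `"haldane"` (default) or `"none"`.
#' @return A `pv_ci`: estimate, ci_low, ci_high, level, corrected,
#'   estimable.
#' @export
ror <- function(table, level = 0.95, zero_cell = c("haldane", "none")) {
  stopifnot(inherits(table, "pv_2x2"))
  z <- .zero_rule(table, match.arg(zero_cell))
  if (!z$estimable) {
    return(.ci_result(NA_real_, NA_real_, NA_real_, level, z$corrected, FALSE))
  }
  est <- (z$a * z$d) / (z$b * z$c)
  se <- sqrt(1 / z$a + 1 / z$b + 1 / z$c + 1 / z$d)
  q <- .z_quantile(level)
  .ci_result(est, exp(log(est) - q * se), exp(log(est) + q * se), level,
             z$corrected, TRUE)
}

#' Proportional reporting ratio
#'
#' PRR = [a / (a+b)] / [c / (c+d)], the event's share of the target drug's
#' reports relative to its share of the comparator's, with the delta-method
#' interval exp(ln PRR +/- z sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))). Zero
#' cells handled as in [ror()].
#'
#' @inheritParams ror
#' @return A `pv_ci`.
#' @export
prr <- function(table, level = 0.95, zero_cell = c("haldane", "none")) {
  stopifnot(inherits(table, "pv_2x2"))
  z <- .zero_rule(table, match.arg(zero_cell))
  if (!z$estimable) {
    return(.ci_result(NA_real_, NA_real_, NA_real_, level, z$corrected, FALSE))
  }
  est <- (z$a / (z$a + z$b)) / (z$c / (z$c + z$d))
  se <- sqrt(1 / z$a - 1 / (z$a + z$b) + 1 / z$c - 1 / (z$c + z$d))
  q <- .z_quantile(level)
  .ci_result(est, exp(log(est) - q * se), exp(log(est) + q * se), level,
             z$corrected, TRUE)
}

#' Pearson chi-square of a 2x2 table
#'
#' The independence chi-square entering the PRR signal criterion, with the
#' Yates continuity correction by default (the conventional choice for that
#' criterion).
#'
#' @param table A `pv_2x2`.
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return Nonnegative chi-square value, or `NA` when an expected cell is
#'   zero (a zero row or column margin).
#' @export
chi_square <- function(table, yates = TRUE) {
  stopifnot(inherits(table, "pv_2x2"))
  obs <- c(table$a, table$b, table$c, table$d)
  n <- table$N
  rows <- c(table$a + table$b, table$c + table$d)
  cols <- c(table$a + table$c, table$b + table$d)
  expd <- c(rows[1] * cols[1], rows[1] * cols[2],
            rows[2] * cols[1], rows[2] * cols[2]) / n
  if (any(expd == 0)) return(NA_real_)
  dev <- abs(obs - expd)
  if (yates) dev <- pmax(0, dev - 0.5)
  sum(dev^2 / expd)
}

#' Information component, closed-form shrinkage variant
#'
#' The observed-to-expected base-2 log ratio with +0.5 shrinkage,
#' IC = log2((a + 0.5) / (E + 0.5)) with E = (a+b)(a+c)/N, and its lower
#' 95% credibility bound IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2).
#' Deterministic and prior-free; the headline IC variant.
#'
#' @param table A `pv_2x2`.
#' @return A list of class `pv_ic`: `method`, `ic`, `ic025`,
#'   `expected_count`.
#' @export
ic_noren <- function(table) {
  stopifnot(inherits(table, "pv_2x2"))
  e <- (table$a + table$b) * (table$a + table$c) / table$N
  ic <- log2((table$a + 0.5) / (e + 0.5))
  ic025 <- ic - 3.3 * (table$a + 0.5)^(-0.5) - 2 * (table$a + 0.5)^(-1.5)
  structure(list(method = "noren_shrinkage", ic = ic, ic025 = ic025,
                 expected_count = e, prior_params = NULL), class = "pv_ic")
}

#' Information component, prior-based variant
#'
#' Two-layer Beta model: the pair probability p11, the drug margin p1. and
#' the event margin p.1 carry independent Beta posteriors
#' Beta(a + g11, N - a + g - g11), Beta(a+b + a1, N - (a+b) + alpha - a1),
#' Beta(a+c + b1, N - (a+c) + beta - b1), with g scaled so the prior IC
#' expectation is zero. IC moments are the exact log-moments of those
#' posteriors (digamma / trigamma), and
#' IC025 = E(IC) - z0.975 sqrt(V(IC)).
#'
#' @param table A `pv_2x2`.
#' @param priors Named list `alpha1`, `beta1`, `alpha`, `beta`, `gamma11`
#'   (defaults 1, 1, 2, 2, 1); all must be positive.
#' @return A `pv_ic` with `prior_params` recording the priors and scaled
#'   `gamma`.
#' @export
ic_bate <- function(table, priors = list(alpha1 = 1, beta1 = 1, alpha = 2,
                                         beta = 2, gamma11 = 1)) {
  stopifnot(inherits(table, "pv_2x2"))
  p <- priors
  if (any(unlist(p[c("alpha1", "beta1", "alpha", "beta", "gamma11")]) <= 0)) {
    stop("prior parameters must be positive", call. = FALSE)
  }
  a <- table$a; n <- table$N
  n1 <- table$a + table$b  # drug margin
  m1 <- table$a + table$c  # event margin
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((n1 + p$alpha1) * (m1 + p$beta1))
  # posterior shapes
  s11 <- c(a + p$gamma11, n - a + gamma - p$gamma11)
  s1 <- c(n1 + p$alpha1, n - n1 + p$alpha - p$alpha1)
  s2 <- c(m1 + p$beta1, n - m1 + p$beta - p$beta1)
  elog <- function(s) digamma(s[1]) - digamma(sum(s))
  vlog <- function(s) trigamma(s[1]) - trigamma(sum(s))
  ic <- (elog(s11) - elog(s1) - elog(s2)) / log(2)
  v <- (vlog(s11) + vlog(s1) + vlog(s2)) / log(2)^2
  ic025 <- ic - qnorm(0.975) * sqrt(v)
  structure(list(method = "bate_prior", ic = ic, ic025 = ic025,
                 expected_count = n1 * m1 / n, ic_var = v,
                 prior_params = c(p, gamma = gamma)), class = "pv_ic")
}

#' @export
print.pv_ci <- function(x, ...) {
  cat(sprintf("%.4g (%.4g, %.4g) [%d%% CI%s%s]\n", x$estimate, x$ci_low,
              x$ci_high, round(100 * x$level),
              if (x$corrected) ", continuity-corrected" else "",
              if (!x$estimable) ", non-estimable" else ""))
  invisible(x)
}

#' @export
print.pv_ic <- function(x, ...) {
  cat(sprintf("IC %.4g, IC025 %.4g (%s, E = %.4g)\n", x$ic, x$ic025,
              x$method, x$expected_count))
  invisible(x)
}
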
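# The fourth signal method: per drug x event logistic regression of
# event-reported (yes/no) on target drug vs the pooled comparator,
# adjusted for age (continuous, mean-centered) and sex (female reference).
# Fit by maximum likelihood (IRLS); rows with missing covariates are
# dropped listwise for this method only.

# collapse row-level reports to one observation per report
.report_level <- function(reports, event, target_drug, comparator) {
  x <- dplyr::filter(reports, .data$drug %in% c(target_drug, comparator))
  x |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(
      y = as.integer(any(.data$event_pt == !!event)),
      exposure = as.integer(.data$drug[1] == !!target_drug),
      age_years = .data$age_years[1],
      sex = .data$sex[1], .groups = "drop")
}

#' Adjusted logistic regression for one drug x event pair
#'
#' Outcome: report mentions the event; exposure: target drug versus the
#' pooled comparator; covariates: centered continuous age and a male
#' indicator (female reference), individually dropped when absent from the
#' data. Complete separation is detected and reported (`converged = FALSE`,
#' reason `"separation"`) rather than silently regularized; `firth = TRUE`
#' switches to Jeffreys-penalized likelihood, which is finite under
#' separation.
#'
#' With no covariates the drug coefficient equals ln(ROR) of the pair's
#' 2x2 table (to solver tolerance).
#'
#' @param reports Reports tibble.
#' @param event Event PT.
#' @param target_drug Exposure drug.
#' @param comparator Pooled comparator drugs.
#' @param covariates Subset of `c("age_years", "sex")`; empty for the crude
#'   model.
#' @param max_iter,tol IRLS iteration cap and log-likelihood convergence
#'   tolerance.
#' @param firth Use Jeffreys-penalized (Firth) likelihood.
#' @return A tibble (term, beta, se, z, p) of class `pv_coef_table` with
#'   attributes `converged`, `reason`, `n_obs`, `n_dropped`, `event`,
#'   `drug`.
#' @export
fit_logistic <- function(reports, event, target_drug,
                         comparator = setdiff(glp1_drugs(), target_drug),
                         covariates = c("age_years", "sex"),
                         max_iter = 50, tol = 1e-8, firth = FALSE) {
  stopifnot(tol > 0, max_iter >= 1)
  dat <- .report_level(reports, event, target_drug, comparator)
  covariates <- intersect(covariates, c("age_years", "sex"))

  n0 <- nrow(dat)
  if ("age_years" %in% covariates) dat <- dat[!is.na(dat$age_years), ]
  if ("sex" %in% covariates) dat <- dat[dat$sex %in% c("female", "male"), ]
  n_dropped <- n0 - nrow(dat)

  fail <- function(reason) {
    out <- tibble::tibble(term = character(), beta = numeric(),
                          se = numeric(), z = numeric(), p = numeric())
    structure(out, class = c("pv_coef_table", class(out)),
              converged = FALSE, reason = reason, n_obs = nrow(dat),
              n_dropped = n_dropped, event = event, drug = target_drug)
  }
  if (nrow(dat) == 0 || length(unique(dat$y)) < 2) return(fail("separation"))

  X <- cbind(`(Intercept)` = 1, drug = dat$exposure)
  if ("age_years" %in% covariates) {
    X <- cbind(X, age_c = dat$age_years - mean(dat$age_years))
  }
  if ("sex" %in% covariates) {
    X <- cbind(X, sex_male = as.integer(dat$sex == "male"))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("singular design; collinear term(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }

  if (firth) {
    fit <- .firth_fit(X, dat$y, max_iter = max_iter, tol = tol)
    beta <- fit$beta; se <- fit$se; converged <- fit$converged
    reason <- if (converged) NA_character_ else "max_iter"
  } else {
    w <- NULL
    fit <- withCallingHandlers(
      glm(dat$y ~ X - 1, family = binomial(),
          control = glm.control(epsilon = tol, maxit = max_iter)),
      warning = function(cnd) {
        w <<- conditionMessage(cnd)
        invokeRestart("muffleWarning")
      })
    beta <- unname(coef(fit))
    se <- sqrt(diag(vcov(fit)))
    sep <- (!is.null(w) && grepl("fitted probabilities numerically 0 or 1",
                                 w) && max(abs(beta)) > 8) ||
      max(abs(beta)) > 15
    converged <- fit$converged && !sep
    reason <- if (sep) "separation" else if (!fit$converged) "max_iter"
              else NA_character_
  }

  z <- beta / se
  out <- tibble::tibble(term = colnames(X), beta = beta, se = unname(se),
                        z = unname(z), p = 2 * (1 - pnorm(abs(z))))
  structure(out, class = c("pv_coef_table", class(out)),
            converged = converged, reason = reason, n_obs = nrow(dat),
            n_dropped = n_dropped, event = event, drug = target_drug)
}

# Jeffreys-penalized logistic Newton iteration: score is
# X' (y - p + h (0.5 - p)) with h the hat diagonal of W^1/2 X.
.firth_fit <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    XtW <- t(X * w)
    info <- XtW %*% X
    ch <- chol(info)
    # hat diagonal of W^1/2 X (X'WX)^-1 X' W^1/2
    root <- X * sqrt(w)
    h <- rowSums((root %*% chol2inv(ch)) * root)
    score <- drop(t(X) %*% (y - p + h * (0.5 - p)))
    beta <- beta + drop(chol2inv(ch) %*% score)
    eta <- drop(X %*% beta)
    ll <- sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(t(X * plogis(eta) * (1 - plogis(eta))) %*% X,
                        logarithm = TRUE)$modulus
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  w <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(chol2inv(chol(t(X * w) %*% X))))
  list(beta = beta, se = se, converged = converged)
}

#' Fit the adjusted model over many drug x event pairs
#'
#' Independent [fit_logistic()] calls; a failure (separation, singularity,
#' too-sparse outcome) is recorded for its pair without aborting the rest.
#'
#' @param reports Reports tibble.
#' @param events,drugs Pairs to fit.
#' @param ... Passed to [fit_logistic()].
#' @return List with `fits` (named `drug:event` list of coefficient tables
#'   or `NULL`) and `summary` (tibble drug/event/beta/se/p/converged/
#'   reason) where `beta` is the drug term.
#' @export
batch_fit <- function(reports, events, drugs = glp1_drugs(), ...) {
  fits <- list()
  rows <- list()
  for (d in drugs) {
    for (e in events) {
      key <- paste(d, e, sep = ":")
      ft <- tryCatch(
        fit_logistic(reports, e, d, comparator = setdiff(drugs, d), ...),
        error = function(cnd) conditionMessage(cnd))
      if (is.character(ft)) {
        fits[key] <- list(NULL)
        rows[[key]] <- tibble::tibble(drug = d, event = e, beta = NA_real_,
                                      se = NA_real_, p = NA_real_,
                                      converged = FALSE, reason = ft)
        next
      }
      fits[[key]] <- ft
      conv <- isTRUE(attr(ft, "converged"))
      i <- match("drug", ft$term)
      rows[[key]] <- tibble::tibble(
        drug = d, event = e,
        beta = if (conv) ft$beta[i] else NA_real_,
        se = if (conv) ft$se[i] else NA_real_,
        p = if (conv) ft$p[i] else NA_real_,
        converged = conv,
        reason = attr(ft, "reason") %||% NA_character_)
    }
  }
  list(fits = fits, summary = dplyr::bind_rows(rows))
}
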
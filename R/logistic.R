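# Logistic regression by explicit Newton-Raphson / IRLS with
# step-halving, Wald standard errors from the inverse observed
# information, and per-unit odds ratios with 95% confidence intervals.

logit_loglik <- function(eta, y) {
  sum(y * eta - log1p(exp(eta)))
}

#' Fit a logistic regression by Newton-Raphson / IRLS
#'
#' Maximizes the Bernoulli log-likelihood with Newton steps and
#' step-halving on likelihood decrease. Convergence is declared when the
#' maximum absolute score (gradient) falls below `tol`. Standard errors
#' come from the inverse observed information. Separation is flagged when
#' any non-intercept coefficient, expressed per SD of its predictor,
#' exceeds 10 in magnitude, or when the fit fails to converge.
#'
#' @param x Design matrix *without* intercept (one column per predictor),
#'   or `NULL` for an intercept-only model.
#' @param y Binary outcome vector (0/1, both classes present).
#' @param tol Score tolerance (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return An object of class `hasi_logit` with elements `coefficients`,
#'   `se`, `converged`, `n_iterations`, `log_likelihood`, `warnings`,
#'   `fitted`, `vcov`, `n`, `n_events`.
#' @export
logistic_fit <- function(x, y, tol = 1e-8, max_iter = 50) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) abort_domain("outcome must be 0/1")
  if (length(unique(y)) < 2) {
    abort_domain("outcome must contain both classes")
  }
  n <- length(y)
  if (is.null(x)) {
    xm <- matrix(1, n, 1, dimnames = list(NULL, "(intercept)"))
  } else {
    x <- as.matrix(x)
    if (nrow(x) != n) abort_domain("design and outcome sizes differ")
    if (is.null(colnames(x))) {
      colnames(x) <- paste0("x", seq_len(ncol(x)))
    }
    xm <- cbind("(intercept)" = 1, x)
  }
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) {
    dropped <- colnames(xm)[qrx$pivot[(qrx$rank + 1):ncol(xm)]]
    abort_domain(paste0("design matrix is rank deficient; collinear: ",
                        paste(dropped, collapse = ", ")))
  }
  p <- ncol(xm)
  beta <- numeric(p)
  ll <- logit_loglik(drop(xm %*% beta), y)
  converged <- FALSE
  warnings <- character(0)
  iter <- 0
  repeat {
    iter <- iter + 1
    eta <- drop(xm %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(xm, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    if (iter > max_iter) break
    w <- pmax(mu * (1 - mu), 1e-12)
    info <- crossprod(xm, xm * w)
    delta <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- logit_loglik(drop(xm %*% cand), y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    beta <- beta + step * delta
    ll <- logit_loglik(drop(xm %*% beta), y)
  }
  eta <- drop(xm %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(xm, xm * w)
  vc <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  # separation heuristic: coefficient per predictor SD
  if (p > 1) {
    sds <- apply(xm[, -1, drop = FALSE], 2, sd)
    scaled <- abs(beta[-1]) * ifelse(sds > 0, sds, 1)
    if (any(scaled > 10)) {
      warnings <- c(warnings, "separation suspected: large standardized coefficient")
    }
  }
  if (!converged) {
    warnings <- c(warnings, "fit did not converge")
  }
  epv <- sum(pmin(sum(y), n - sum(y))) / max(1, p - 1)
  if (p > 1 && epv < 10) {
    warnings <- c(warnings,
                  sprintf("events per variable = %.1f (< 10): estimates may be unstable",
                          epv))
  }
  structure(
    list(coefficients = setNames(beta, colnames(xm)),
         se = setNames(se, colnames(xm)),
         converged = converged, n_iterations = iter,
         log_likelihood = ll, warnings = warnings,
         fitted = mu, vcov = vc, n = n, n_events = sum(y)),
    class = "hasi_logit"
  )
}

#' @export
print.hasi_logit <- function(x, ...) {
  cat("Logistic fit (IRLS):", x$n, "subjects,", x$n_events, "events;",
      if (x$converged) "converged" else "NOT converged",
      "in", x$n_iterations, "iterations\n")
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hasi_logit <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  zc <- qnorm(1 - (1 - conf_level) / 2)
  est <- x$coefficients
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se),
    statistic = unname(est / x$se),
    p.value = 2 * pnorm(-abs(unname(est / x$se))),
    conf.low = unname(est - zc * x$se),
    conf.high = unname(est + zc * x$se)
  )
  if (exponentiate) {
    out$estimate <- exp(out$estimate)
    out$conf.low <- exp(out$conf.low)
    out$conf.high <- exp(out$conf.high)
  }
  out
}

#' @exportS3Method generics::glance
glance.hasi_logit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events,
         log_likelihood = x$log_likelihood,
         converged = x$converged, n_iterations = x$n_iterations,
         n_warnings = length(x$warnings))
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(coef)`, `CI = exp(coef +/- z * SE)`, Wald p from the normal
#' reference. Requires a converged fit.
#'
#' @param fit A `hasi_logit` object.
#' @param level Confidence level (default 0.95).
#' @param include_intercept Keep the intercept row (default `FALSE`).
#' @return Tibble `term`, `odds_ratio`, `ci_low`, `ci_high`, `p.value`.
#' @export
odds_ratios <- function(fit, level = 0.95, include_intercept = FALSE) {
  if (!fit$converged) {
    abort_domain(paste0(
      "fit did not converge; inspect the raw fit diagnostics ",
      "(coefficients, warnings) instead of odds ratios"
    ))
  }
  td <- tidy(fit, exponentiate = TRUE, conf_level = level)
  out <- tibble(term = td$term, odds_ratio = td$estimate,
                ci_low = td$conf.low, ci_high = td$conf.high,
                p.value = td$p.value)
  if (!include_intercept) out <- out[out$term != "(intercept)", ]
  out
}

# design-matrix builder: index + optional clinical covariates with the
# fixed coding male = 1, comorbidity present = 1
model_design <- function(cohort, index = NULL, covariates = character(0)) {
  cols <- list()
  if (!is.null(index)) {
    df <- left_join(cohort["subject_id"], index, by = "subject_id")
    if (anyNA(df$index)) abort_validation("index missing for some subjects")
    cols$hasi40 <- df$index
  }
  for (cv in covariates) {
    cols[[cv]] <- switch(cv,
      sex = as.numeric(cohort$sex == "male"),
      diabetes = as.numeric(cohort$diabetes),
      dyslipidemia = as.numeric(cohort$dyslipidemia),
      {
        if (!cv %in% names(cohort)) {
          abort_schema(paste0("covariate column absent from cohort: ", cv))
        }
        as.numeric(cohort[[cv]])
      }
    )
  }
  do.call(cbind, cols)
}

#' Univariable logistic model of group on the index
#'
#' @param cohort A validated cohort tibble.
#' @param index Per-subject index tibble (`subject_id`, `index`).
#' @return List with elements `fit` (`hasi_logit`) and `or` (tibble from
#'   [odds_ratios()]) giving the per-1-unit odds ratio; `or` is `NULL`
#'   when the fit did not converge (for example under separation).
#' @export
fit_univariable_index <- function(cohort, index) {
  require_two_groups(cohort)
  x <- model_design(cohort, index = index)
  fit <- logistic_fit(x, cohort$group)
  list(fit = fit, or = if (fit$converged) odds_ratios(fit))
}

#' Multivariable logistic model: index adjusted for clinical covariates
#'
#' Adjusts the index for age, sex, BMI, diabetes and dyslipidemia (the
#' default covariate set). With 42 subjects and 6 predictors the
#' events-per-variable ratio is well below 10 and the fit carries the
#' corresponding warning.
#'
#' @inheritParams fit_univariable_index
#' @param covariates Covariate column names.
#' @return List with elements `fit` and `or`.
#' @export
fit_multivariable_index <- function(cohort, index,
                                    covariates = c("age", "sex", "bmi",
                                                   "diabetes",
                                                   "dyslipidemia")) {
  require_two_groups(cohort)
  x <- model_design(cohort, index = index, covariates = covariates)
  fit <- logistic_fit(x, cohort$group)
  list(fit = fit, or = if (fit$converged) odds_ratios(fit))
}
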
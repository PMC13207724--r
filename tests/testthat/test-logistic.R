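test_that("closed-form fits are recovered", {
  # intercept-only, balanced events: log-odds 0
  y <- rep(c(0, 1), each = 21)
  fit <- logistic_fit(NULL, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-8)

  # intercept-only, unbalanced
  y2 <- c(rep(1, 30), rep(0, 10))
  expect_equal(unname(logistic_fit(NULL, y2)$coefficients), log(3),
               tolerance = 1e-6)

  # saturated 2x2: slope = log odds ratio; counts a=12 b=9 c=3 d=18
  x <- c(rep(1, 12), rep(0, 9), rep(1, 3), rep(0, 18))
  y3 <- c(rep(1, 21), rep(0, 21))
  fit <- suppressWarnings(logistic_fit(matrix(x, ncol = 1), y3))
  expect_equal(unname(fit$coefficients[2]), log(8), tolerance = 1e-6)
})

test_that("the score equations vanish at the optimum", {
  set.seed(2)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  y <- rbinom(200, 1, plogis(0.3 + x %*% c(0.5, -0.8, 0.2)))
  fit <- logistic_fit(x, y)
  xm <- cbind(1, x)
  expect_lt(max(abs(crossprod(xm, y - fit$fitted))), 1e-8)
})

test_that("coefficients and standard errors agree with glm", {
  set.seed(14)
  for (i in 1:5) {
    n <- 150
    x <- matrix(rnorm(n * 2), ncol = 2)
    y <- rbinom(n, 1, plogis(0.2 + x %*% c(0.8, -0.5)))
    fit <- logistic_fit(x, y)
    ref <- stats::glm(y ~ x, family = stats::binomial())
    expect_equal(unname(fit$coefficients), unname(coef(ref)),
                 tolerance = 1e-6)
    # glm stops on a deviance criterion, slightly short of our score
    # tolerance, so SEs agree a little less tightly than coefficients
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  }
})

test_that("separation and degenerate designs are detected", {
  x <- matrix(c(1:10), ncol = 1)
  y <- c(rep(0, 5), rep(1, 5))  # perfectly separated
  fit <- suppressWarnings(logistic_fit(x, y))
  expect_true(!fit$converged ||
                any(grepl("separation", fit$warnings)))

  xx <- cbind(a = rnorm(20), b = 0)
  expect_error(logistic_fit(xx, rep(c(0, 1), 10)),
               class = "hasindex_domain_error")
  expect_error(logistic_fit(matrix(rnorm(10)), rep(1, 10)),
               class = "hasindex_domain_error")
})

test_that("odds ratios exponentiate the Wald interval", {
  fit <- list(coefficients = c("(intercept)" = 0.2, hasi40 = 0),
              se = c("(intercept)" = 0.1, hasi40 = 0.5),
              converged = TRUE)
  class(fit) <- "hasi_logit"
  or <- odds_ratios(fit)
  expect_equal(or$odds_ratio, 1)
  expect_equal(or$ci_low, exp(-qnorm(0.975) * 0.5), tolerance = 1e-10)
  expect_equal(or$ci_high, exp(qnorm(0.975) * 0.5), tolerance = 1e-10)
  expect_equal(or$ci_low, 0.3753, tolerance = 1e-4)
  expect_equal(or$ci_high, 2.6645, tolerance = 1e-4)
  expect_true(or$ci_low <= or$odds_ratio & or$odds_ratio <= or$ci_high)

  fit$converged <- FALSE
  expect_error(odds_ratios(fit), class = "hasindex_domain_error")
})

test_that("negating the index negates the slope and inverts the OR", {
  co <- paper_scale_cohort(seed = 4)
  idx <- cohort_index(co)
  f1 <- fit_univariable_index(co, idx)
  idx2 <- idx; idx2$index <- -idx2$index
  f2 <- fit_univariable_index(co, idx2)
  expect_equal(unname(f2$fit$coefficients["hasi40"]),
               -unname(f1$fit$coefficients["hasi40"]), tolerance = 1e-6)
  expect_equal(f2$or$odds_ratio, 1 / f1$or$odds_ratio, tolerance = 1e-6)
})

test_that("affine predictor rescaling rescales the slope and not the fit", {
  co <- paper_scale_cohort(seed = 4)
  idx <- cohort_index(co)
  f1 <- fit_univariable_index(co, idx)
  idx3 <- idx; idx3$index <- 2.5 * idx3$index + 1
  f3 <- fit_univariable_index(co, idx3)
  expect_equal(unname(f3$fit$coefficients["hasi40"]),
               unname(f1$fit$coefficients["hasi40"]) / 2.5, tolerance = 1e-6)
  expect_equal(f3$fit$fitted, f1$fit$fitted, tolerance = 1e-8)
})

test_that("a constant index triggers a rank error; a copied covariate too", {
  co <- paper_scale_cohort(seed = 4)
  flat <- tibble::tibble(subject_id = co$subject_id, index = 1)
  expect_error(fit_univariable_index(co, flat),
               class = "hasindex_domain_error")

  idx <- cohort_index(co)
  co2 <- co; co2$age <- idx$index  # covariate duplicates the index
  expect_error(suppressWarnings(
    fit_multivariable_index(co2, idx, covariates = "age")),
    class = "hasindex_domain_error")
})

test_that("the multivariable model warns about low events per variable", {
  co <- paper_scale_cohort(seed = 4)
  idx <- cohort_index(co)
  res <- suppressWarnings(fit_multivariable_index(co, idx))
  expect_true(any(grepl("events per variable", res$fit$warnings)))
  expect_true(all(c("hasi40", "age", "sex", "bmi", "diabetes",
                    "dyslipidemia") %in% res$or$term))
})

test_that("adjusting for covariates unrelated to outcome leaves the OR", {
  # large-n no-confounding check: adjusted slope ~ univariable slope
  set.seed(77)
  n <- 2000
  idxv <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.6 * idxv))
  co <- small_cohort(n_per_group = n / 2)
  co$group <- as.integer(y)
  idx <- tibble::tibble(subject_id = co$subject_id, index = idxv)
  b_uni <- fit_univariable_index(co, idx)$fit$coefficients["hasi40"]
  b_adj <- suppressWarnings(
    fit_multivariable_index(co, idx,
                            covariates = c("bmi")))$fit$coefficients["hasi40"]
  expect_equal(unname(b_adj), unname(b_uni), tolerance = 0.05)
})
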
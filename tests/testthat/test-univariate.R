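test_that("Mann-Whitney U and exact p match hand enumeration", {
  r <- mw_test(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")

  r <- mw_test(c(1, 4), c(2, 3))
  expect_equal(r$statistic, 2)  # n1 n2 / 2, perfectly balanced
  expect_equal(r$p.value, 1)

  x <- c(3, 1, 4, 1, 5)
  r <- mw_test(x, x)
  expect_equal(r$statistic, length(x)^2 / 2)  # tie credit
  expect_equal(r$p.value, 1)
})

test_that("exact Mann-Whitney agrees with the enumeration oracle on random inputs", {
  set.seed(101)
  for (i in 1:25) {
    n1 <- sample(1:5, 1); n2 <- sample(1:5, 1)
    x <- sample(1:6, n1, replace = TRUE)  # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    got <- mw_test(x, y, method = "exact")
    want <- oracle_mw_exact(x, y)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p.value, want$p, tolerance = 1e-12)
  }
})

test_that("asymptotic Mann-Whitney matches the tie-corrected normal approximation", {
  set.seed(7)
  x <- rnorm(25); y <- rnorm(30) + 0.5
  got <- mw_test(x, y, method = "asymptotic")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(got$statistic, unname(ref$statistic))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)

  # tied data
  x <- sample(1:4, 20, replace = TRUE); y <- sample(1:4, 25, replace = TRUE)
  got <- mw_test(x, y, method = "asymptotic")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("asymptotic p is close to exact p for moderate tie-free samples", {
  # the normal approximation is within 0.02 of the exact p once both
  # groups have >= 6 members (n >= 12); below that the exact law is too
  # discrete for the bound and the gap can reach ~0.04
  set.seed(33)
  for (i in 1:15) {
    n1 <- sample(6:8, 1); n2 <- sample(6:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    pe <- mw_test(x, y, method = "exact")$p.value
    pa <- mw_test(x, y, method = "asymptotic")$p.value
    expect_lte(abs(pe - pa), 0.02)
  }
  for (i in 1:10) {
    n1 <- sample(2:5, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_lte(abs(mw_test(x, y, method = "exact")$p.value -
                     mw_test(x, y, method = "asymptotic")$p.value), 0.05)
  }
})

test_that("Fisher's exact 2x2 test enumerates the conditional law", {
  expect_equal(fisher_exact_2x2(1, 0, 0, 1), 1)
  expect_equal(fisher_exact_2x2(0, 21, 7, 14), 0.008621, tolerance = 1e-4)
  # transpose symmetry
  set.seed(5)
  for (i in 1:20) {
    tb <- sample(0:12, 4, replace = TRUE)
    if (sum(tb) == 0) next
    p1 <- fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4])
    p2 <- fisher_exact_2x2(tb[1], tb[3], tb[2], tb[4])
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, oracle_fisher(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-9)
    ref <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    expect_equal(p1, ref, tolerance = 1e-7)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4),
               class = "hasindex_domain_error")
})

test_that("Pearson chi-square matches its closed form and base R", {
  r <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)

  r <- chi_square_2x2(20, 10, 10, 20)
  expect_equal(r$statistic, 60 * (20 * 20 - 10 * 10)^2 / 30^4,
               tolerance = 1e-12)
  expect_equal(r$statistic, 6.6667, tolerance = 1e-4)

  # statistic scales with N at fixed proportions
  expect_equal(chi_square_2x2(40, 20, 20, 40)$statistic,
               2 * chi_square_2x2(20, 10, 10, 20)$statistic)

  ref <- stats::chisq.test(matrix(c(17, 8, 5, 12), 2), correct = FALSE)
  got <- chi_square_2x2(17, 5, 8, 12)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)

  expect_error(chi_square_2x2(0, 0, 3, 4), class = "hasindex_domain_error")
})

test_that("expected-cell rule switches between Fisher and chi-square", {
  expect_equal(compare_counts_2x2(1, 20, 7, 14)$method, "fisher")
  expect_equal(compare_counts_2x2(20, 10, 10, 20)$method, "chi-square")
})

test_that("BH adjustment matches the step-up definition and p.adjust", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(c(0.004, 0.012, 0.018)), c(0.012, 0.018, 0.018))

  set.seed(12)
  for (i in 1:40) {
    m <- sample(1:50, 1)
    p <- round(runif(m), 3)  # rounding forces ties
    q <- adjust_bh(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in p
    expect_equal(length(unique(q[duplicated(p) | duplicated(p, fromLast = TRUE)])) <=
                   length(unique(p[duplicated(p) | duplicated(p, fromLast = TRUE)])),
                 TRUE)
  }
  expect_error(adjust_bh(c(0.5, 1.2)), class = "hasindex_domain_error")
})

test_that("Spearman rho is Pearson on midranks, symmetric, exact for small n", {
  expect_equal(spearman_test(1:8, (1:8)^3)$rho, 1)
  r <- spearman_test(c(1, 2, 3), c(3, 1, 2))
  expect_equal(r$rho, -0.5)

  set.seed(21)
  x <- sample(1:5, 12, replace = TRUE); y <- sample(1:5, 12, replace = TRUE)
  expect_equal(spearman_test(x, y)$rho,
               cor(rank(x), rank(y)))  # ties via midranks
  expect_equal(spearman_test(x, y)$rho, spearman_test(y, x)$rho)
  expect_equal(spearman_test(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)

  # exact tie-free null distribution against cor.test's exact p
  for (n in c(4, 5, 6, 7, 8)) {
    for (i in 1:4) {
      x <- sample(n); y <- sample(n)
      got <- spearman_test(x, y)
      ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                              exact = TRUE))
      expect_equal(got$method, "exact")
      expect_equal(got$p.value, ref$p.value, tolerance = 1e-9)
    }
  }

  # t-approximation branch for larger n
  set.seed(3)
  x <- rnorm(40); y <- x + rnorm(40)
  got <- spearman_test(x, y)
  rho <- got$rho
  tstat <- rho * sqrt((40 - 2) / (1 - rho^2))
  expect_equal(got$p.value, 2 * pt(-abs(tstat), 38), tolerance = 1e-12)

  expect_error(spearman_test(rep(1, 5), 1:5),
               class = "hasindex_degenerate_error")
})

test_that("panel comparison mirrors the per-metabolite table layout", {
  co <- paper_scale_cohort(seed = 6)
  idx <- cohort_index(co)
  tab <- compare_panel(co, index = idx)
  expect_equal(tab$variable, c(aa_panel()$metabolite, "HASI-40"))
  mets <- tab[tab$variable != "HASI-40", ]
  expect_equal(mets$q.value, adjust_bh(mets$p.value))
  expect_true(is.na(tab$q.value[tab$variable == "HASI-40"]))
  # medians agree with direct computation
  expect_equal(mets$group0_median[mets$variable == "serine"],
               median(co$serine[co$group == 0]))
})

test_that("identical groups give p = 1 for every metabolite", {
  co <- small_cohort(n_per_group = 5)
  g0 <- co[co$group == 0, ]
  dup <- g0
  dup$group <- 1L
  dup$subject_id <- paste0("dup", seq_len(nrow(dup)))
  co2 <- validate_cohort(dplyr::bind_rows(g0, dup))
  tab <- compare_panel(co2)
  expect_true(all(tab$p.value == 1))
})

test_that("LVEF correlations cover the panel plus the index", {
  co <- paper_scale_cohort(seed = 13)
  idx <- cohort_index(co)
  tab <- correlate_with_lvef(co, index = idx)
  expect_equal(nrow(tab), 24)
  expect_true(all(abs(tab$rho) <= 1))
  expect_equal(tab$rho[tab$variable == "serine"],
               cor(co$serine, co$lvef, method = "spearman"),
               tolerance = 1e-12)
})
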
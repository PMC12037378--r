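# Rank statistics and 2x2 association measures against independent oracles.

test_that("spearman_correlation handles monotone and random cases", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  set.seed(8)
  for (i in 1:5) {
    a <- rnorm(8)
    b <- sample(c(rnorm(7), a[3]))  # occasional tie
    expect_equal(spearman_correlation(a, b)$rho, oracle_spearman(a, b),
                 tolerance = 1e-12)
  }
  expect_error(spearman_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("spearman p-value matches the t approximation", {
  set.seed(21)
  x <- rnorm(30); y <- x + rnorm(30, 0, 2)
  got <- spearman_correlation(x, y)
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  # cor.test uses the same t approximation when exact = FALSE
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("kruskal_wallis matches the rank-sum formula oracle and stats::", {
  g <- list(c(1.2, 3.4, 2.2), c(5.5, 2.2, 7.1), c(0.3, 9.9, 2.2))
  got <- kruskal_wallis(g)
  expect_equal(got$H, oracle_kw(g), tolerance = 1e-12)
  ref <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
  expect_equal(got$H, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  # permuted labels of one sample: H near 0 expectation not required, but
  # identical values across groups must give exactly H = 0, p = 1
  expect_equal(kruskal_wallis(list(rep(2, 3), rep(2, 4))),
               list(H = 0, p_value = 1, df = 1))
  expect_error(kruskal_wallis(list(1:3)), "at least 2")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
})

test_that("completely separated ranks maximise H over label permutations", {
  vals <- c(1, 2, 3, 10, 11, 12)
  sep <- kruskal_wallis(list(vals[1:3], vals[4:6]))$H
  # brute force over all 3-subsets as group one
  combs <- utils::combn(6, 3)
  hs <- apply(combs, 2, function(i)
    kruskal_wallis(list(vals[i], vals[-i]))$H)
  expect_equal(max(hs), sep, tolerance = 1e-12)
})

test_that("chi-square agrees with the expected-count oracle and stats::", {
  tab <- matrix(c(20, 10, 10, 20), 2)
  got <- chi_square_association(tab)
  expect_equal(got$chi2, oracle_chi2(tab), tolerance = 1e-12)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)

  yates <- chi_square_association(tab, yates = TRUE)
  refy <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  expect_equal(yates$chi2, unname(refy$statistic), tolerance = 1e-12)

  # proportional table -> independence
  expect_equal(chi_square_association(matrix(c(10, 20, 30, 60), 2))$chi2, 0)
  # column permutation invariance on a 2x3 table
  t23 <- matrix(c(5, 9, 12, 3, 7, 11), 2)
  expect_equal(chi_square_association(t23)$chi2,
               chi_square_association(t23[, c(3, 1, 2)])$chi2)
  expect_error(chi_square_association(matrix(c(0, 0, 3, 4), 2)),
               "zero marginal in column 1")
})

test_that("odds_ratio matches arithmetic and the log-variance oracle", {
  bal <- odds_ratio(contingency_2x2(10, 10, 10, 10))
  expect_equal(bal$odds_ratio, 1)
  expect_true(bal$ci_low < 1 && bal$ci_high > 1)
  expect_equal(odds_ratio(contingency_2x2(50, 50, 25, 50))$odds_ratio, 2)

  got <- odds_ratio(contingency_2x2(40, 40, 20, 40))
  ci <- oracle_or_ci(40, 40, 20, 40)
  expect_equal(got$ci_low, ci[1], tolerance = 1e-10)
  expect_equal(got$ci_high, ci[2], tolerance = 1e-10)
  expect_false(got$haldane_corrected)

  # Haldane-Anscombe on a zero cell
  z <- odds_ratio(contingency_2x2(0, 10, 5, 10))
  expect_true(z$haldane_corrected)
  expect_equal(z$odds_ratio, (0.5 * 10.5) / (10.5 * 5.5))
  expect_error(odds_ratio(contingency_2x2(0, 5, 5, 0)), "diagonal")
})

test_that("complication_odds builds the lifespan-dichotomy tables", {
  df <- data.frame(rbc_lifespan_days = c(50, 60, 80, 100, 110, 120),
                   cvd_flag = c(1, 1, 0, 0, 0, 1))
  or <- complication_odds(df)
  # exposed: 2 cases / 1 noncase; unexposed: 1 case / 2 noncases
  expect_equal(or$odds_ratio, (2 * 2) / (1 * 1))
  expect_error(complication_odds(data.frame(rbc_lifespan_days = 1)),
               "no complication flags")
})
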
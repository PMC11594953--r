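test_that("cross-tabulation counts patients and reproduces margins", {
  same <- sm_category(c(0, 1, 2, 3, 3))
  tab <- sf_lf_crosstab(same, same)
  expect_equal(sum(diag(tab$counts)), 5)
  expect_equal(sum(tab$counts) - sum(diag(tab$counts)), 0)

  set.seed(5)
  sf <- sample(0:3, 117, replace = TRUE)
  lf <- sample(0:3, 117, replace = TRUE)
  tab <- sf_lf_crosstab(sf, lf)
  expect_equal(tab$n, 117)
  expect_equal(sum(tab$counts), 117)
  expect_equal(as.numeric(tab$sf_margin), as.numeric(table(factor(sf, 0:3))))
  expect_equal(as.numeric(tab$lf_margin), as.numeric(table(factor(lf, 0:3))))
  # margins survive any permutation of the pairing
  tab2 <- sf_lf_crosstab(sf, sample(lf))
  expect_equal(tab2$sf_margin, tab$sf_margin)
  expect_equal(tab2$lf_margin, tab$lf_margin)

  expect_error(sf_lf_crosstab(integer(0), integer(0)), "empty")
  expect_error(sf_lf_crosstab(0:1, 0:2), "length")
})

test_that("concordance proportion equals a per-patient match count", {
  ident <- sf_lf_crosstab(rep(0:3, 5), rep(0:3, 5))
  rep_ident <- concordance_proportion(ident)
  expect_equal(rep_ident$exact_agreement, 1)
  expect_true(rep_ident$meets_primary_endpoint)

  anti <- sf_lf_crosstab(rep(0:3, 5), rep(3:0, 5))
  rep_anti <- concordance_proportion(anti)
  expect_equal(rep_anti$exact_agreement, 0)
  expect_false(rep_anti$meets_primary_endpoint)

  set.seed(99)
  sf <- sample(0:3, 117, replace = TRUE)
  lf <- sample(0:3, 117, replace = TRUE)
  rep_rand <- concordance_proportion(sf_lf_crosstab(sf, lf))
  # brute-force per-patient comparison oracle
  expect_equal(rep_rand$exact_agreement, mean(sf == lf))
  extreme <- sf %in% c(0, 3) | lf %in% c(0, 3)
  expect_equal(rep_rand$extreme_agreement,
               sum(sf == lf & sf %in% c(0, 3)) / sum(extreme))
})

test_that("uncorrected Pearson chi-squared reproduces the readmission contrast", {
  tab <- contingency_2x2(5, 8, 31, 7) # good 5/13 vs poor 31/38 readmitted
  res <- pearson_chi2_2x2(tab)
  expect_equal(res$statistic, 8.674, tolerance = 1e-3)
  expect_equal(res$df, 1L)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$p_value, 0.0032, tolerance = 0.02)
  # with Yates correction the statistic drops well below the uncorrected one
  expect_lt(pearson_chi2_2x2(tab, correct = TRUE)$statistic, res$statistic)

  flat <- contingency_2x2(10, 10, 10, 10)
  expect_equal(pearson_chi2_2x2(flat)$statistic, 0)
  expect_equal(pearson_chi2_2x2(flat)$p_value, 1)

  expect_error(pearson_chi2_2x2(contingency_2x2(0, 0, 5, 5)), "exact")
})

test_that("chi-squared matches the expected-count oracle on random tables", {
  set.seed(42)
  checked <- 0
  while (checked < 200) {
    cells <- sample(1:30, 4, replace = TRUE)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    # oracle: sum over cells of (observed - expected)^2 / expected
    rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
    expected <- outer(rs, cs) / n
    oracle <- sum((tab - expected)^2 / expected)
    expect_equal(pearson_chi2_2x2(tab)$statistic, oracle, tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("chi-squared is invariant under row and column swaps", {
  set.seed(17)
  for (i in 1:25) {
    cells <- sample(1:40, 4, replace = TRUE)
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    s <- pearson_chi2_2x2(tab)$statistic
    expect_equal(pearson_chi2_2x2(tab[2:1, ])$statistic, s)
    expect_equal(pearson_chi2_2x2(tab[, 2:1])$statistic, s)
    # zero iff odds ratio 1 on positive tables
    if (abs(prod(diag(tab)) - tab[1, 2] * tab[2, 1]) < .Machine$double.eps) {
      expect_equal(s, 0)
    } else {
      expect_gt(s, 0)
    }
  }
})

test_that("enumeration exact test matches hypergeometric ground truth", {
  expect_equal(exact_test_2x2(contingency_2x2(1, 0, 0, 1)), 1.0)
  expect_equal(exact_test_2x2(contingency_2x2(5, 0, 0, 5)), 1 / 126)
  # independent cross-check against the standard implementation
  set.seed(8)
  for (i in 1:50) {
    cells <- sample(0:15, 4, replace = TRUE)
    if (sum(cells) == 0) next
    tab <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    p <- exact_test_2x2(tab)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
  }
  # on the study table both tests are significant at 0.05; the asymptotic
  # Pearson p (0.0032) clears 0.01 while the exact p (0.0106) sits just above
  study <- contingency_2x2(5, 8, 31, 7)
  expect_lt(exact_test_2x2(study), 0.05)
  expect_lt(pearson_chi2_2x2(study)$p_value, 0.01)
  expect_equal(exact_test_2x2(study), 0.0106, tolerance = 1e-2)
})

test_that("category distribution stats match the expanded score list", {
  res <- category_distribution_stats(c(13, 46, 20, 38))
  expect_equal(round(res$mean, 2), 1.71)
  expect_equal(round(res$sd, 2), 1.04)
  expect_equal(res$range, c(0, 3))

  expect_equal(category_distribution_stats(c(0, 25, 0, 0))$sd, 0)
  two <- category_distribution_stats(c(1, 1))
  expect_equal(two$mean, 0.5)
  expect_equal(two$sd, sqrt(0.5), tolerance = 1e-12)

  set.seed(12)
  for (i in 1:30) {
    counts <- sample(0:20, 4, replace = TRUE)
    if (sum(counts) < 2) next
    expanded <- rep(0:3, counts)
    res <- category_distribution_stats(counts)
    expect_equal(res$mean, mean(expanded))
    expect_equal(res$sd, sd(expanded))
  }
  expect_error(category_distribution_stats(c(0, 0, 0, 0)), "zero")
})
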
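test_that("TPM arithmetic matches hand computation", {
  expect_equal(tpm(50, 1e7), 5)
  expect_equal(tpm(3, 1e6), 3)
  expect_equal(tpm(0, 1e6), 0)
  expect_error(tpm(5, 0), "positive")
})

test_that("the pseudocount replaces zero-count TPM values only", {
  expect_equal(apply_pseudocount(0, 0), 0.01)
  expect_equal(apply_pseudocount(0.08, 1), 0.08)
  # a zero-count library entry prints as 0.01 in the published tables
  row <- conserved_mirna_table()
  mir827 <- row[row$mirna_id == "tae-miR827-5p", ]
  expect_equal(mir827$tpm_t1, 0.01)
  expect_equal(apply_pseudocount(0, 0), mir827$tpm_t1)
})

test_that("log2 ratios reproduce published table rows at two decimals", {
  expect_equal(round(log2_ratio(1.71, 0.25), 2), 2.77)
  expect_equal(round(log2_ratio(4.08, 1036.32), 2), -7.99)
  expect_equal(log2_ratio(3.14, 3.14), 0)
  expect_error(log2_ratio(0, 1), "positive")
})

test_that("the exact Poisson test matches direct-summation oracles", {
  # identical empty libraries: two-sided p capped at 1
  expect_equal(ac_test(0, 1e6, 0, 1e6), 1)
  # frozen fixture value from the direct-summation oracle
  expect_equal(ac_test(5, 1e4, 25, 1e4), oracle_ac_test(5, 1e4, 25, 1e4),
               tolerance = 1e-9)
  # grids against the term-by-term and negative-binomial-tail oracles
  set.seed(10)
  for (i in 1:50) {
    x <- sample(0:50, 1)
    y <- sample(0:50, 1)
    n1 <- sample(c(1e4, 1e6, 1e7), 1)
    n2 <- sample(c(1e4, 2e6, 1e7), 1)
    p <- ac_test(x, n1, y, n2)
    expect_equal(p, oracle_ac_test(x, n1, y, n2), tolerance = 1e-9)
    expect_equal(p, oracle_ac_test_nb(x, n1, y, n2), tolerance = 1e-9)
  }
})

test_that("the conditional distribution normalises to one", {
  for (x in c(0, 3, 20)) {
    for (f in c(0.5, 1, 2.3)) {
      total <- sum(exp(mirpattern:::ac_log_pmf(0:5000, x, f)))
      expect_equal(total, 1, tolerance = 1e-12)
    }
  }
})

test_that("the exact Poisson test depends only on counts at equal totals", {
  for (n in c(1e4, 1e6, 3e7)) {
    expect_equal(ac_test(7, n, 19, n), ac_test(7, 1e5, 19, 1e5),
                 tolerance = 1e-12)
  }
})

test_that("chi-square matches the textbook 2x2 Pearson formula", {
  # equal proportions: statistic 0, p 1
  r <- chisq_test2(30, 1000, 30, 1000)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- chisq_test2(30, 1000, 10, 1000)
  # hand-computed Pearson statistic on [[30, 970], [10, 990]]
  hand <- 2000 * (30 * 990 - 970 * 10)^2 / (1000 * 1000 * 40 * 1960)
  expect_equal(r2$statistic, hand)
  # cross-check against the standard implementation
  ref <- stats::chisq.test(matrix(c(30, 970, 10, 990), 2, byrow = TRUE),
                           correct = FALSE)
  expect_equal(r2$statistic, unname(ref$statistic))
  expect_equal(r2$p_value, ref$p.value)

  # library swap symmetry
  expect_equal(chisq_test2(30, 1000, 10, 2000)$p_value,
               chisq_test2(10, 2000, 30, 1000)$p_value)

  # degenerate table
  r3 <- chisq_test2(0, 1000, 0, 1000)
  expect_true(r3$degenerate)
  expect_equal(r3$p_value, 1)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.02), 0.02)
  expect_equal(bh_fdr(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  # q >= p and order invariance
  set.seed(11)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  perm <- sample(40)
  expect_equal(bh_fdr(p[perm]), q[perm])
  expect_error(bh_fdr(c(0.5, 0)), "p > 0")
})

test_that("screening applies the p, FDR and fold thresholds jointly", {
  res <- tibble::tibble(
    mirna_id = c("a", "b", "c"), genotype = "genotype1",
    p_value = c(0.005, 0.005, 0.001),
    q_value = c(0.005, 0.02, 0.001),
    fold_change = c(4, 4, 1.5)
  )
  kept <- screen_de(res, screen_criteria())
  expect_equal(kept$mirna_id, "a")
})

test_that("diff_expression assembles per-contrast results and tidiers", {
  counts <- tibble::tibble(mirna_id = c("m1", "m2", "m3"),
                           c1 = c(100L, 50L, 0L), t1 = c(400L, 50L, 80L),
                           c2 = c(100L, 55L, 10L), t2 = c(25L, 50L, 10L))
  totals <- c(c1 = 1e6, t1 = 1e6, c2 = 1e6, t2 = 1e6)
  de <- diff_expression(counts, totals)
  td <- tidy(de)
  expect_equal(nrow(td), 6)
  m1g1 <- td[td$mirna_id == "m1" & td$genotype == "genotype1", ]
  expect_equal(m1g1$log2_ratio, 2)
  expect_lt(m1g1$p_value, 1e-10)
  # zero-count control is pseudocount-substituted before the ratio
  m3g1 <- td[td$mirna_id == "m3" & td$genotype == "genotype1", ]
  expect_true(m3g1$sub_control)
  expect_equal(m3g1$tpm_control, 0.01)
  g <- glance(de)
  expect_equal(g$n_mirnas, 3)
  expect_equal(g$n_tests, 6)
  expect_s3_class(autoplot(de), "ggplot")
  # chi-square route runs through the same surface
  de2 <- diff_expression(counts, totals, test = "chisq")
  expect_true(all(tidy(de2)$p_value >= 0 & tidy(de2)$p_value <= 1))
})

test_that("type-I error of the exact test is controlled at the null", {
  set.seed(12)
  n_sim <- 3000
  x <- rpois(n_sim, 20)
  y <- rpois(n_sim, 20)
  p <- ac_test(x, 1e6, y, 1e6)
  expect_lte(mean(p < 0.01), 0.015)
})
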
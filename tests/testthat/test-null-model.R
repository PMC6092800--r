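test_that("branch frequencies normalise under all weight modes", {
  bs <- load_branch_system()
  f0 <- estimate_frequencies(c(10, rep(0, 9)), bs)
  expect_equal(f0$F, c(1, rep(0, 9)))
  expect_equal(estimate_frequencies(c(10, rep(0, 9)), bs,
                                    "multiply_duration")$F,
               c(1, rep(0, 9)))
  f1 <- estimate_frequencies(rep(7, 10), bs)
  expect_equal(f1$F, rep(0.1, 10))

  # durations (50, 10): counts (5, 5) weighted by duration -> (5/6, 1/6)
  bs2 <- branch_system(c(60, 10))
  f2 <- estimate_frequencies(c(5, 5), bs2, "multiply_duration")
  expect_equal(f2$F, c(5 / 6, 1 / 6))
  f3 <- estimate_frequencies(c(5, 5), bs2, "divide_duration")
  expect_equal(f3$F, c(1 / 6, 5 / 6))

  # from a named birth vector, with the source size recorded
  b <- setNames(c(2L, 2L, 5L), c("g1", "g2", "g3"))
  f4 <- estimate_frequencies(b, bs)
  expect_equal(f4$source_n, 3L)
  expect_equal(sum(f4$F), 1)
  expect_equal(f4$F[2], 2 / 3)

  expect_error(estimate_frequencies(rep(0, 10), bs), "all-zero|zero")
})

test_that("expected counts follow the corrected closed form", {
  # all receptors in branch 1, F concentrated there: everything synchronous
  e <- expected_counts(c(5, 0, 0), c(1, 0, 0))
  expect_equal(unname(e$expected), c(0, 5, 0))
  # two receptors, uniform F on 2 branches: brute-force over the 4 cells
  e2 <- expected_counts(c(1, 1), c(0.5, 0.5))
  expect_equal(unname(e2$expected), c(0.5, 1.0, 0.5))
  expect_error(expected_counts(c(1, 1), c(0.5, 0.25, 0.25)),
               "length mismatch")
})

test_that("expected counts equal brute-force enumeration and conserve n", {
  set.seed(21)
  for (i in 1:50) {
    K <- sample(2:10, 1)
    R <- rpois(K, 5)
    if (sum(R) == 0) R[1] <- 1
    F <- random_simplex(K)
    e <- expected_counts(R, F)
    expect_equal(e$expected, oracle_expected(R, F), tolerance = 1e-12)
    expect_equal(sum(e$expected), sum(R), tolerance = 1e-9)
  }
})

test_that("degenerate frequencies empty the impossible category", {
  # F on the most ancestral branch: no ligand can appear after it
  e <- expected_counts(c(0, 3, 4), c(1, 0, 0))
  expect_equal(e$expected[["LA"]], 0)
  expect_equal(e$expected[["LB"]], 7)
  # F on the youngest branch: no ligand can appear before it
  e2 <- expected_counts(c(3, 4, 0), c(0, 0, 1))
  expect_equal(e2$expected[["LB"]], 0)
  expect_equal(e2$expected[["LA"]], 7)
})

test_that("the literal printed expectation is non-conserving, the default is not", {
  R <- c(2, 3, 5); F <- c(0.2, 0.3, 0.5)
  lit <- expected_counts(R, F, literal = TRUE)
  expect_gt(abs(sum(lit$expected) - sum(R)), 0.1)
  expect_equal(lit$expected[["LS"]], expected_counts(R, F)$expected[["LS"]])
})

test_that("goodness of fit reproduces the study chi-squared", {
  e <- c(256, 102, 195)
  z <- gof_test(c(116, 225, 212), e)
  expect_equal(z$statistic, 226.368, tolerance = 1e-3)
  expect_equal(z$df, 2L)
  expect_lt(z$p.value, 1e-15)

  z0 <- gof_test(c(10, 20, 30), c(10, 20, 30))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$p.value, 1)

  expect_warning(gof_test(c(10, 20, 30), c(5, 5, 5)), "total")
  expect_error(gof_test(c(1, 2, 3), c(0, 3, 3)), "pool")
})

test_that("pairwise equal-proportion tests reproduce the printed p-values", {
  expect_equal(equal_proportion_test(225, 212)$p.value, 0.534,
               tolerance = 5e-4)
  expect_equal(signif(equal_proportion_test(116, 225)$p.value, 2), 3.6e-09)
  expect_equal(signif(equal_proportion_test(116, 212)$p.value, 2), 1.2e-07)
  z <- equal_proportion_test(100, 100)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
  expect_error(equal_proportion_test(0, 0), "not both zero")
})
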
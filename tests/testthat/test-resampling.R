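test_that("permutation draws are deterministic, conserving and degenerate-safe", {
  R <- c(0, 4, 0, 6, 0)
  F <- random_simplex(5)
  n1 <- draw_null(R, F, reps = 200, seed = 42)
  n2 <- draw_null(R, F, reps = 200, seed = 42)
  expect_identical(n1$counts, n2$counts)
  expect_true(all(rowSums(n1$counts) == sum(R)))

  # point-mass F on the only occupied branch: every replicate all-LS
  p <- draw_null(c(0, 7, 0), c(0, 1, 0), reps = 50, seed = 1)
  expect_true(all(p$counts[, "LS"] == 7L))
  expect_true(all(p$counts[, c("LB", "LA")] == 0L))

  expect_error(draw_null(R, F, reps = 0), "reps")
})

test_that("permutation mean matches the analytic expectation", {
  set.seed(31)
  R <- rpois(10, 20); R[1] <- R[1] + 1
  F <- random_simplex(10)
  reps <- 4000L
  nul <- draw_null(R, F, reps = reps, seed = 77)
  e <- expected_counts(R, F)$expected
  for (k in c("LB", "LS", "LA")) {
    se <- sd(nul$counts[, k]) / sqrt(reps)
    expect_lt(abs(mean(nul$counts[, k]) - e[[k]]), 3 * max(se, 1e-8))
  }
})

test_that("the null distance spectrum peaks at zero for uniform frequencies", {
  # combinatorial edge effect: a gap of 0 is achievable from all K branches,
  # a gap of +/-d only from K - d of them
  K <- 10L
  R <- rep(20L, K)
  nul <- draw_null(R, rep(1 / K, K), reps = 2000, seed = 5,
                   keep_distances = TRUE)
  h <- nul$distance_hist
  expect_equal(sum(h), sum(R), tolerance = 1e-9)
  expect_true(all(h[["0"]] > h[names(h) != "0"]))
  # and mass decays with |distance|
  d <- abs(as.integer(names(h)))
  expect_true(cor(d, as.numeric(h), method = "spearman") < -0.9)
})

test_that("empirical p-values use the add-one rule and are monotone", {
  nul <- draw_null(c(50, 50), c(0.5, 0.5), reps = 199, seed = 3)
  expect_equal(empirical_pvalue(0, nul, "LS", "greater"), 1)
  expect_equal(empirical_pvalue(101, nul, "LS", "greater"), 1 / 200)
  expect_equal(empirical_pvalue(101, nul, "LS", "less"), 1)
  ps <- vapply(0:100, empirical_pvalue, numeric(1), null = nul,
               category = "LS", side = "greater")
  expect_true(all(diff(ps) <= 0))
  med <- median(nul$counts[, "LS"])
  expect_lt(abs(empirical_pvalue(med, nul, "LS", "greater") - 0.5), 0.1)
})

test_that("branch correlation recovers perfect and planted relations", {
  perf <- classify_pairs(data.frame(receptor_branch = 1:3,
                                    ligand_branch = 2:4))
  z <- branch_correlation(perf, exclude_synchronous = FALSE)
  expect_equal(z$r, 1)
  expect_equal(z$n_used, 3L)

  # Excluding the synchronous diagonal biases the independent-draw
  # correlation slightly negative: for uniform branch draws over K
  # branches the off-diagonal correlation is exactly -1/(K - 1).
  # Near-branch coupling must overcome that and come out clearly positive.
  mk <- function(theta, rho, seed) {
    sim <- simulate_cobirth_data(synthetic_config(
      n_receptors = 800, n_genome_genes = 10, n_families = 40,
      coupling_theta = theta, near_branch_decay = rho, ligand_lambda = 0,
      frac_synthesized = 0, seed = seed))
    classify_pairs(reduce_to_first_ligand(sim$interactions, sim$births))
  }
  indep <- branch_correlation(mk(0, 1, 19))
  expect_lt(abs(indep$r - (-1 / 9)), 0.12)
  coupled <- branch_correlation(mk(0.3, 0.4, 19))
  expect_gt(coupled$r, 0.15)
  expect_lt(coupled$p.value, 1e-3)
  expect_gt(coupled$r, indep$r + 0.2)

  flat <- classify_pairs(data.frame(receptor_branch = c(2, 2, 2),
                                    ligand_branch = c(3, 4, 5)))
  expect_error(branch_correlation(flat, exclude_synchronous = FALSE),
               "zero variance")
  expect_error(branch_correlation(perf[1:2, ], exclude_synchronous = FALSE),
               "at least 3")
})
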
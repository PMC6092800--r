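test_that("weight classes follow the dalton cut-points", {
  expect_equal(weight_class(c(100, 549, 550, 25000, 25001)),
               c("small", "small", "medium", "medium", "big"))
  expect_error(weight_class(-3), "positive")
})

test_that("two perfectly associated binary variables load one dimension", {
  x <- rep(c("a", "b"), each = 50)
  m <- run_mca(data.frame(p = x, q = x), n_dims = 1)
  # total inertia J/Q - 1 = 4/2 - 1 = 1, carried entirely by dimension 1
  expect_equal(m$total_inertia, 1, tolerance = 1e-10)
  expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  expect_length(m$eigenvalues, 1L)
  # paired levels co-locate
  lc <- m$level_coords[, 1]
  expect_equal(lc[["p.a"]], lc[["q.a"]], tolerance = 1e-8)
  expect_true(sign(lc[["p.a"]]) != sign(lc[["p.b"]]))
})

test_that("MCA eigenvalues match the canonical-correlation oracle for Q = 2", {
  set.seed(42)
  x <- sample(letters[1:3], 200, TRUE)
  y <- sample(LETTERS[1:4], 200, TRUE)
  m <- run_mca(data.frame(x = x, y = y), n_dims = 2)
  rho <- MASS::corresp(unclass(table(x, y)), nf = 2)$cor
  oracle <- sort(c((1 + rho) / 2, (1 - rho) / 2,
                   rep(0.5, (3 - 1) + (4 - 1) - 2 * length(rho))),
                 decreasing = TRUE)
  expect_equal(sort(m$eigenvalues, decreasing = TRUE), oracle,
               tolerance = 1e-10)
})

test_that("MCA structural identities hold on random trait tables", {
  set.seed(9)
  for (i in 1:5) {
    n <- 120
    tr <- data.frame(a = sample(letters[1:3], n, TRUE),
                     b = sample(letters[1:4], n, TRUE),
                     c = sample(letters[1:2], n, TRUE))
    m <- run_mca(tr, n_dims = 2)
    J <- sum(vapply(tr, function(v) length(unique(v)), integer(1)))
    expect_equal(m$total_inertia, J / 3 - 1, tolerance = 1e-9)
    expect_true(all(diff(m$eigenvalues) <= 1e-12))
    expect_true(all(m$eigenvalues >= 0))
    # permuting rows leaves eigenvalues unchanged
    m2 <- run_mca(tr[sample(n), , drop = FALSE], n_dims = 2)
    expect_equal(m$eigenvalues, m2$eigenvalues, tolerance = 1e-10)
  }
})

test_that("a planted big-ligand/LS association surfaces on dimension 1", {
  set.seed(123)
  n <- 300
  cat <- sample(c("LB", "LS", "LA"), n, TRUE)
  w <- ifelse(cat == "LS" & runif(n) < 0.85, 30000,
              sample(c(200, 5000), n, TRUE))
  pairs <- data.frame(category = cat, family_id = "f")
  tt <- make_trait_table(pairs, weight_da = w,
                         signal_type = sample(c("hormone", "neuropeptide"),
                                              n, TRUE),
                         include_family = FALSE)
  m <- run_mca(tt, n_dims = 2)
  d1 <- m$level_coords[, 1]
  expect_gt(d1[["appearance.LS"]] * d1[["weight_class.big"]], 0)
  # and the association disappears when the labels are shuffled
  tt$appearance <- sample(tt$appearance)
  m0 <- run_mca(tt, n_dims = 2)
  score <- function(m) {
    d <- m$level_coords[, 1]
    abs(d[["appearance.LS"]] - d[["weight_class.big"]]) <
      abs(d[["appearance.LS"]] - d[["weight_class.small"]])
  }
  expect_true(score(m))
  expect_gt(m$eigenvalues[1], m0$eigenvalues[1])
})

test_that("MCA validates inputs and supports variable down-weighting", {
  tr <- data.frame(a = rep(c("x", "y"), 10), b = rep("z", 20))
  expect_error(run_mca(tr), "single observed level.*b")
  tr$b <- rep(c("z", "w"), each = 10)
  expect_error(run_mca(tr, n_dims = 5), "exceeds")
  m <- run_mca(tr, n_dims = 1, var_weights = c(b = 0.2))
  expect_s3_class(m, "mca_result")
  expect_error(run_mca(tr, n_dims = 1, var_weights = c(b = -1)), "positive")
})
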
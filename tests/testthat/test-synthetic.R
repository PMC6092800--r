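test_that("the generator is seed-deterministic and structurally valid", {
  cfg <- synthetic_config(n_receptors = 80, n_genome_genes = 500,
                          n_families = 20, seed = 7)
  s1 <- simulate_cobirth_data(cfg)
  s2 <- simulate_cobirth_data(cfg)
  expect_identical(s1$interactions, s2$interactions)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$births, s2$births)

  expect_silent(validate_interactions(s1$interactions))
  expect_equal(length(unique(s1$interactions$receptor_id)), 80L)
  expect_equal(length(unique(s1$interactions$family_id)), 20L)
  expect_length(s1$genome, 500L)
  # enzyme chains stay within the configured 1-4 range and resolve to the
  # planted ligand branch
  enz <- enzyme_gene_list(s1$interactions)
  syn <- s1$interactions$ligand_kind == "synthesized"
  expect_true(all(lengths(enz)[syn] %in% 1:4))
  expect_equal(resolve_ligand_branch(s1$interactions, s1$births),
               s1$truth$ligand_branch)

  expect_error(synthetic_config(n_receptors = 0), "n_receptors")
  expect_error(synthetic_config(coupling_theta = 1.2), "coupling_theta")
})

test_that("written datasets round-trip through the TSV/YAML dialects", {
  dir <- withr::local_tempdir()
  sim <- simulate_cobirth_data(synthetic_config(
    n_receptors = 40, n_genome_genes = 200, n_families = 10, seed = 3))
  paths <- write_synthetic_dataset(sim, dir)
  bs <- load_branch_system()
  expect_identical(read_gene_births(paths[["genome"]], bs), sim$genome)
  expect_identical(read_gene_births(paths[["births"]], bs), sim$births)
  expect_equal(read_interactions(paths[["interactions"]]),
               sim$interactions, ignore_attr = TRUE)
  cfg2 <- read_synthetic_config(paths[["config"]])
  expect_equal(cfg2$F_true, sim$config$F_true)
  expect_equal(cfg2$seed, sim$config$seed)
  # same config re-simulates byte-identically
  sim2 <- simulate_cobirth_data(cfg2)
  expect_identical(sim2$interactions, sim$interactions)
})

test_that("full synchrony forces every pair into LS", {
  sim <- simulate_cobirth_data(synthetic_config(
    n_receptors = 100, n_genome_genes = 10, n_families = 10,
    coupling_theta = 1, seed = 5))
  pairs <- classify_pairs(reduce_to_first_ligand(sim$interactions,
                                                 sim$births))
  expect_true(all(pairs$category == "LS"))
})

test_that("at theta = 0 category counts match the independence expectation", {
  F_true <- random_simplex(10)
  sim <- simulate_cobirth_data(synthetic_config(
    n_receptors = 5000, n_genome_genes = 10, n_families = 100,
    coupling_theta = 0, ligand_lambda = 0, frac_synthesized = 0,
    F_true = F_true, seed = 13))
  pairs <- classify_pairs(reduce_to_first_ligand(sim$interactions,
                                                 sim$births))
  tab <- tabulate_pairs(pairs)
  e <- expected_counts(receptor_branch_counts(pairs), F_true)$expected
  for (k in c("LB", "LS", "LA")) {
    se <- sqrt(e[[k]] * (1 - e[[k]] / 5000))
    expect_lt(abs(tab$counts[[k]] - e[[k]]), 3 * se)
  }
})

test_that("first-ligand reduction cannot exceed the per-ligand synchrony count", {
  sim <- simulate_cobirth_data(synthetic_config(
    n_receptors = 300, n_genome_genes = 10, n_families = 30,
    coupling_theta = 0.4, ligand_lambda = 2, seed = 23))
  pairs <- classify_pairs(reduce_to_first_ligand(sim$interactions,
                                                 sim$births))
  rb_all <- sim$births[sim$interactions$receptor_id]
  per_ligand_sync <- tapply(sim$truth$ligand_branch == rb_all,
                            sim$interactions$receptor_id, any)
  expect_lte(sum(pairs$category == "LS"), sum(per_ligand_sync))
})

test_that("genome frequencies converge to F_true at the study genome size", {
  F_true <- random_simplex(10)
  sim <- simulate_cobirth_data(synthetic_config(
    n_receptors = 1, n_families = 1, F_true = F_true, seed = 29))
  expect_length(sim$genome, 19928L)
  f <- estimate_frequencies(sim$genome)
  expect_lt(max(abs(f$F - F_true)), 0.01)
})

test_that("coupling recovery inverts the moment equation and clips", {
  expect_equal(recover_coupling(100, 40, 100), 1)
  expect_equal(recover_coupling(40, 40, 100), 0)
  expect_equal(recover_coupling(10, 40, 100), 0)   # clipped at zero
  expect_equal(recover_coupling(70, 40, 100), 0.5)
  expect_error(recover_coupling(10, 100, 100), "saturated")
})
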
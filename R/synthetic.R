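#' Configuration for the synthetic receptor-ligand generator
#'
#' Defaults emulate the scale of the human membrane-receptor study: a genome
#' of 19,928 dated genes, 553 receptors in 113 families, a mean of ~2.7
#' ligands per receptor (so that over 75% of receptors have several
#' ligands), 18% of receptors binding only synthesized (enzyme-chain)
#' ligands with 1-4 enzymes per chain, and a receptor-ligand birth-coupling
#' of theta = 0.27, the method-of-moments value implied by the observed
#' synchrony excess in the human data. `F_true` defaults to the uniform
#' distribution over the branch system so the generator needs no external
#' genome table.
#'
#' @param n_genome_genes genes in the simulated genome-wide birth table.
#' @param F_true numeric vector of true branch-birth probabilities
#'   (normalised); its length sets K.
#' @param n_receptors number of receptors.
#' @param coupling_theta probability in \[0, 1\] that a ligand is born in the
#'   same branch as its receptor rather than independently from `F_true`.
#' @param ligand_lambda mean number of ligands per receptor beyond the
#'   first; each receptor gets `1 + rpois(ligand_lambda)` ligands.
#' @param frac_synthesized fraction of receptors whose ligands are
#'   enzyme-chain molecules.
#' @param enzymes_per_ligand integer range (length 2) of enzymes per chain.
#' @param n_families number of receptor families (receptors are partitioned
#'   so every family is non-empty).
#' @param near_branch_decay geometric decay rho in (0, 1\] applied to the
#'   independent ligand draw: the off-synchrony draw is proportional to
#'   `F_true[b'] * rho^|b' - b|` around the receptor branch b. `rho = 1`
#'   (default) recovers the pure independent draw; smaller values plant the
#'   neighbouring-branch affinity seen in real distance spectra.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_genome_genes = 19928L,
                             F_true = NULL,
                             n_receptors = 553L,
                             coupling_theta = 0.27,
                             ligand_lambda = 1.7,
                             frac_synthesized = 0.18,
                             enzymes_per_ligand = c(1L, 4L),
                             n_families = 113L,
                             near_branch_decay = 1,
                             seed = 1L) {
  if (is.null(F_true)) F_true <- rep(1 / 10, 10)
  F_true <- as.numeric(F_true)
  if (any(F_true < 0) || sum(F_true) <= 0)
    stop("'F_true' must be non-negative with a positive sum", call. = FALSE)
  F_true <- F_true / sum(F_true)
  if (n_receptors < 1L) stop("'n_receptors' must be >= 1", call. = FALSE)
  if (coupling_theta < 0 || coupling_theta > 1)
    stop("'coupling_theta' must lie in [0, 1]", call. = FALSE)
  if (frac_synthesized < 0 || frac_synthesized > 1)
    stop("'frac_synthesized' must lie in [0, 1]", call. = FALSE)
  if (ligand_lambda < 0) stop("'ligand_lambda' must be >= 0", call. = FALSE)
  enzymes_per_ligand <- as.integer(enzymes_per_ligand)
  if (length(enzymes_per_ligand) != 2L || any(enzymes_per_ligand < 1L) ||
      diff(enzymes_per_ligand) < 0L)
    stop("'enzymes_per_ligand' must be an increasing integer range",
         call. = FALSE)
  if (n_families < 1L || n_families > n_receptors)
    stop("'n_families' must lie in 1..n_receptors", call. = FALSE)
  if (near_branch_decay <= 0 || near_branch_decay > 1)
    stop("'near_branch_decay' must lie in (0, 1]", call. = FALSE)
  structure(list(n_genome_genes = as.integer(n_genome_genes),
                 F_true = F_true, K = length(F_true),
                 n_receptors = as.integer(n_receptors),
                 coupling_theta = coupling_theta,
                 ligand_lambda = ligand_lambda,
                 frac_synthesized = frac_synthesized,
                 enzymes_per_ligand = enzymes_per_ligand,
                 n_families = as.integer(n_families),
                 near_branch_decay = near_branch_decay,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a synthetic-generator configuration from YAML
#'
#' @param path YAML file whose top-level keys are [synthetic_config()]
#'   arguments.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  args <- yaml::read_yaml(path)
  do.call(synthetic_config,
          args[intersect(names(args), names(formals(synthetic_config)))])
}

# draw one ligand branch given its receptor branch under the coupling model
.draw_ligand_branch <- function(rb, cfg) {
  n <- length(rb)
  sync <- stats::runif(n) < cfg$coupling_theta
  out <- rb
  if (any(!sync)) {
    idx <- which(!sync)
    if (cfg$near_branch_decay < 1) {
      out[idx] <- vapply(rb[idx], function(b) {
        w <- cfg$F_true * cfg$near_branch_decay^abs(seq_len(cfg$K) - b)
        sample.int(cfg$K, 1L, prob = w)
      }, integer(1))
    } else {
      out[idx] <- sample.int(cfg$K, length(idx), replace = TRUE,
                             prob = cfg$F_true)
    }
  }
  list(branch = out, sync_draw = sync)
}

#' Simulate a full synthetic dataset
#'
#' Generates a genome-wide birth table, a receptor-ligand interaction table
#' and the matching birth table for all receptors, gene-product ligands and
#' enzyme genes, with known ground truth. Receptor branches are drawn from
#' `F_true`; each ligand's branch equals its receptor's with probability
#' `coupling_theta` and is otherwise drawn independently from `F_true`
#' (optionally tilted toward neighbouring branches, see
#' [synthetic_config()]). For enzyme-chain ligands the enzyme genes are
#' drawn so that the most recent enzyme falls in the ligand's branch (each
#' enzyme from `F_true` truncated at the ligand branch, with one enzyme
#' pinned there), so the chain resolves to the planted ligand branch.
#'
#' With one ligand per receptor the probability a pair is synchronous given
#' a receptor in branch b is `theta + (1 - theta) * F_b`.
#'
#' @param config a [synthetic_config()].
#' @return List with `genome` (named integer vector gene -> branch),
#'   `interactions` (data.frame in the [read_interactions()] layout),
#'   `births` (named integer vector for receptors/ligands/enzymes),
#'   `truth` (list: `theta`, per-interaction `sync_draw` and
#'   `ligand_branch`), and `config`.
#' @export
simulate_cobirth_data <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  K <- cfg$K
  genome <- stats::setNames(
    sample.int(K, cfg$n_genome_genes, replace = TRUE, prob = cfg$F_true),
    sprintf("G%05d", seq_len(cfg$n_genome_genes)))
  rid <- sprintf("R%04d", seq_len(cfg$n_receptors))
  rb <- sample.int(K, cfg$n_receptors, replace = TRUE, prob = cfg$F_true)
  # every family non-empty: first one receptor per family, rest at random
  fam <- integer(cfg$n_receptors)
  fam[seq_len(cfg$n_families)] <- seq_len(cfg$n_families)
  if (cfg$n_receptors > cfg$n_families)
    fam[-seq_len(cfg$n_families)] <-
      sample.int(cfg$n_families, cfg$n_receptors - cfg$n_families,
                 replace = TRUE)
  synth_receptor <- stats::runif(cfg$n_receptors) < cfg$frac_synthesized
  n_lig <- 1L + stats::rpois(cfg$n_receptors, cfg$ligand_lambda)
  rec_idx <- rep.int(seq_len(cfg$n_receptors), n_lig)
  draw <- .draw_ligand_branch(rb[rec_idx], cfg)
  lig_branch <- draw$branch
  n_int <- length(rec_idx)
  lig_id <- sprintf("L%05d", seq_len(n_int))
  kind <- ifelse(synth_receptor[rec_idx], "synthesized", "gene_product")
  enz_col <- character(n_int)
  births <- c(stats::setNames(rb, rid))
  enz_counter <- 0L
  for (i in which(kind == "synthesized")) {
    rng <- seq.int(cfg$enzymes_per_ligand[1L], cfg$enzymes_per_ligand[2L])
    m <- if (length(rng) == 1L) rng else sample(rng, 1L)
    L <- lig_branch[i]
    w <- cfg$F_true[seq_len(L)]
    eb <- if (L == 1L) rep(1L, m) else
      sample.int(L, m, replace = TRUE, prob = w)
    eb[sample.int(m, 1L)] <- L   # pin the most recent enzyme to the target
    ids <- sprintf("E%05d", enz_counter + seq_len(m))
    enz_counter <- enz_counter + m
    enz_col[i] <- paste(ids, collapse = ";")
    births <- c(births, stats::setNames(eb, ids))
  }
  gp <- kind == "gene_product"
  births <- c(births, stats::setNames(lig_branch[gp], lig_id[gp]))
  interactions <- data.frame(
    receptor_id = rid[rec_idx],
    ligand_id = lig_id,
    family_id = sprintf("F%03d", fam[rec_idx]),
    evidence = "experimental",
    ligand_kind = kind,
    enzyme_gene_ids = enz_col,
    stringsAsFactors = FALSE
  )
  list(genome = genome, interactions = interactions, births = births,
       truth = list(theta = cfg$coupling_theta, sync_draw = draw$sync_draw,
                    ligand_branch = lig_branch),
       config = cfg)
}

#' Write a simulated dataset to TSV files
#'
#' @param sim result of [simulate_cobirth_data()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written (`genome`,
#'   `interactions`, `births`, `config`), invisibly.
#' @export
write_synthetic_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome_births.tsv"),
             interactions = file.path(dir, "interactions.tsv"),
             births = file.path(dir, "gene_births.tsv"),
             config = file.path(dir, "config.yaml"))
  write_gene_births(sim$genome, paths[["genome"]])
  write_interactions(sim$interactions, paths[["interactions"]])
  write_gene_births(sim$births, paths[["births"]])
  yaml::write_yaml(unclass(sim$config), paths[["config"]])
  invisible(paths)
}

#' Method-of-moments recovery of the birth-coupling parameter
#'
#' Under the coupling model the expected number of synchronous pairs is
#' `theta * n + (1 - theta) * e_LS`, where `e_LS` is the synchrony
#' expectation under independence; inverting gives
#' `theta_hat = (observed_LS - e_LS) / (n - e_LS)`, clipped to \[0, 1\].
#'
#' @param observed_LS observed synchronous-pair count.
#' @param e_LS expected synchronous count under independence (from
#'   [expected_counts()]).
#' @param n total number of pairs; must exceed `e_LS`.
#' @return The point estimate `theta_hat` in \[0, 1\].
#' @export
recover_coupling <- function(observed_LS, e_LS, n) {
  if (n <= e_LS)
    stop("model saturated: n must exceed the independence expectation e_LS",
         call. = FALSE)
  min(1, max(0, (observed_LS - e_LS) / (n - e_LS)))
}
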
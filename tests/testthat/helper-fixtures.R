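# Shared fixtures and independent oracles, built in code.

# A 6-branch toy system with simple ages.
toy_system <- function() {
  branch_system(c(600, 500, 400, 300, 200, 100))
}

# A small interaction set in the style of the schematic reduction example:
# 22 interactions over 10 receptors in 3 families, including a two-ligand
# tie at the most ancestral branch (R01), a family tie resolved by the
# first ligand (R02 vs R03), and two enzyme-chain ligands (one
# single-branch, one mixed).
toy_interactions <- function() {
  rec <- function(r, l, f, kind = "gene_product", enz = "")
    data.frame(receptor_id = r, ligand_id = l, family_id = f,
               evidence = "experimental", ligand_kind = kind,
               enzyme_gene_ids = enz, stringsAsFactors = FALSE)
  rbind(
    rec("R01", "La", "fam1"), rec("R01", "Lb", "fam1"),
    rec("R01", "Lc", "fam1"), rec("R01", "Lr", "fam1"),
    rec("R01", "Ls", "fam1"),
    rec("R04", "Ld", "fam1"),
    rec("R05", "Le", "fam1"), rec("R05", "Lf", "fam1"),
    rec("R02", "Lg", "fam2"),
    rec("R03", "Lh", "fam2"), rec("R03", "Li", "fam2"),
    rec("R06", "Lj", "fam2"),
    rec("R07", "Lk", "fam3"), rec("R07", "Ll", "fam3"),
    rec("R07", "Lm", "fam3"), rec("R07", "Lt", "fam3"),
    rec("R08", "Ln", "fam3", "synthesized", "e1;e2"),
    rec("R09", "Lo", "fam3", "synthesized", "e3;e4"),
    rec("R10", "Lp", "fam3"), rec("R10", "Lq", "fam3"),
    rec("R10", "Lu", "fam3"), rec("R10", "Lv", "fam3")
  )
}

toy_births <- function() {
  c(R01 = 1L, R02 = 1L, R03 = 1L, R04 = 2L, R05 = 3L, R06 = 2L,
    R07 = 2L, R08 = 3L, R09 = 4L, R10 = 5L,
    La = 1L, Lb = 1L, Lc = 3L, Lr = 4L, Ls = 5L,
    Ld = 2L, Le = 1L, Lf = 2L,
    Lg = 3L, Lh = 1L, Li = 2L, Lj = 2L,
    Lk = 2L, Ll = 4L, Lm = 5L, Lt = 6L,
    Lp = 1L, Lq = 2L, Lu = 3L, Lv = 6L,
    e1 = 2L, e2 = 1L,    # mixed chain -> resolves to branch 2
    e3 = 4L, e4 = 4L)    # single-branch chain -> branch 4
}

# Brute-force oracle for the analytic null: enumerate all K^2
# (receptor-branch, ligand-branch) cells.
oracle_expected <- function(R, F) {
  K <- length(F)
  e <- c(LB = 0, LS = 0, LA = 0)
  for (b1 in seq_len(K)) for (b2 in seq_len(K)) {
    w <- R[b1] * F[b2]
    if (b2 < b1) e[["LB"]] <- e[["LB"]] + w
    else if (b2 == b1) e[["LS"]] <- e[["LS"]] + w
    else e[["LA"]] <- e[["LA"]] + w
  }
  e
}

random_simplex <- function(K) {
  x <- stats::rexp(K)
  x / sum(x)
}
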
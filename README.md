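# cobirth

Did receptors and their ligands appear together in evolution, or did one
partner routinely wait for the other? `cobirth` answers this for lists of
receptor–ligand interactions whose genes have been dated on an ordered
system of phylogenetic branches (phylostratigraphy: a gene's *branch of
appearance* is the most ancestral branch containing all taxa where the gene
is present and functional today). It is written for molecular evolution
groups working with human membrane receptors and endogenous ligands, but
nothing ties it to that system: any birth-annotated interaction list on any
ordered branch system fits.

## The analysis

Starting from an interaction table (receptor, ligand, family, evidence,
and — for ligands synthesized by an enzyme chain — the enzyme genes), the
package:

1. **dates each ligand**, using the most recent enzyme of the chain for
   synthesized ligands such as dopamine;
2. **reduces to non-redundant pairs**: one row per receptor, keeping its
   *first* (most ancestral) ligand, and optionally one earliest-born
   receptor per family to guard against duplication-driven
   pseudo-replication;
3. **classifies** every pair as LB (ligand before), LS (synchronous) or LA
   (ligand after) with the signed branch distance
   `d = b_ligand − b_receptor`;
4. **tests against independence**. With `R_b` receptors observed in branch
   `b` and `F_b` the genome-wide fraction of genes born in branch `b`
   (estimated from gene-tree roots, optionally weighted by branch
   duration), the expected counts under independent birth are

   ```
   E[LS] = Σ_b R_b F_b
   E[LB] = Σ_b R_b Σ_{b' < b} F_{b'}
   E[LA] = Σ_b R_b Σ_{b' > b} F_{b'}
   ```

   compared with the observed counts by Pearson's chi-squared (2 df), with
   pairwise 1-df equal-proportion tests between categories, a seeded
   permutation null (random ligand draws from `F`) with add-one empirical
   p-values, and the Pearson correlation of receptor and ligand branches
   over non-synchronous pairs;
5. **estimates the birth coupling** `θ` — the probability that a ligand is
   born in the same branch as its receptor rather than independently — by
   method of moments: `θ̂ = (O_LS − E[LS]) / (n − E[LS])`;
6. **characterises the pairs** by multiple correspondence analysis of
   categorical traits (appearance category, ligand weight class at
   550 Da / 25 kDa cut-points, molecule group, signal type, function,
   family).

A synthetic-data generator (`simulate_cobirth_data()`) emulates all the
inputs at the scale of the human study — a 19,928-gene genome, 553
receptors in 113 families, 1–4 enzymes per chain — with a planted coupling
`θ`, so the whole pipeline is testable end to end without any downloads.

## Worked example

```r
library(cobirth)

sim <- simulate_cobirth_data(synthetic_config(seed = 11))  # planted theta = 0.27
fit <- cobirth_pipeline(sim$interactions, sim$births, sim$genome)
summary(fit)
```

```
Receptor-ligand co-birth fit

  553 pairs over 10 branches (F: none weighting)
            LB    LS    LA
observed 298.0 167.0  88.0
expected 258.1  55.3 239.6

  chi-squared = 327.4, df = 2, p = 7.99e-72
  coupling theta (method of moments) = 0.224

  Observed shares (%): LB 53.89, LS 30.20, LA 15.91
  Pairwise equal-proportion tests (1 df):
    LS_vs_LA chi2 =  24.47, p = 7.53e-07
    LB_vs_LS chi2 =  36.91, p = 1.24e-09
    LB_vs_LA chi2 = 114.25, p = 1.15e-26
  Branch correlation (non-synchronous pairs): r = -0.012, p = 0.822, n = 386
```

The observed LS count (167) is three times its independence expectation
(55.3): the planted synchrony is detected, and the moment estimator reads
it back as `θ̂ = 0.224` (the first-ligand reduction over multiple ligands
per receptor pulls `θ̂` slightly below the planted per-ligand 0.27; with
one ligand per receptor it is unbiased). The permutation route agrees:

```r
nul <- simulate(fit, nsim = 10000, seed = 12)
empirical_pvalue(fit$tab$counts[["LS"]], nul, "LS", "greater")
#> 9.999e-05      # = 1/(reps + 1): no replicate reached the observed count
```

A thin command-line wrapper with `classify`, `nullmodel`, `permute`,
`correlate`, `mca` and `simulate` subcommands lives at
`system.file("scripts", "cobirth-cli.R", package = "cobirth")`.

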
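---
title: "Co-birth of receptors and ligands: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-birth of receptors and ligands: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cobirth)
```

This vignette is the package's account of its science: what is being
modelled, which choices were open and how they were decided, and what the
synthetic tests do and do not establish about real data.

## The question and the data model

For a set of receptors with known endogenous ligands, we ask whether the
genes encoding the two partners tended to be born together. Births are
expressed on a `branch_system`: an ordered set of K dated branches of the
species tree, index 1 the most ancestral. The default is a 10-branch animal
tree (Opisthokonta 1500 my ... Mammalia 184 my) in which the earliest
metazoan lineages (Placozoa, Porifera, Ctenophora, Cnidaria) are merged
into the single Metazoa branch; their branching order is unresolved, and a
single merged branch introduces less bias than committing to any one
resolution. Alternative branchings are supported through TSV/YAML
configuration, but none is endorsed.

Three inputs drive the analysis: a birth table for the receptor/ligand/
enzyme genes, the interaction list, and a genome-wide birth table from
which the null frequencies are estimated.

Two reductions precede all statistics:

* **first ligand.** Only a receptor's most ancestral ligand says whether a
  partner existed when the receptor appeared; later ligands concern
  co-evolution, not co-birth. Ties between ligands born in the same branch
  are broken lexicographically — the choice is immaterial (only the shared
  branch enters the analysis) but lexicographic order makes runs
  reproducible where an arbitrary choice would not be.
* **one per family (optional).** Families arise largely by duplication, so
  family members are not independent observations; keeping only the
  earliest receptor per family (ties resolved by the more ancestral first
  ligand, then lexicographically) gives a smaller but
  duplication-insensitive list.

Ligands that are synthesized molecules rather than gene products (dopamine,
acetylcholine, ...) are dated by the *most recent* gene of their enzyme
chain: the molecule cannot exist until the full chain does. Chains whose
enzymes span several branches can be excluded as a sensitivity analysis
(`exclude_mixed_enzyme_ligands`), since alternative or reorganised
biosynthetic routes make such datings less certain.

## The null model

Under independence, a receptor observed in branch `b` would acquire a first
ligand born in branch `b'` with the genome-wide probability `F_b'`. With
`R_b` receptors per branch:

$$E_{LS} = \sum_b R_b F_b,\qquad
  E_{LB} = \sum_b R_b \sum_{b'<b} F_{b'},\qquad
  E_{LA} = \sum_b R_b \sum_{b'>b} F_{b'}.$$

These conserve the total, $E_{LB}+E_{LS}+E_{LA}=n$ — the property that
pins the formula down. A historical variant that indexes the receptor count
by the inner (ligand) branch inside the double sums double-counts receptors
and breaks conservation; it is kept behind
`expected_counts(..., literal = TRUE)` purely for comparison, and a unit
test documents its non-conservation.

**Duration weighting.** The branches span very different time intervals
(10 my between Chordata and Vertebrata, 110 my between Vertebrata and
Teleostei). `estimate_frequencies()` therefore offers `multiply_duration`
and `divide_duration` modes alongside the default `none`. The default is
unweighted for two reasons: the weighted and unweighted analyses lead to
the same qualitative conclusion on data of this shape, and the *direction*
a duration correction should take is genuinely ambiguous (is a long branch
more likely to host a birth, or does each recorded birth there represent a
lower per-my rate?). Both modes are implemented; neither is endorsed.

Observed versus expected counts are compared with Pearson's chi-squared on
the three categories (2 df); pairwise category comparisons use a 1-df
equal-proportion chi-squared without continuity correction. That exact
form was validated by reproducing, from the published human contingency
(116/225/212), all three published pairwise p-values (0.534, 3.6e-09,
1.2e-07) — see `tests/testthat/test-acceptance.R`, which recomputes them.

**Percentages.** Category shares are printed to 2 dp using
largest-remainder apportionment, so the three shares always sum to exactly
100.00. This is deliberate rather than plain half-up rounding: independent
per-category rounding can print a triple that disagrees with its own total
(for 116/225/212 it yields 20.98/40.69/38.34, which sums to 100.01), while
the apportioned triple 20.98/40.69/38.33 is self-consistent.

## Permutation null and empirical p-values

`draw_null()` keeps every receptor's branch fixed — the receptor
configuration is conditioning information — and draws ligand branches
i.i.d. from `F`, 10,000 replicates by default, fully determined by its
`seed`. Empirical p-values use the add-one rule
`p = (1 + #extreme)/(reps + 1)`, the standard finite-sample correction that
avoids reporting zero. The null distance spectrum peaks at 0 for purely
combinatorial reasons: a gap of 0 can be produced from all K branches, a
gap of ±d only from K − d of them.

**A caveat on the branch correlation.** `branch_correlation()` by default
drops LS pairs and asks whether the remaining pairs still sit in
neighbouring branches. Note that excluding the diagonal biases the
independent-draw correlation *negative* — exactly −1/(K−1) for uniform
draws — so a null run is expected to show a small negative r, and an
observed clearly positive r is evidence of near-branch affinity over and
above that bias. The property test checks the analytic −1/(K−1), not
"r ≈ 0". The `exclude_synchronous` flag exposes both conventions, since
either could reasonably be reported.

## The coupling parameter and its estimator

The generative model behind the synthetic data and the estimator is a
two-component mixture: a ligand is born in its receptor's branch with
probability θ, and otherwise independently from `F`. Then
`E[O_LS] = θ n + (1 − θ) E_LS`, inverted by
`recover_coupling()` as `θ̂ = (O_LS − E_LS)/(n − E_LS)`, clipped to [0, 1].
With one ligand per receptor, `P(LS | receptor in b) = θ + (1 − θ) F_b`
exactly; with several ligands per receptor the first-ligand reduction
shifts mass toward LB and `θ̂` reads slightly below the per-ligand θ, which
is visible in the worked example in the README.

## Multiple correspondence analysis

`run_mca()` is canonical indicator-matrix MCA: the complete disjunctive
matrix is analysed by SVD of the standardized residuals
$D_r^{-1/2}(P - rc^\top)D_c^{-1/2}$; eigenvalues are squared singular
values and total inertia equals J/Q − 1. No Benzécri/Greenacre inertia
correction is applied — the analysis is used for qualitative groupings
(which trait levels co-locate with which appearance category), not for
variance accounting, and the uncorrected variant is the simplest canonical
one. No installed package provides indicator MCA with these exact outputs,
so the decomposition is done directly on base `svd()`; the test suite
cross-checks the eigenvalues against the canonical-correlation
decomposition of `MASS::corresp()` on two-variable tables, where the
relationship $\lambda = (1 \pm \rho_i)/2$ is exact. Ligand weight classes
use the 550 Da and 25,000 Da cut-points (small/medium/big). The
many-levelled family variable is included by default but can be
down-weighted (`var_weights`) or dropped (`include_family = FALSE`) to
keep it from dominating the inertia.

## The synthetic generator

`simulate_cobirth_data()` emulates the study conditions: its defaults are a
19,928-gene genome, 553 receptors in 113 families, `1 + Poisson(1.7)`
ligands per receptor (mean ≈ 2.7, so over 75% of receptors have several
ligands), 18% of receptors holding enzyme-chain ligands with 1–4 enzymes,
and θ = 0.27 — the value the moment estimator returns for the published
human contingency. `F_true` defaults to uniform so the generator has no
external dependency; supply an estimated frequency vector to mimic a real
genome. Enzyme chains are drawn conditionally (each enzyme at or before
the ligand's branch, one pinned at it) so that the chain resolves to the
planted ligand branch and the coupling survives enzyme dating. An optional
geometric kernel (`near_branch_decay` < 1) tilts the off-synchrony draw
toward branches near the receptor's, planting the neighbouring-branch
affinity that shows up in real distance spectra.

What the generator does *not* emulate: gene loss and re-annotation error
(births are exact), family-correlated birth branches (family labels
partition receptors but do not influence branches), duplication history,
and trait–category dependence beyond what a test plants explicitly.
Passing tests therefore demonstrate that the machinery is correct under
the stated model, not that real datings are unbiased.

## Problem sizes and numerical choices

The test suite runs the permutation check at 10,000 replicates on a
553-pair configuration, parameter recovery at 200 replicates for each
θ ∈ {0, 0.25, 0.5, 0.75, 1} (mean absolute error < 0.03), and the
analytic-vs-brute-force equivalence over random instances with K ≤ 10 —
sizes chosen to give comfortable Monte-Carlo margins while keeping a full
run around a minute. Frequencies must sum to 1 within 1e−12 after
normalisation; expectation conservation is asserted within 1e−9;
chi-squared tests with an expected category of zero abort with advice to
pool categories rather than returning an infinite statistic. Degenerate
configurations (empty interaction lists, single-level MCA variables,
zero-variance correlations, saturated `n ≤ E_LS` coupling recovery) raise
informative errors rather than propagating NaN.

## Known limitations

* Branch systems are ordinal; the statistics ignore *how much* time
  separates branches except through the optional frequency weighting.
* The coupling model puts excess mass only on exact synchrony; real
  near-branch affinity is generated (and detected) but not estimated as a
  second parameter.
* The moment estimator of θ has no standard error attached; use the
  permutation null for uncertainty statements.
* MCA outputs are descriptive; no inference is performed on the axes.
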
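#' Fit the receptor-ligand co-birth model
#'
#' The central analysis of the package. Given classified receptor /
#' first-ligand pairs and genome-wide branch-birth frequencies, it
#' tabulates the observed LB/LS/LA distribution, computes the analytic
#' expectation under independent gene birth (each receptor keeping its
#' branch, its ligand branch drawn from the genome-wide frequencies F),
#' tests the discrepancy with Pearson's chi-squared (2 df), runs the three
#' pairwise equal-proportion tests, estimates the synchrony coupling
#' `theta` by method of moments ([recover_coupling()]) and the
#' receptor-ligand branch correlation over non-synchronous pairs
#' ([branch_correlation()]).
#'
#' @param pairs classified-pair data.frame from [classify_pairs()] (or
#'   [read_classified_pairs()]).
#' @param genome_births named integer vector of genome-wide gene births (or
#'   per-branch counts), used to estimate F; ignored when `frequencies` is
#'   given.
#' @param frequencies a ready-made [branch_frequencies()] object.
#' @param system the active [branch_system()].
#' @param weight_mode duration weighting passed to [estimate_frequencies()].
#' @param exclude_synchronous drop LS pairs from the branch correlation
#'   (default `TRUE`).
#' @return An object of class `cobirth`: list with `pairs`, `tab`
#'   (`category_counts`), `R` (per-branch receptor counts), `freq`,
#'   `expected`, `gof`, `pairwise` (LS_vs_LA, LB_vs_LS, LB_vs_LA),
#'   `theta_hat`, `correlation` (or `NULL` when undefined), `system`,
#'   `call`.
#' @examples
#' sim <- simulate_cobirth_data(synthetic_config(n_receptors = 200,
#'                                               n_genome_genes = 5000,
#'                                               n_families = 40, seed = 7))
#' pairs <- classify_pairs(reduce_to_first_ligand(sim$interactions,
#'                                                sim$births))
#' fit <- cobirth(pairs, genome_births = sim$genome)
#' print(fit)
#' coef(fit)
#' @export
cobirth <- function(pairs, genome_births = NULL, frequencies = NULL,
                    system = load_branch_system(),
                    weight_mode = c("none", "multiply_duration",
                                    "divide_duration"),
                    exclude_synchronous = TRUE) {
  weight_mode <- match.arg(weight_mode)
  if (nrow(pairs) == 0L) stop("no pairs to fit", call. = FALSE)
  if (is.null(pairs$category) || is.null(pairs$distance))
    pairs <- classify_pairs(pairs, system)
  freq <- if (!is.null(frequencies)) {
    stopifnot(inherits(frequencies, "branch_frequencies"))
    frequencies
  } else if (!is.null(genome_births)) {
    estimate_frequencies(genome_births, system, weight_mode)
  } else {
    stop("supply 'genome_births' or 'frequencies' for the null model",
         call. = FALSE)
  }
  if (freq$K != system$K)
    stop("branch systems disagree: frequencies have K = ", freq$K,
         " but the system has K = ", system$K, call. = FALSE)
  tab <- tabulate_pairs(pairs, system)
  R <- receptor_branch_counts(pairs, system)
  expected <- expected_counts(R, freq)
  gof <- gof_test(tab, expected)
  cnt <- tab$counts
  pairwise <- list(LS_vs_LA = equal_proportion_test(cnt[["LS"]], cnt[["LA"]]),
                   LB_vs_LS = equal_proportion_test(cnt[["LB"]], cnt[["LS"]]),
                   LB_vs_LA = equal_proportion_test(cnt[["LB"]], cnt[["LA"]]))
  theta_hat <- if (tab$n > expected$expected[["LS"]])
    recover_coupling(cnt[["LS"]], expected$expected[["LS"]], tab$n)
  else NA_real_
  correlation <- tryCatch(
    branch_correlation(pairs, exclude_synchronous = exclude_synchronous),
    error = function(e) NULL)
  structure(list(pairs = pairs, tab = tab, R = R, freq = freq,
                 expected = expected, gof = gof, pairwise = pairwise,
                 theta_hat = theta_hat, correlation = correlation,
                 exclude_synchronous = exclude_synchronous,
                 system = system, call = match.call()),
            class = "cobirth")
}

#' Run the full pipeline from raw tables to a fitted model
#'
#' Convenience wrapper covering the analysis configurations used in the
#' human study: optional restriction to experimentally supported
#' interactions, optional removal of enzyme-chain ligands whose enzymes
#' span several branches, first-ligand reduction, optional one-per-family
#' reduction, classification, and the [cobirth()] fit.
#'
#' @param interactions interaction data.frame (see [read_interactions()]).
#' @param births named integer vector of births for receptors, ligands and
#'   enzymes.
#' @param genome_births genome-wide births (or per-branch counts) for the
#'   null frequencies.
#' @param system the active [branch_system()].
#' @param evidence `"all"` keeps predicted interactions, `"experimental"`
#'   drops them.
#' @param family_reduce apply [reduce_one_per_family()] after the
#'   first-ligand reduction.
#' @param exclude_mixed_enzyme_ligands drop interactions whose enzyme chain
#'   spans several branches before reducing.
#' @param weight_mode duration weighting for the null frequencies.
#' @return A fitted `cobirth` object.
#' @export
cobirth_pipeline <- function(interactions, births, genome_births,
                             system = load_branch_system(),
                             evidence = c("all", "experimental"),
                             family_reduce = FALSE,
                             exclude_mixed_enzyme_ligands = FALSE,
                             weight_mode = "none") {
  evidence <- match.arg(evidence)
  validate_interactions(interactions)
  if (evidence == "experimental")
    interactions <- interactions[interactions$evidence == "experimental", ,
                                 drop = FALSE]
  if (exclude_mixed_enzyme_ligands)
    interactions <- interactions[!mixed_enzyme_ligand(interactions, births), ,
                                 drop = FALSE]
  pairs <- reduce_to_first_ligand(interactions, births)
  if (family_reduce) pairs <- reduce_one_per_family(pairs)
  pairs <- classify_pairs(pairs, system)
  cobirth(pairs, genome_births = genome_births, system = system,
          weight_mode = weight_mode)
}

#' @export
print.cobirth <- function(x, digits = 3L, ...) {
  cat("Receptor-ligand co-birth fit\n\n")
  cat(sprintf("  %d pairs over %d branches (F: %s weighting)\n", x$tab$n,
              x$system$K, x$freq$weight_mode))
  m <- rbind(observed = x$tab$counts, expected = round(x$expected$expected, 1))
  print(m)
  cat(sprintf("\n  chi-squared = %.1f, df = %d, p = %.3g\n",
              x$gof$statistic, x$gof$df, x$gof$p.value))
  cat(sprintf("  coupling theta (method of moments) = %.*f\n", digits,
              x$theta_hat))
  invisible(x)
}

#' @export
coef.cobirth <- function(object, ...) {
  c(coupling_theta = object$theta_hat)
}

#' @export
residuals.cobirth <- function(object, ...) {
  (object$tab$counts - object$expected$expected) /
    sqrt(object$expected$expected)
}

#' Expected counts for new receptor configurations
#'
#' @param object a fitted `cobirth`.
#' @param R per-branch receptor counts (defaults to the fitted counts).
#' @param ... unused.
#' @return A `null_expectation` under the fitted frequencies.
#' @export
predict.cobirth <- function(object, R = object$R, ...) {
  expected_counts(R, object$freq)
}

#' Draw the permutation null from a fitted model
#'
#' @param object a fitted `cobirth`.
#' @param nsim replicates (default 10,000).
#' @param seed integer seed for the draws.
#' @param ... passed to [draw_null()] (e.g. `keep_distances`).
#' @return A `permutation_null`; see [draw_null()] and
#'   [empirical_pvalue()].
#' @export
simulate.cobirth <- function(object, nsim = 10000L, seed = 1L, ...) {
  draw_null(object$R, object$freq, reps = nsim, seed = seed, ...)
}

#' @export
summary.cobirth <- function(object, ...) {
  structure(list(fit = object,
                 shares = category_shares(object$tab),
                 ls_breakdown = ls_branch_breakdown(object$pairs,
                                                    object$system)),
            class = "summary.cobirth")
}

#' @export
print.summary.cobirth <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n  Observed shares (%):",
      paste(sprintf("%s %.2f", names(x$shares), x$shares), collapse = ", "),
      "\n")
  cat("  Pairwise equal-proportion tests (1 df):\n")
  for (k in names(f$pairwise))
    cat(sprintf("    %-8s chi2 = %6.2f, p = %.3g\n", k,
                f$pairwise[[k]]$statistic, f$pairwise[[k]]$p.value))
  if (!is.null(f$correlation))
    cat(sprintf("  Branch correlation (%s): r = %.3f, p = %.3g, n = %d\n",
                if (f$exclude_synchronous) "non-synchronous pairs"
                else "all pairs",
                f$correlation$r, f$correlation$p.value, f$correlation$n_used))
  ls2 <- x$ls_breakdown[order(-x$ls_breakdown$n), ][1:3, ]
  cat("  LS pairs concentrate in branches:",
      paste(sprintf("%s (%g%%)", ls2$label, ls2$pct), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a fitted co-birth model
#'
#' `which = 1` draws the observed vs expected category barplot; `which = 2`
#' the signed branch-distance spectrum, with the permutation-null mean
#' overlaid when a `permutation_null` drawn with `keep_distances = TRUE` is
#' supplied.
#'
#' @param x a fitted `cobirth`.
#' @param which plots to draw (subset of `1:2`).
#' @param null optional `permutation_null` for the distance overlay.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.cobirth <- function(x, which = 1L, null = NULL, ...) {
  if (1L %in% which) {
    m <- rbind(Observed = x$tab$counts, Expected = x$expected$expected)
    graphics::barplot(m, beside = TRUE, col = c("firebrick", "grey20"),
                      legend.text = rownames(m), ylab = "pairs", ...)
  }
  if (2L %in% which) {
    h <- x$tab$distance_hist
    d <- as.integer(names(h))
    graphics::plot(d, h, type = "l", col = "firebrick",
                   xlab = "ligand branch - receptor branch",
                   ylab = "pairs", ...)
    if (!is.null(null) && !is.null(null$distance_hist))
      graphics::lines(as.integer(names(null$distance_hist)),
                      null$distance_hist, col = "grey20")
  }
  invisible(x)
}
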
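#' Permutation null by random ligand draws
#'
#' Builds the empirical null distribution of category counts: per replicate,
#' every receptor keeps its observed birth branch and is paired with a ligand
#' branch drawn i.i.d. from the genome-wide frequencies F; the resulting
#' pairs are classified and counted. Receptor branches are conditioning
#' information, so only the ligand side is randomised.
#'
#' @param R integer vector of per-branch receptor counts (length K).
#' @param F a `branch_frequencies` object or numeric probability vector.
#' @param reps number of replicates (default 10,000).
#' @param seed integer seed; the draw is deterministic given the seed, which
#'   is recorded in the result.
#' @param keep_distances accumulate the null signed-distance histogram
#'   (summed over replicates) alongside the per-replicate counts.
#' @return An object of class `permutation_null`: list with `counts` (a
#'   `reps` x 3 integer matrix, columns LB/LS/LA), `reps`, `seed`, `n`
#'   (pairs per replicate) and, if requested, `distance_hist` (mean per-
#'   replicate histogram over -(K-1)..(K-1)).
#' @export
draw_null <- function(R, F, reps = 10000L, seed = 1L,
                      keep_distances = FALSE) {
  f <- if (inherits(F, "branch_frequencies")) F$F else as.numeric(F)
  R <- as.integer(R)
  if (length(R) != length(f))
    stop("length mismatch between R and F", call. = FALSE)
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop("'reps' must be >= 1", call. = FALSE)
  n <- sum(R)
  if (n < 1L) stop("no receptors to pair", call. = FALSE)
  K <- length(f)
  rb <- rep.int(seq_len(K), R)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  counts <- matrix(0L, nrow = reps, ncol = 3L,
                   dimnames = list(NULL, c("LB", "LS", "LA")))
  support <- seq.int(-(K - 1L), K - 1L)
  hist <- if (keep_distances) stats::setNames(numeric(length(support)),
                                              support) else NULL
  # draw in blocks to bound memory at ~ block * n integers
  block <- max(1L, min(reps, as.integer(ceiling(2e6 / n))))
  done <- 0L
  while (done < reps) {
    m <- min(block, reps - done)
    lig <- matrix(sample.int(K, m * n, replace = TRUE, prob = f),
                  nrow = m, ncol = n)
    d <- lig - matrix(rb, nrow = m, ncol = n, byrow = TRUE)
    counts[done + seq_len(m), "LB"] <- rowSums(d < 0L)
    counts[done + seq_len(m), "LS"] <- rowSums(d == 0L)
    counts[done + seq_len(m), "LA"] <- rowSums(d > 0L)
    if (keep_distances)
      hist <- hist + as.numeric(table(factor(d, levels = support)))
    done <- done + m
  }
  structure(list(counts = counts, reps = reps, seed = as.integer(seed),
                 n = n,
                 distance_hist = if (keep_distances) hist / reps else NULL),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf("Permutation null: %d replicates of %d pairs (seed %d)\n",
              x$reps, x$n, x$seed))
  cat("Mean per-replicate category counts:\n")
  print(round(colMeans(x$counts), 2))
  invisible(x)
}

#' Empirical p-value against a permutation null
#'
#' Uses the add-one finite-sample form
#' `p = (1 + #{replicates at least as extreme}) / (reps + 1)`, so p is never
#' exactly zero.
#'
#' @param observed_count observed count in the chosen category.
#' @param null a `permutation_null` from [draw_null()].
#' @param category one of `"LB"`, `"LS"`, `"LA"`.
#' @param side `"greater"` tests for excess (replicates >= observed),
#'   `"less"` for deficit.
#' @return The empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed_count, null,
                             category = c("LS", "LB", "LA"),
                             side = c("greater", "less")) {
  category <- match.arg(category)
  side <- match.arg(side)
  stopifnot(inherits(null, "permutation_null"))
  x <- null$counts[, category]
  extreme <- if (side == "greater") sum(x >= observed_count)
             else sum(x <= observed_count)
  (1 + extreme) / (null$reps + 1)
}

#' Correlation between receptor and ligand birth branches
#'
#' Pearson correlation of the receptor and ligand branch indices across
#' pairs. By default synchronous (LS) pairs are excluded, asking whether the
#' pairs that did not appear together still appeared in neighbouring
#' branches.
#'
#' @param pairs classified-pair data.frame.
#' @param exclude_synchronous drop LS pairs before correlating (default
#'   `TRUE`).
#' @return List with `r`, `p.value`, `n_used`.
#' @export
branch_correlation <- function(pairs, exclude_synchronous = TRUE) {
  d <- if (exclude_synchronous)
    pairs[pairs$category != "LS", , drop = FALSE] else pairs
  if (nrow(d) < 3L)
    stop("need at least 3 usable pairs for a correlation", call. = FALSE)
  if (stats::sd(d$receptor_branch) == 0 || stats::sd(d$ligand_branch) == 0)
    stop("correlation undefined: zero variance in branch indices",
         call. = FALSE)
  ht <- stats::cor.test(d$receptor_branch, d$ligand_branch,
                        method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, n_used = nrow(d))
}
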
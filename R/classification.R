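#' Classify receptor-ligand pairs by relative birth branch
#'
#' Each receptor / first-ligand pair falls into one of three categories:
#' LB (Ligand Before) when the ligand gene appeared in a more ancestral
#' branch than the receptor, LS (Ligand Synchronous) when both appeared in
#' the same branch, LA (Ligand After) when the ligand appeared later. The
#' signed branch distance is `ligand_branch - receptor_branch`, negative for
#' LB.
#'
#' @param pairs data.frame with columns `receptor_branch` and
#'   `ligand_branch` (from [reduce_to_first_ligand()]).
#' @param system the active [branch_system()]; branches validated against
#'   1..K.
#' @return `pairs` with columns `category` (character, LB/LS/LA) and
#'   `distance` (integer) appended.
#' @export
classify_pairs <- function(pairs, system = load_branch_system()) {
  rb <- .check_branches(pairs$receptor_branch, system, "receptor_branch")
  lb <- .check_branches(pairs$ligand_branch, system, "ligand_branch")
  cl <- classify_pair(rb, lb)
  pairs$category <- cl$category
  pairs$distance <- cl$distance
  pairs
}

#' @rdname classify_pairs
#' @param receptor_branch,ligand_branch integer branch indices (vectorised).
#' @return `classify_pair()` returns a list with components `category` and
#'   `distance`.
#' @export
classify_pair <- function(receptor_branch, ligand_branch) {
  d <- as.integer(ligand_branch) - as.integer(receptor_branch)
  list(category = ifelse(d < 0L, "LB", ifelse(d == 0L, "LS", "LA")),
       distance = d)
}

#' Tabulate classified pairs
#'
#' Counts pairs per category and builds the signed-distance histogram over
#' the full support -(K-1)..+(K-1).
#'
#' @param pairs classified-pair data.frame (from [classify_pairs()]); must be
#'   non-empty.
#' @param system the active [branch_system()].
#' @return An object of class `category_counts`: list with `counts` (named
#'   integer vector LB/LS/LA), `n`, and `distance_hist` (named integer
#'   vector over -(K-1)..(K-1)).
#' @export
tabulate_pairs <- function(pairs, system = load_branch_system()) {
  if (nrow(pairs) == 0L)
    stop("no classified pairs to tabulate", call. = FALSE)
  category_counts(sum(pairs$category == "LB"),
                  sum(pairs$category == "LS"),
                  sum(pairs$category == "LA"),
                  distances = pairs$distance, K = system$K)
}

#' Construct category counts directly
#'
#' @param n_LB,n_LS,n_LA non-negative integer counts.
#' @param distances optional integer vector of signed distances used to fill
#'   the histogram; when omitted only the bins -1, 0, +1 are populated from
#'   the counts.
#' @param K number of branches (histogram support).
#' @return A `category_counts` object; see [tabulate_pairs()].
#' @export
category_counts <- function(n_LB, n_LS, n_LA, distances = NULL, K = 10L) {
  cnt <- c(LB = as.integer(n_LB), LS = as.integer(n_LS), LA = as.integer(n_LA))
  if (anyNA(cnt) || any(cnt < 0L))
    stop("category counts must be non-negative integers", call. = FALSE)
  support <- seq.int(-(K - 1L), K - 1L)
  hist <- stats::setNames(integer(length(support)), support)
  if (!is.null(distances)) {
    tb <- table(factor(as.integer(distances), levels = support))
    hist[] <- as.integer(tb)
    if (sum(hist) != sum(cnt))
      stop("distance histogram does not match the category counts",
           call. = FALSE)
  } else {
    hist[as.character(c(-1L, 0L, 1L))] <- cnt[c("LB", "LS", "LA")]
  }
  structure(list(counts = cnt, n = sum(cnt), distance_hist = hist),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat(sprintf("Category counts over %d receptor-ligand pairs:\n", x$n))
  sh <- category_shares(x)
  for (k in names(x$counts))
    cat(sprintf("  %s: %4d (%.2f%%)\n", k, x$counts[[k]], sh[[k]]))
  invisible(x)
}

#' Category percentages summing to 100
#'
#' Percentages are reported to 2 decimal places using largest-remainder
#' apportionment: each share is floored at 2 dp and the residual hundredths
#' needed to reach exactly 100 are assigned to the categories with the
#' largest remainders. This keeps the three printed shares consistent with
#' one another (they always sum to 100.00).
#'
#' @param counts a `category_counts` object or a named/unnamed numeric vector
#'   of three counts (LB, LS, LA).
#' @return Named numeric vector of percentages (LB, LS, LA), 2 dp, summing
#'   to 100.
#' @examples
#' category_shares(c(116, 225, 212))   # 20.98 40.69 38.33
#' @export
category_shares <- function(counts) {
  x <- if (inherits(counts, "category_counts")) counts$counts else counts
  if (length(x) != 3L || any(x < 0) || sum(x) == 0)
    stop("'counts' must be three non-negative counts with a positive sum",
         call. = FALSE)
  pct <- as.numeric(x) / sum(x) * 100
  fl <- floor(pct * 100) / 100
  extra <- as.integer(round((100 - sum(fl)) * 100))
  if (extra > 0L) {
    bump <- order(pct - fl, decreasing = TRUE)[seq_len(extra)]
    fl[bump] <- fl[bump] + 0.01
  }
  stats::setNames(round(fl, 2), c("LB", "LS", "LA"))
}

#' Per-branch breakdown of synchronous pairs
#'
#' Counts LS pairs by their (shared) branch of appearance, with the share of
#' all LS pairs each branch carries.
#'
#' @param pairs classified-pair data.frame.
#' @param system the active [branch_system()].
#' @return Data.frame with columns `branch`, `label`, `n`, `pct`.
#' @export
ls_branch_breakdown <- function(pairs, system = load_branch_system()) {
  ls <- pairs[pairs$category == "LS", , drop = FALSE]
  tb <- table(factor(ls$receptor_branch, levels = seq_len(system$K)))
  data.frame(branch = seq_len(system$K),
             label = system$branches$label,
             n = as.integer(tb),
             pct = if (nrow(ls)) round(as.integer(tb) / nrow(ls) * 100, 1)
                   else rep(0, system$K),
             stringsAsFactors = FALSE)
}
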
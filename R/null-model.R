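#' Genome-wide branch frequencies
#'
#' Estimates the probability that a random gene was born in each branch, the
#' F_b of the independence null, from a genome-wide birth table (in the human
#' analysis, the roots of all 19,928 gene trees). The elapsed time within
#' branches differs by an order of magnitude (10 my vs 110 my steps), so an
#' optional weighting by branch duration is provided; the unweighted and
#' weighted nulls give the same qualitative result and the unweighted form is
#' the default.
#'
#' @param genome_births named integer vector (gene id -> branch), or a plain
#'   integer vector of per-branch gene counts of length K.
#' @param system the active [branch_system()].
#' @param weight_mode `"none"` (F_b proportional to the gene count N_b),
#'   `"multiply_duration"` (N_b times the branch duration) or
#'   `"divide_duration"` (N_b per unit time).
#' @return An object of class `branch_frequencies`: list with `F` (numeric
#'   length-K vector summing to 1), `weight_mode`, `source_n` (genes
#'   counted) and `K`.
#' @export
estimate_frequencies <- function(genome_births, system = load_branch_system(),
                                 weight_mode = c("none", "multiply_duration",
                                                 "divide_duration")) {
  weight_mode <- match.arg(weight_mode)
  if (!is.null(names(genome_births)) || length(genome_births) != system$K) {
    b <- .check_branches(genome_births, system, "branch")
    counts <- as.numeric(tabulate(b, nbins = system$K))
    source_n <- length(b)
  } else {
    counts <- as.numeric(genome_births)
    if (anyNA(counts) || any(counts < 0))
      stop("per-branch counts must be non-negative", call. = FALSE)
    source_n <- sum(counts)
  }
  if (sum(counts) == 0)
    stop("all branch counts are zero; cannot estimate frequencies",
         call. = FALSE)
  w <- switch(weight_mode,
              none = counts,
              multiply_duration = counts * branch_durations(system),
              divide_duration = counts / branch_durations(system))
  structure(list(F = w / sum(w), weight_mode = weight_mode,
                 source_n = as.integer(source_n), K = system$K),
            class = "branch_frequencies")
}

#' Construct branch frequencies from a probability vector
#'
#' @param F numeric vector of K non-negative values; normalised to sum 1.
#' @param weight_mode recorded mode label (default `"none"`).
#' @return A `branch_frequencies` object.
#' @export
branch_frequencies <- function(F, weight_mode = "none") {
  F <- as.numeric(F)
  if (anyNA(F) || any(F < 0) || sum(F) == 0)
    stop("'F' must be non-negative with a positive sum", call. = FALSE)
  structure(list(F = F / sum(F), weight_mode = weight_mode,
                 source_n = NA_integer_, K = length(F)),
            class = "branch_frequencies")
}

#' @export
print.branch_frequencies <- function(x, ...) {
  cat(sprintf("Branch frequencies (K = %d, mode = %s%s):\n", x$K,
              x$weight_mode,
              if (is.na(x$source_n)) "" else
                sprintf(", %d genes", x$source_n)))
  print(round(stats::setNames(x$F, paste0("B", seq_len(x$K))), 4))
  invisible(x)
}

#' Per-branch receptor counts
#'
#' @param pairs classified-pair data.frame (uses `receptor_branch`), or an
#'   integer vector of receptor branches.
#' @param system the active [branch_system()].
#' @return Integer vector of length K: receptors born in each branch.
#' @export
receptor_branch_counts <- function(pairs, system = load_branch_system()) {
  b <- if (is.data.frame(pairs)) pairs$receptor_branch else pairs
  tabulate(.check_branches(b, system, "receptor_branch"), nbins = system$K)
}

#' Expected category counts under independent gene birth
#'
#' Under the null, each receptor keeps its observed birth branch and its
#' first ligand's branch is drawn independently from the genome-wide
#' frequencies F. With R_b receptors in branch b the expected counts are
#' \deqn{E_{LS} = \sum_b R_b F_b, \quad
#'       E_{LB} = \sum_b R_b \sum_{b' < b} F_{b'}, \quad
#'       E_{LA} = \sum_b R_b \sum_{b' > b} F_{b'},}
#' which conserve the total: E_LB + E_LS + E_LA = sum(R).
#'
#' `literal = TRUE` evaluates a historical variant in which the receptor
#' count inside the double sums is indexed by the inner (ligand) branch,
#' `sum_{b' < b} R_{b'} F_{b'}`; that form double-counts receptors and does
#' not conserve the total. It is kept for comparison only.
#'
#' @param R integer vector of per-branch receptor counts (length K), e.g.
#'   from [receptor_branch_counts()].
#' @param F a `branch_frequencies` object or numeric probability vector of
#'   the same length.
#' @param literal evaluate the non-conserving historical variant
#'   (default `FALSE`).
#' @return An object of class `null_expectation`: list with `expected`
#'   (named numeric vector LB/LS/LA) and `n` (= sum(R)).
#' @export
expected_counts <- function(R, F, literal = FALSE) {
  f <- if (inherits(F, "branch_frequencies")) F$F else as.numeric(F)
  R <- as.numeric(R)
  if (length(R) != length(f))
    stop(sprintf("length mismatch: R has %d branches, F has %d",
                 length(R), length(f)), call. = FALSE)
  if (anyNA(R) || any(R < 0)) stop("'R' must be non-negative", call. = FALSE)
  K <- length(f)
  cum_before <- c(0, cumsum(f)[-K])        # sum of F over branches < b
  cum_after <- rev(c(0, cumsum(rev(f))[-K]))  # sum of F over branches > b
  if (literal) {
    e <- c(LB = sum(cumsum(R * f)[-K]),    # sum_{b1>=2} sum_{b2<b1} R_b2 F_b2
           LS = sum(R * f),
           LA = sum(rev(cumsum(rev(R * f))[-K])))
  } else {
    e <- c(LB = sum(R * cum_before), LS = sum(R * f), LA = sum(R * cum_after))
  }
  structure(list(expected = e, n = sum(R), literal = literal),
            class = "null_expectation")
}

#' @export
print.null_expectation <- function(x, ...) {
  cat(sprintf("Expected category counts under independence (n = %g%s):\n",
              x$n, if (isTRUE(x$literal)) ", literal variant" else ""))
  print(round(x$expected, 2))
  invisible(x)
}

#' Goodness-of-fit of observed categories against the null expectation
#'
#' Pearson's chi-squared over the three categories,
#' `sum((O - E)^2 / E)` on 2 degrees of freedom.
#'
#' @param observed a `category_counts` object or numeric vector of three
#'   observed counts (LB, LS, LA).
#' @param expected a `null_expectation` object or numeric vector of three
#'   expected counts; all components must be positive.
#' @return List with `statistic`, `df` (2), `p.value`, `observed`,
#'   `expected`.
#' @export
gof_test <- function(observed, expected) {
  o <- if (inherits(observed, "category_counts")) observed$counts
       else as.numeric(observed)
  e <- if (inherits(expected, "null_expectation")) expected$expected
       else as.numeric(expected)
  if (length(o) != 3L || length(e) != 3L)
    stop("three categories expected", call. = FALSE)
  if (any(e <= 0))
    stop("expected count is zero in a category; pool categories before testing",
         call. = FALSE)
  if (abs(sum(o) - sum(e)) > 1e-6 * max(1, sum(o)))
    warning(sprintf("observed total (%g) differs from expected total (%g)",
                    sum(o), sum(e)), call. = FALSE)
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, df = 2L,
       p.value = stats::pchisq(stat, df = 2L, lower.tail = FALSE),
       observed = stats::setNames(o, c("LB", "LS", "LA")),
       expected = stats::setNames(e, c("LB", "LS", "LA")))
}

#' Pairwise equal-proportion test between two category counts
#'
#' Chi-squared goodness-of-fit of two counts against equal expected counts
#' ((a + b) / 2 each), 1 degree of freedom, no continuity correction; used
#' for the pairwise LS vs LA / LB vs LS / LB vs LA comparisons.
#'
#' @param count_a,count_b non-negative integer counts, not both zero.
#' @return List with `statistic`, `df` (1), `p.value`.
#' @export
equal_proportion_test <- function(count_a, count_b) {
  if (count_a < 0 || count_b < 0 || count_a + count_b == 0)
    stop("counts must be non-negative and not both zero", call. = FALSE)
  ht <- stats::chisq.test(c(count_a, count_b), p = c(0.5, 0.5))
  list(statistic = unname(ht$statistic), df = 1L, p.value = ht$p.value)
}
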
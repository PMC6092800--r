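#' Dated branch systems for gene-birth annotation
#'
#' A branch system is the ordered set of K dated branches of the species tree
#' on which all gene births are expressed. Branch 1 is the most ancestral;
#' ages of origin (in million years, my) strictly decrease with the index.
#' The default system is the 10-branch animal tree used throughout the
#' package: Opisthokonta (1500 my), Metazoa (713), Bilateria (580), Chordata
#' (560), Vertebrata (550), Teleostei (420), Sarcopterygii (400), Tetrapoda
#' (359), Amniota (326) and Mammalia (184). At the base of the metazoan tree
#' Placozoa, Porifera, Ctenophora and Cnidaria are deliberately merged into
#' the single Metazoa branch because their relative branching order is
#' unresolved.
#'
#' @param ages numeric vector of ages of origin in my, most ancestral first;
#'   must be strictly decreasing and positive.
#' @param labels optional character vector of branch labels, recycled-length
#'   checked against `ages`.
#' @return An object of class `branch_system`: a list with `branches` (a
#'   data.frame with columns `index`, `label`, `age_origin`, `duration`) and
#'   `K`. `duration` is the elapsed time within a branch,
#'   `age_origin[b] - age_origin[b + 1]` (the youngest branch runs to the
#'   present, so its duration equals its age of origin).
#' @examples
#' bs <- branch_system(c(100, 50, 10), labels = c("root", "mid", "tip"))
#' branch_durations(bs)
#' @seealso [load_branch_system()] for the built-in default and file input.
#' @export
branch_system <- function(ages, labels = NULL) {
  ages <- as.numeric(ages)
  if (length(ages) < 2L)
    stop("a branch system needs at least 2 branches", call. = FALSE)
  if (anyNA(ages) || any(ages <= 0))
    stop("branch ages must be positive numbers", call. = FALSE)
  bad <- which(diff(ages) >= 0)
  if (length(bad))
    stop(sprintf("branch ages must strictly decrease with the index; branch %d (%g my) is not younger than branch %d (%g my)",
                 bad[1L] + 1L, ages[bad[1L] + 1L], bad[1L], ages[bad[1L]]),
         call. = FALSE)
  K <- length(ages)
  if (is.null(labels)) labels <- paste0("B", seq_len(K))
  if (length(labels) != K)
    stop("'labels' must have one entry per branch", call. = FALSE)
  branches <- data.frame(
    index = seq_len(K),
    label = as.character(labels),
    age_origin = ages,
    duration = c(-diff(ages), ages[K]),
    stringsAsFactors = FALSE
  )
  structure(list(branches = branches, K = K), class = "branch_system")
}

#' @export
print.branch_system <- function(x, ...) {
  cat(sprintf("Branch system with %d dated branches (my):\n", x$K))
  print(x$branches, row.names = FALSE)
  invisible(x)
}

#' Branch durations
#'
#' @param system a [branch_system()].
#' @return Numeric vector of length K: the elapsed time (my) within each
#'   branch.
#' @export
branch_durations <- function(system) {
  stopifnot(inherits(system, "branch_system"))
  system$branches$duration
}

.default_ages <- c(1500, 713, 580, 560, 550, 420, 400, 359, 326, 184)
.default_labels <- c("Opisthokonta", "Metazoa", "Bilateria", "Chordata",
                     "Vertebrata", "Teleostei", "Sarcopterygii", "Tetrapoda",
                     "Amniota", "Mammalia")

#' Load a branch system from a file, data.frame or the built-in default
#'
#' With no argument, returns the default 10-branch animal-tree system (see
#' [branch_system()]). A data.frame must carry columns `index`, `label`
#' and `age_origin`. A file path may point to a TSV with those columns or a
#' YAML file with a top-level `branches` list whose entries have `index`,
#' `label` and `age_origin` fields.
#'
#' @param config `NULL` (default system), a data.frame, or a path to a TSV or
#'   YAML (`.yaml`/`.yml`) file.
#' @return A [branch_system()].
#' @examples
#' load_branch_system()$K      # 10
#' @export
load_branch_system <- function(config = NULL) {
  if (is.null(config))
    return(branch_system(.default_ages, .default_labels))
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop("branch-system file not found: ", config, call. = FALSE)
    if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      y <- yaml::read_yaml(config)
      if (is.null(y$branches))
        stop("YAML branch config must have a top-level 'branches' list",
             call. = FALSE)
      config <- do.call(rbind, lapply(y$branches, function(b)
        data.frame(index = as.integer(b$index), label = as.character(b$label),
                   age_origin = as.numeric(b$age_origin))))
    } else {
      config <- utils::read.delim(config, stringsAsFactors = FALSE)
    }
  }
  if (!is.data.frame(config))
    stop("'config' must be NULL, a data.frame or a file path", call. = FALSE)
  need <- c("index", "label", "age_origin")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("branch table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- as.integer(config$index)
  if (anyDuplicated(idx))
    stop("duplicate branch indices: ",
         paste(unique(idx[duplicated(idx)]), collapse = ", "), call. = FALSE)
  if (!identical(sort(idx), seq_along(idx)))
    stop("branch indices must be consecutive 1..K", call. = FALSE)
  ord <- order(idx)
  branch_system(config$age_origin[ord], config$label[ord])
}

# validate a vector of branch indices against a system; returns integer vector
.check_branches <- function(branch, system, what = "branch") {
  b <- suppressWarnings(as.integer(branch))
  bad <- which(is.na(b) | b < 1L | b > system$K)
  if (length(bad))
    stop(sprintf("%s out of range 1..%d at position %d (value '%s')",
                 what, system$K, bad[1L], as.character(branch[bad[1L]])),
         call. = FALSE)
  b
}
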
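#' Read a gene-birth table
#'
#' Reads a TSV with header columns `gene_id` and `branch` mapping each gene
#' to its branch of appearance (the most ancestral branch containing all taxa
#' where the gene is present and functional today).
#'
#' @param path path to a tab-separated file with a header row.
#' @param system the active [branch_system()]; branches are validated against
#'   its range 1..K.
#' @return A named integer vector: names are gene ids, values branch indices.
#'   An empty table yields an empty vector with a warning.
#' @export
read_gene_births <- function(path, system = load_branch_system()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene_id", "branch")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("gene-birth table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(d) == 0L) {
    warning("empty gene-birth table: ", path, call. = FALSE)
    return(stats::setNames(integer(0), character(0)))
  }
  b <- suppressWarnings(as.integer(d$branch))
  bad <- which(is.na(b) | b < 1L | b > system$K)
  if (length(bad))
    stop(sprintf("unknown branch '%s' (valid range 1..%d) at line %d of %s",
                 d$branch[bad[1L]], system$K, bad[1L] + 1L, path),
         call. = FALSE)
  dup <- which(duplicated(d$gene_id))
  if (length(dup))
    stop(sprintf("duplicate gene_id '%s' at line %d of %s",
                 d$gene_id[dup[1L]], dup[1L] + 1L, path), call. = FALSE)
  stats::setNames(b, d$gene_id)
}

#' Write a gene-birth table
#'
#' @param births named integer vector (gene id -> branch).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_births <- function(births, path) {
  d <- data.frame(gene_id = names(births), branch = as.integer(births),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.evidence_levels <- c("experimental", "predicted")
.ligand_kinds <- c("gene_product", "synthesized")

#' Read a receptor-ligand interaction table
#'
#' Reads a TSV with header columns `receptor_id`, `ligand_id`, `family_id`,
#' `evidence` (`experimental` or `predicted`), `ligand_kind` (`gene_product`
#' or `synthesized`) and `enzyme_gene_ids` (semicolon-separated, empty unless
#' the ligand is synthesized). Synthesized ligands are non-peptide molecules
#' (dopamine, serotonin, ...) whose presence is dated through the genes
#' encoding their biosynthetic enzymes, so they must carry at least one
#' enzyme gene. Predicted-evidence records are retained on read; filter with
#' the `evidence` argument of [cobirth_pipeline()] or by subsetting.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A data.frame of validated interaction records, one row per
#'   interaction, `enzyme_gene_ids` kept as the semicolon-separated string.
#' @seealso [enzyme_gene_list()] to split the enzyme column.
#' @export
read_interactions <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = NULL)
  need <- c("receptor_id", "ligand_id", "family_id", "evidence",
            "ligand_kind", "enzyme_gene_ids")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("interaction table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d <- d[, need]
  validate_interactions(d, path = path)
}

#' Validate interaction records
#'
#' @param d data.frame with the interaction columns of [read_interactions()].
#' @param path optional source path, used in error messages only.
#' @return `d`, invisibly validated (returned unchanged on success).
#' @export
validate_interactions <- function(d, path = "<data.frame>") {
  where <- function(i) sprintf("line %d of %s", i + 1L, path)
  bad <- which(!d$evidence %in% .evidence_levels)
  if (length(bad))
    stop(sprintf("unknown evidence '%s' at %s (expected %s)",
                 d$evidence[bad[1L]], where(bad[1L]),
                 paste(.evidence_levels, collapse = "/")), call. = FALSE)
  bad <- which(!d$ligand_kind %in% .ligand_kinds)
  if (length(bad))
    stop(sprintf("unknown ligand_kind '%s' at %s (expected %s)",
                 d$ligand_kind[bad[1L]], where(bad[1L]),
                 paste(.ligand_kinds, collapse = "/")), call. = FALSE)
  bad <- which(d$receptor_id == d$ligand_id)
  if (length(bad))
    stop(sprintf("receptor_id equals ligand_id ('%s') at %s",
                 d$receptor_id[bad[1L]], where(bad[1L])), call. = FALSE)
  enz <- enzyme_gene_list(d)
  bad <- which(d$ligand_kind == "synthesized" & lengths(enz) == 0L)
  if (length(bad))
    stop(sprintf("synthesized ligand '%s' with empty enzyme gene list at %s",
                 d$ligand_id[bad[1L]], where(bad[1L])), call. = FALSE)
  bad <- which(d$ligand_kind == "gene_product" & lengths(enz) > 0L)
  if (length(bad))
    stop(sprintf("gene_product ligand '%s' carries enzyme genes at %s",
                 d$ligand_id[bad[1L]], where(bad[1L])), call. = FALSE)
  d
}

#' Split the semicolon-separated enzyme column into a list
#'
#' @param d interaction data.frame (or the `enzyme_gene_ids` column itself).
#' @return List of character vectors, one per record; empty vector for
#'   gene-product ligands.
#' @export
enzyme_gene_list <- function(d) {
  x <- if (is.data.frame(d)) d$enzyme_gene_ids else d
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(v) v[nzchar(trimws(v))])
}

#' Write an interaction table
#'
#' @param d interaction data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write classified receptor-ligand pairs
#'
#' Classified pairs are serialised as a TSV with columns `receptor_id`,
#' `first_ligand_id`, `receptor_branch`, `ligand_branch`, `category`
#' (LB/LS/LA), `distance` and, when present, `family_id`. Writing then
#' re-reading reproduces the records exactly.
#'
#' @param pairs classified-pair data.frame (from [classify_pairs()]).
#' @param path TSV path.
#' @param system the active [branch_system()], used for validation on read.
#' @return `read_classified_pairs()` returns the data.frame;
#'   `write_classified_pairs()` returns `path` invisibly.
#' @export
write_classified_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_classified_pairs
#' @export
read_classified_pairs <- function(path, system = load_branch_system()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("receptor_id", "first_ligand_id", "receptor_branch",
            "ligand_branch", "category", "distance")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("classified-pair table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  d$receptor_branch <- .check_branches(d$receptor_branch, system,
                                       "receptor_branch")
  d$ligand_branch <- .check_branches(d$ligand_branch, system, "ligand_branch")
  d$distance <- as.integer(d$distance)
  bad <- which(d$category != ifelse(d$distance < 0L, "LB",
                                    ifelse(d$distance == 0L, "LS", "LA")) |
               d$distance != d$ligand_branch - d$receptor_branch)
  if (length(bad))
    stop(sprintf("inconsistent category/distance at line %d of %s",
                 bad[1L] + 1L, path), call. = FALSE)
  d
}
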
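#' Resolve the birth branch of each ligand
#'
#' A gene-product ligand is dated by its own gene's birth branch. A
#' synthesized ligand (dopamine, acetylcholine, ...) cannot exist until every
#' enzyme of its biosynthetic chain is present, so it is dated by the most
#' recent (largest-index) branch among its enzyme genes; when all enzymes
#' appeared in one branch that branch is used directly.
#'
#' @param interactions validated interaction data.frame
#'   (see [read_interactions()]).
#' @param births named integer vector mapping gene ids to branches; must
#'   cover every ligand gene and enzyme gene referenced.
#' @return Integer vector of ligand birth branches, one per interaction row.
#' @export
resolve_ligand_branch <- function(interactions, births) {
  enz <- enzyme_gene_list(interactions)
  need <- unique(c(interactions$ligand_id[interactions$ligand_kind ==
                                            "gene_product"],
                   unlist(enz, use.names = FALSE)))
  miss <- setdiff(need, names(births))
  if (length(miss))
    stop("gene(s) missing from the birth table: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) sprintf(" (+%d more)", length(miss) - 5L),
         call. = FALSE)
  out <- integer(nrow(interactions))
  gp <- interactions$ligand_kind == "gene_product"
  out[gp] <- unname(births[interactions$ligand_id[gp]])
  out[!gp] <- vapply(enz[!gp], function(g) max(unname(births[g])), integer(1))
  out
}

#' Flag enzyme-chain ligands whose enzymes span several branches
#'
#' @inheritParams resolve_ligand_branch
#' @return Logical vector, one per interaction row: `TRUE` for synthesized
#'   ligands whose enzyme genes do not all share one branch, `FALSE`
#'   otherwise (including all gene-product ligands).
#' @export
mixed_enzyme_ligand <- function(interactions, births) {
  enz <- enzyme_gene_list(interactions)
  syn <- interactions$ligand_kind == "synthesized"
  out <- logical(nrow(interactions))
  out[syn] <- vapply(enz[syn],
                     function(g) length(unique(unname(births[g]))) > 1L,
                     logical(1))
  out
}

#' Reduce an interaction list to one first-ligand pair per receptor
#'
#' Most receptors bind several ligands; only the first ligand to appear is
#' informative about whether a receptor had a partner at birth. For each
#' receptor the ligand with the most ancestral (minimum) birth branch is
#' retained; ties on branch are broken by lexicographically smallest
#' ligand id, which is reproducible and immaterial since only the branch of
#' appearance, shared by all tied ligands, enters the analysis.
#'
#' @inheritParams resolve_ligand_branch
#' @return A data.frame with one row per distinct receptor: `receptor_id`,
#'   `first_ligand_id`, `receptor_branch`, `ligand_branch`, `family_id`.
#'   Empty input yields an empty data.frame with a warning.
#' @export
reduce_to_first_ligand <- function(interactions, births) {
  if (nrow(interactions) == 0L) {
    warning("no interactions to reduce", call. = FALSE)
    return(data.frame(receptor_id = character(0),
                      first_ligand_id = character(0),
                      receptor_branch = integer(0),
                      ligand_branch = integer(0),
                      family_id = character(0),
                      stringsAsFactors = FALSE))
  }
  fam <- unique(interactions[, c("receptor_id", "family_id")])
  dup <- fam$receptor_id[duplicated(fam$receptor_id)]
  if (length(dup))
    stop("receptor(s) assigned to more than one family: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  miss <- setdiff(unique(interactions$receptor_id), names(births))
  if (length(miss))
    stop("receptor gene(s) missing from the birth table: ",
         paste(utils::head(miss, 5L), collapse = ", "), call. = FALSE)
  lb <- resolve_ligand_branch(interactions, births)
  # per receptor: minimum ligand branch, then lexicographic ligand id
  ord <- order(interactions$receptor_id, lb, interactions$ligand_id)
  first <- ord[!duplicated(interactions$receptor_id[ord])]
  out <- data.frame(
    receptor_id = interactions$receptor_id[first],
    first_ligand_id = interactions$ligand_id[first],
    receptor_branch = unname(births[interactions$receptor_id[first]]),
    ligand_branch = lb[first],
    family_id = interactions$family_id[first],
    stringsAsFactors = FALSE
  )
  out[order(out$receptor_id), , drop = FALSE]
}

#' Reduce first-ligand pairs to one pair per receptor family
#'
#' Guards against duplication-driven pseudo-replication: within each receptor
#' family only the earliest-born receptor is kept, with its first ligand.
#' Among receptors tied on branch, the one whose first ligand is most
#' ancestral wins; any remaining tie is broken by lexicographic receptor id.
#'
#' @param pairs first-ligand pair data.frame carrying `family_id`
#'   (from [reduce_to_first_ligand()] or [classify_pairs()]).
#' @return A data.frame with one row per family, same columns as the input.
#' @export
reduce_one_per_family <- function(pairs) {
  if (is.null(pairs$family_id) || anyNA(pairs$family_id))
    stop("every pair must carry a family_id", call. = FALSE)
  if (nrow(pairs) == 0L) return(pairs)
  ord <- order(pairs$family_id, pairs$receptor_branch, pairs$ligand_branch,
               pairs$receptor_id)
  keep <- ord[!duplicated(pairs$family_id[ord])]
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$family_id), , drop = FALSE]
}
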
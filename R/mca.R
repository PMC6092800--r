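#' Ligand molecular-weight class
#'
#' Bins ligand molecular weight into the three classes used in the trait
#' analysis: small (< 550 Da), medium (550 to 25,000 Da), big (> 25,000 Da).
#'
#' @param weight_da numeric molecular weight in daltons.
#' @return Character vector in \{"small", "medium", "big"\}.
#' @export
weight_class <- function(weight_da) {
  w <- as.numeric(weight_da)
  if (anyNA(w) || any(w <= 0))
    stop("molecular weights must be positive", call. = FALSE)
  ifelse(w < 550, "small", ifelse(w <= 25000, "medium", "big"))
}

#' Assemble the categorical trait table for MCA
#'
#' One row per classified pair; every supplied trait becomes a categorical
#' variable alongside the appearance category.
#'
#' @param pairs classified-pair data.frame (uses `category` and, when
#'   present, `family_id`).
#' @param weight_da numeric ligand molecular weights (Da), binned via
#'   [weight_class()].
#' @param molecule_group,signal_type,fun optional character vectors of
#'   molecule group labels, signal types (hormone, neuropeptide, ...) and
#'   interaction functions (immunity, metabolism, ...).
#' @param include_family include `family_id` as a variable (default `TRUE`;
#'   with many one- or two-member families it carries much of the indicator
#'   inertia, so consider down-weighting it via the `var_weights` argument
#'   of [run_mca()] or excluding it).
#' @return Data.frame of factors, one column per variable.
#' @export
make_trait_table <- function(pairs, weight_da, molecule_group = NULL,
                             signal_type = NULL, fun = NULL,
                             include_family = TRUE) {
  tt <- data.frame(appearance = factor(pairs$category,
                                       levels = c("LB", "LS", "LA")),
                   weight_class = factor(weight_class(weight_da),
                                         levels = c("small", "medium",
                                                    "big")))
  if (!is.null(molecule_group))
    tt$molecule_group <- factor(as.character(molecule_group))
  if (!is.null(signal_type)) tt$signal_type <- factor(as.character(signal_type))
  if (!is.null(fun)) tt$fun <- factor(as.character(fun))
  if (include_family) tt$family_id <- factor(as.character(pairs$family_id))
  droplevels(tt)
}

#' Multiple correspondence analysis of pair traits
#'
#' Canonical indicator-matrix MCA: the complete disjunctive (indicator)
#' matrix Z is built from the categorical variables, and a correspondence
#' analysis of Z is performed through the singular value decomposition of
#' the matrix of standardized residuals
#' \eqn{S = D_r^{-1/2} (P - r c^\top) D_c^{-1/2}} with `P = Z / sum(Z)`.
#' Eigenvalues are the squared singular values; total inertia equals
#' `J/Q - 1` for J category levels over Q variables. No Benzecri/Greenacre
#' inertia correction is applied. Variables can be down-weighted (their
#' indicator columns scaled) to keep many-level variables such as the
#' receptor family from dominating the inertia.
#'
#' @param traits data.frame of factors (see [make_trait_table()]); at least
#'   2 variables, 3 rows, and every variable with >= 2 observed levels.
#' @param n_dims number of dimensions to retain (default 2).
#' @param var_weights optional named numeric vector of per-variable weights
#'   (default 1 for every variable).
#' @return An object of class `mca_result`: list with `eigenvalues` (all
#'   non-trivial dimensions), `total_inertia`, `row_coords` and
#'   `level_coords` (principal coordinates, `n_dims` columns),
#'   `level_info` (variable and level per indicator column), `n_dims`,
#'   `Q`, `J`.
#' @export
run_mca <- function(traits, n_dims = 2L, var_weights = NULL) {
  if (!is.data.frame(traits) || ncol(traits) < 2L)
    stop("'traits' must be a data.frame with at least 2 variables",
         call. = FALSE)
  if (nrow(traits) < 3L) stop("need at least 3 rows", call. = FALSE)
  traits[] <- lapply(traits, function(x) droplevels(factor(x)))
  nlev <- vapply(traits, nlevels, integer(1))
  if (any(nlev < 2L))
    stop("variable(s) with a single observed level: ",
         paste(names(traits)[nlev < 2L], collapse = ", "), call. = FALSE)
  Q <- ncol(traits)
  Z <- do.call(cbind, lapply(names(traits), function(v) {
    m <- stats::model.matrix(~ x - 1, data.frame(x = traits[[v]]))
    colnames(m) <- paste(v, levels(traits[[v]]), sep = ".")
    m
  }))
  info <- data.frame(variable = rep(names(traits), nlev),
                     level = unlist(lapply(traits, levels),
                                    use.names = FALSE),
                     stringsAsFactors = FALSE)
  if (!is.null(var_weights)) {
    miss <- setdiff(names(traits), names(var_weights))
    w <- stats::setNames(rep(1, Q), names(traits))
    w[names(var_weights)] <- var_weights
    if (any(w <= 0)) stop("variable weights must be positive", call. = FALSE)
    Z <- Z * rep(w, nlev)[col(Z)]
  }
  J <- ncol(Z)
  max_dims <- J - Q
  if (n_dims > max_dims)
    stop(sprintf("n_dims = %d exceeds the %d available dimensions",
                 n_dims, max_dims), call. = FALSE)
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - tcrossprod(r, cc)) / sqrt(tcrossprod(r, cc))
  sv <- svd(S)
  keep <- which(sv$d > 1e-10)
  eig <- sv$d[keep]^2
  dims <- seq_len(n_dims)
  row_coords <- (sv$u[, keep, drop = FALSE] / sqrt(r)) %*%
    diag(sv$d[keep], length(keep))
  level_coords <- (sv$v[, keep, drop = FALSE] / sqrt(cc)) %*%
    diag(sv$d[keep], length(keep))
  dimnames(row_coords) <- list(rownames(traits),
                               paste0("Dim", seq_along(keep)))
  dimnames(level_coords) <- list(colnames(Z), paste0("Dim", seq_along(keep)))
  structure(list(eigenvalues = eig, total_inertia = sum(eig),
                 row_coords = row_coords[, dims, drop = FALSE],
                 level_coords = level_coords[, dims, drop = FALSE],
                 level_info = info, n_dims = as.integer(n_dims),
                 Q = Q, J = J),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  cat(sprintf("MCA of %d variables (%d levels); total inertia %.4f\n",
              x$Q, x$J, x$total_inertia))
  ev <- utils::head(x$eigenvalues, 5L)
  cat("Leading eigenvalues:", paste(sprintf("%.4f", ev), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
plot.mca_result <- function(x, dims = c(1L, 2L), ...) {
  lc <- x$level_coords[, dims, drop = FALSE]
  graphics::plot(lc, type = "n",
                 xlab = sprintf("Dim %d (%.1f%%)", dims[1],
                                100 * x$eigenvalues[dims[1]] /
                                  x$total_inertia),
                 ylab = sprintf("Dim %d (%.1f%%)", dims[2],
                                100 * x$eigenvalues[dims[2]] /
                                  x$total_inertia), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::text(lc, labels = rownames(lc),
                 col = as.integer(factor(x$level_info$variable)))
  invisible(x)
}
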
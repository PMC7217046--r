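# Derivation of cell-type-specific gene modules from a reference expression
# atlas: per-gene Z scoring across tissues, expression rank of the target
# column, and a tissue-specificity count.

as_atlas_matrix <- function(atlas) {
  if (inherits(atlas, "synthetic_atlas")) atlas <- atlas$expr
  stopifnot(is.matrix(atlas), !is.null(rownames(atlas)), !is.null(colnames(atlas)))
  if (anyDuplicated(rownames(atlas))) stop("gene IDs must be unique")
  if (anyNA(atlas)) stop("atlas must contain no missing values")
  atlas
}

#' Per-gene Z scores across atlas columns
#'
#' Standardizes each gene across all tissues/cell types using the
#' population SD (divide by N). Genes with zero variance are flagged and
#' their Z row set to all zeros (never NaN).
#'
#' @param atlas A genes x tissues matrix (or a `synthetic_atlas`).
#' @return The Z matrix with a logical attribute `zero_variance` marking
#'   flagged genes.
#' @export
zscore_by_gene <- function(atlas) {
  x <- as_atlas_matrix(atlas)
  if (ncol(x) < 2L) stop("at least 2 atlas columns required")
  m <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - m)^2))
  flagged <- sd_pop < 1e-12
  z <- (x - m) / ifelse(flagged, 1, sd_pop)
  z[flagged, ] <- 0
  attr(z, "zero_variance") <- flagged
  z
}

#' Tissue-specificity score of one gene
#'
#' Counts the columns in which the gene shows increased expression,
#' defined as a Z score strictly greater than 3 (3 SD above the mean across
#' all tissues). The most tissue-specific genes have the lowest counts; the
#' target column itself is included in the count.
#'
#' @param z_row Numeric vector of Z scores for one gene (or a Z matrix, in
#'   which case a per-gene vector is returned).
#' @param z_threshold Increased-expression cutoff (default 3, strict).
#' @return Integer count(s) of columns with `Z > z_threshold`.
#' @export
specificity_score <- function(z_row, z_threshold = 3) {
  if (is.matrix(z_row)) {
    return(as.integer(rowSums(z_row > z_threshold)))
  }
  stopifnot(all(is.finite(z_row)))
  sum(z_row > z_threshold)
}

#' Derive a cell-type-specific gene module
#'
#' A gene belongs to the module for `target_cell` when all three criteria
#' hold at the target column: (1) its expression rank across all columns is
#' in the top 3 (rank 1–3, ties assigned the best rank); (2) its Z score is
#' strictly greater than 5; (3) its specificity score (columns with Z > 3)
#' is strictly less than 10.
#'
#' @param atlas A genes x tissues matrix or `synthetic_atlas`.
#' @param target_cell Column label of the target cell type; defaults to the
#'   atlas's own target for a `synthetic_atlas`.
#' @param z_min Z-score criterion (default 5, strict).
#' @param rank_max Rank criterion (default 3).
#' @param specificity_max Specificity criterion (default 10, strict upper
#'   bound).
#' @param z_threshold Z cutoff inside the specificity count (default 3).
#' @return A tibble of class `gene_module` with columns `gene_id`,
#'   `z_target`, `rank_target`, `specificity`, ordered by decreasing
#'   `z_target`; the target cell is stored in attribute `target_cell`.
#' @export
derive_cell_module <- function(atlas, target_cell = NULL,
                               z_min = 5, rank_max = 3L,
                               specificity_max = 10L, z_threshold = 3) {
  if (inherits(atlas, "synthetic_atlas") && is.null(target_cell)) {
    target_cell <- atlas$target_cell
  }
  x <- as_atlas_matrix(atlas)
  if (is.null(target_cell) || !target_cell %in% colnames(x)) {
    stop("target column '", target_cell %||% "<missing>", "' not found in atlas")
  }
  z <- zscore_by_gene(x)
  # per-gene rank of the target column by expression, 1 = highest;
  # ties share the best (minimum) rank
  tgt <- match(target_cell, colnames(x))
  rank_target <- apply(x, 1, function(r) rank(-r, ties.method = "min")[tgt])
  z_target <- z[, tgt]
  spec_count <- specificity_score(z, z_threshold = z_threshold)
  keep <- rank_target <= rank_max & z_target > z_min & spec_count < specificity_max
  out <- tibble::tibble(
    gene_id = rownames(x)[keep],
    z_target = unname(z_target[keep]),
    rank_target = as.integer(unname(rank_target[keep])),
    specificity = as.integer(spec_count[keep])
  )
  out <- out[order(-out$z_target), ]
  attr(out, "target_cell") <- target_cell
  class(out) <- c("gene_module", class(out))
  out
}
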
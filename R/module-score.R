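# Per-sample module scores from a normalized expression matrix: the first
# principal component of the module-restricted, gene-centered matrix via
# singular value decomposition.

#' Restrict an expression matrix to module genes
#'
#' @param expr A genes x samples numeric matrix with row (gene) and column
#'   (sample) names, normalized (log-scale or variance-stabilized); a
#'   `synthetic_mixtures` object is also accepted.
#' @param module A `gene_module` tibble (or a character vector of gene
#'   IDs).
#' @return The row-subset matrix. Module genes absent from the matrix are
#'   reported via `message()`; fewer than 2 matches is an error.
#' @export
subset_to_module <- function(expr, module) {
  if (inherits(expr, "synthetic_mixtures")) expr <- expr$expr
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (anyNA(expr)) stop("expression matrix must contain no missing values")
  genes <- if (is.character(module)) module else module$gene_id
  present <- genes %in% rownames(expr)
  if (sum(present) < 2L) {
    stop("only ", sum(present), " module gene(s) found in the expression matrix; ",
         ">= 2 required")
  }
  if (any(!present)) {
    message(sum(!present), " module gene(s) absent from the matrix: ",
            paste(genes[!present], collapse = ", "))
  }
  expr[genes[present], , drop = FALSE]
}

#' SVD module score (first principal component of module genes)
#'
#' Centers each gene, takes the singular value decomposition of the
#' centered matrix, and returns the first principal component score per
#' sample (`sigma_1 * v_1`). The sign is fixed so that the score correlates
#' positively with the per-sample mean module expression (higher score =
#' more of the cell type). Optional unit-variance scaling of genes is
#' exposed but off by default.
#'
#' @param expr_subset Module genes x samples matrix (>= 2 of each), e.g.
#'   from [subset_to_module()].
#' @param scale_genes Scale genes to unit variance before SVD (default
#'   `FALSE`: centering only).
#' @return A list of class `module_score`: `scores` (named per-sample
#'   vector), `explained_variance_share` of the first singular component,
#'   and `sign_anchor` (the correlation used to fix the sign).
#' @export
svd_module_score <- function(expr_subset, scale_genes = FALSE) {
  stopifnot(is.matrix(expr_subset), nrow(expr_subset) >= 2, ncol(expr_subset) >= 2)
  x <- expr_subset - rowMeans(expr_subset)
  if (scale_genes) {
    s <- apply(x, 1, stats::sd)
    x <- x / ifelse(s < 1e-12, 1, s)
  }
  if (max(abs(x)) < 1e-12) stop("no variance: module expression is constant")
  sv <- svd(x)
  score <- sv$d[1] * sv$v[, 1]
  anchor <- stats::cor(score, colMeans(expr_subset))
  if (!is.na(anchor) && anchor < 0) {
    score <- -score
    anchor <- -anchor
  }
  names(score) <- colnames(expr_subset)
  structure(
    list(
      scores = score,
      explained_variance_share = sv$d[1]^2 / sum(sv$d^2),
      sign_anchor = anchor
    ),
    class = "module_score"
  )
}

#' Spearman correlation of module scores with histology
#'
#' Rank correlation with average ranks for ties; the p value uses the exact
#' null distribution for n <= 10 without ties and the t approximation
#' otherwise.
#'
#' @param scores A `module_score` or a numeric per-sample vector.
#' @param histology Paired per-sample histologic values (e.g.,
#'   semiquantitative CD20 grades or DAB area fractions).
#' @return A tibble with `rho`, `p_value`, `n`, `method`.
#' @export
correlate_with_histology <- function(scores, histology) {
  if (inherits(scores, "module_score")) scores <- scores$scores
  stopifnot(length(scores) == length(histology))
  n <- length(scores)
  if (n < 3) stop("at least 3 paired samples required")
  if (stats::sd(scores) < 1e-12 || stats::sd(histology) < 1e-12) {
    stop("rho undefined: constant vector")
  }
  ties <- anyDuplicated(scores) > 0 || anyDuplicated(histology) > 0
  ct <- suppressWarnings(stats::cor.test(
    scores, histology,
    method = "spearman",
    exact = (n <= 10 && !ties)
  ))
  tibble::tibble(
    rho = unname(ct$estimate),
    p_value = ct$p.value,
    n = n,
    method = if (n <= 10 && !ties) "exact" else "t-approximation"
  )
}

#' Size-factor normalization stand-in for raw counts
#'
#' Median-of-ratios size factors followed by `log2(x / sf + 1)`. This is a
#' simple normalization utility for raw-count inputs so that downstream
#' scoring can assume a log-scale matrix; synthetic matrices from this
#' package are already log scale and do not need it.
#'
#' @param counts Non-negative genes x samples count matrix.
#' @return A list with `log_expr` (log2-normalized matrix) and
#'   `size_factors`.
#' @export
normalize_counts <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  log_geo <- rowMeans(log(counts + 0.5))
  ratios <- log(counts + 0.5) - log_geo
  sf <- exp(apply(ratios, 2, stats::median))
  log_expr <- log2(sweep(counts, 2, sf, "/") + 1)
  list(log_expr = log_expr, size_factors = sf)
}
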
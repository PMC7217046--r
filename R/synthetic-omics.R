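# Synthetic reference atlas (marker genes planted in one cell-type column)
# and bulk expression mixtures with controlled B cell content.

#' Specification for a synthetic reference atlas
#'
#' The atlas emulates a normalized log-scale expression compendium over many
#' tissues and primary cell types, with `n_markers` genes planted as
#' specific to `target_cell`: their expression is `marker_fold`-fold above
#' their own background level in the target column only. Background genes
#' share one baseline per gene plus i.i.d. log-scale noise across columns.
#'
#' Note that with population-SD Z scores a planted marker's target Z at zero
#' noise equals `sqrt(n_tissues - 1)`, so the downstream `Z > 5` selection
#' criterion is only satisfiable for `n_tissues > 26`.
#'
#' @param n_tissues Number of tissue/cell-type columns (>= 12).
#' @param n_genes Number of genes.
#' @param target_cell Label of the target column.
#' @param n_markers Number of planted target-specific genes (< n_genes).
#' @param marker_fold Linear fold-change of markers in the target column
#'   (> 1).
#' @param noise_sd Log2-scale noise SD.
#' @param seed Integer seed.
#' @return A list of class `atlas_spec`.
#' @export
atlas_spec <- function(n_tissues = 50L,
                       n_genes = 1000L,
                       target_cell = "B cell",
                       n_markers = 30L,
                       marker_fold = 16,
                       noise_sd = 0.25,
                       seed = 1L) {
  stopifnot(
    is_whole(n_tissues), n_tissues >= 12,
    is_whole(n_genes), n_genes >= 1,
    is_whole(n_markers), n_markers >= 0, n_markers < n_genes,
    marker_fold > 1,
    noise_sd >= 0,
    nchar(target_cell) > 0
  )
  structure(
    list(
      n_tissues = as.integer(n_tissues), n_genes = as.integer(n_genes),
      target_cell = target_cell, n_markers = as.integer(n_markers),
      marker_fold = marker_fold, noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "atlas_spec"
  )
}

#' Generate a synthetic reference atlas with planted markers
#'
#' @param spec An [atlas_spec()].
#' @return A list of class `synthetic_atlas`: `expr` (genes x tissues,
#'   log2 scale, with gene and column names), `markers` (character vector of
#'   planted marker gene IDs — the ground truth), `target_cell`, `spec`.
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "atlas_spec"))
  genes <- sprintf("GENE_%05d", seq_len(spec$n_genes))
  markers <- character(0)
  if (spec$n_markers > 0) {
    markers <- sprintf("BMARK_%03d", seq_len(spec$n_markers))
    genes[seq_len(spec$n_markers)] <- markers
  }
  cols <- c(spec$target_cell,
            sprintf("tissue_%02d", seq_len(spec$n_tissues - 1L)))
  withr::with_seed(spec$seed, {
    baseline <- stats::runif(spec$n_genes, 3, 8)
    expr <- matrix(baseline, spec$n_genes, spec$n_tissues) +
      matrix(stats::rnorm(spec$n_genes * spec$n_tissues, 0, spec$noise_sd),
             spec$n_genes, spec$n_tissues)
  })
  if (spec$n_markers > 0) {
    expr[seq_len(spec$n_markers), 1] <-
      expr[seq_len(spec$n_markers), 1] + log2(spec$marker_fold)
  }
  dimnames(expr) <- list(genes, cols)
  structure(
    list(expr = expr, markers = markers,
         target_cell = spec$target_cell, spec = spec),
    class = "synthetic_atlas"
  )
}

#' Generate bulk expression mixtures with known B cell content
#'
#' Each sample is a convex combination, on the linear scale, of the atlas
#' target-cell profile (weight `b_fractions[j]`) and the mean background
#' tissue profile (weight `1 - b_fractions[j]`), returned on the log2 scale
#' with additive Gaussian noise. Ground-truth fractions are retained.
#'
#' @param atlas A `synthetic_atlas`.
#' @param b_fractions Per-sample target-cell fraction, each in \[0, 1\].
#' @param noise_sd Log2-scale noise SD.
#' @param seed Integer seed.
#' @return A list of class `synthetic_mixtures`: `expr` (genes x samples,
#'   log2), `b_fractions`, `sample_ids`.
#' @export
generate_bulk_mixtures <- function(atlas, b_fractions, noise_sd = 0.2, seed = 1L) {
  stopifnot(inherits(atlas, "synthetic_atlas"))
  if (any(b_fractions < 0 | b_fractions > 1)) {
    stop("all b_fractions must lie in [0, 1]")
  }
  n <- length(b_fractions)
  stopifnot(n >= 1)
  lin <- 2^atlas$expr
  target <- lin[, atlas$target_cell]
  background <- rowMeans(lin[, colnames(lin) != atlas$target_cell, drop = FALSE])
  mix <- outer(target, b_fractions) +
    outer(background, 1 - b_fractions)            # genes x samples, linear
  expr <- log2(mix)
  withr::with_seed(seed, {
    expr <- expr + matrix(stats::rnorm(length(expr), 0, noise_sd),
                          nrow(expr), ncol(expr))
  })
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(expr) <- list(rownames(atlas$expr), ids)
  structure(
    list(expr = expr, b_fractions = b_fractions, sample_ids = ids),
    class = "synthetic_mixtures"
  )
}

#' Generate paired-observer area-fraction readings
#'
#' Emulates two blinded observers measuring the same slides:
#' `observer_k = max(0, truth + bias_k + eps_k)` with i.i.d. Gaussian
#' errors, deterministic given the seed.
#'
#' @param truth Non-negative per-sample true area fractions (percent).
#' @param bias Length-2 additive offsets for observers a and b.
#' @param noise_sd Measurement noise SD (same units as `truth`).
#' @param seed Integer seed.
#' @return A [paired_measurements()] tibble.
#' @export
generate_paired_readings <- function(truth, bias = c(0, 0), noise_sd = 0.15,
                                     seed = 1L) {
  stopifnot(all(truth >= 0), length(bias) == 2, noise_sd >= 0)
  n <- length(truth)
  withr::with_seed(seed, {
    a <- pmax(0, truth + bias[1] + stats::rnorm(n, 0, noise_sd))
    b <- pmax(0, truth + bias[2] + stats::rnorm(n, 0, noise_sd))
  })
  paired_measurements(sprintf("slide_%03d", seq_len(n)), a, b)
}
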
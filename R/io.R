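# Plain-text/raster interchange: PNG slides with sidecar ground-truth
# masks and a JSON manifest, TSV matrices, CSV panels and cohorts.

#' Write a synthetic slide to disk
#'
#' Writes `<id>.png` (8-bit RGB), `<id>_tissue_mask.png` and
#' `<id>_dab_mask.png` (single-channel, 0/255), and `<id>_manifest.json`
#' (seed, spec, truth area fraction).
#'
#' @param slide A `synthetic_slide`.
#' @param dir Output directory (created if needed).
#' @param id Slide identifier used as the file stem.
#' @return Invisibly, the manifest path.
#' @export
write_slide <- function(slide, dir, id) {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(slide$image / 255, file.path(dir, paste0(id, ".png")))
  png::writePNG(slide$tissue_mask * 1, file.path(dir, paste0(id, "_tissue_mask.png")))
  png::writePNG(slide$dab_mask * 1, file.path(dir, paste0(id, "_dab_mask.png")))
  manifest <- list(
    id = id,
    seed = slide$spec$seed,
    grade = slide$spec$grade,
    image_size = slide$spec$image_size,
    tissue_fraction = slide$spec$tissue_fraction,
    noise_sd = slide$spec$noise_sd,
    truth_area_fraction = slide$truth_area_fraction
  )
  path <- file.path(dir, paste0(id, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slide written by [write_slide()]
#'
#' @param dir Directory containing the files.
#' @param id Slide identifier.
#' @return A list with `image` (h x w x 3, 0–255), `tissue_mask`,
#'   `dab_mask` (logical), and `manifest`.
#' @export
read_slide <- function(dir, id) {
  img <- png::readPNG(file.path(dir, paste0(id, ".png")))
  tm <- png::readPNG(file.path(dir, paste0(id, "_tissue_mask.png")))
  dm <- png::readPNG(file.path(dir, paste0(id, "_dab_mask.png")))
  list(
    image = round(img * 255),
    tissue_mask = tm > 0.5,
    dab_mask = dm > 0.5,
    manifest = jsonlite::read_json(
      file.path(dir, paste0(id, "_manifest.json")), simplifyVector = TRUE
    )
  )
}

#' Write a genes-by-columns matrix as TSV
#'
#' First column holds the gene ID, remaining columns the matrix columns.
#'
#' @param mat A numeric matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the identifier column (default `"gene_id"`).
#' @export
write_matrix_tsv <- function(mat, path, id_col = "gene_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV matrix written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return A numeric matrix with the first column as row names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a gene module as TSV
#'
#' Columns: `gene_id`, `z_target`, `rank_target`, `specificity`.
#'
#' @param module A `gene_module` tibble.
#' @param path Output path.
#' @export
write_module_tsv <- function(module, path) {
  utils::write.table(as.data.frame(module), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write or read a cohort/panel table as CSV
#'
#' @param x A data frame (cohort table or score-panel table).
#' @param path File path.
#' @return `read_table_csv()` returns a tibble.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Batch quantification results as CSV
#'
#' One row per slide: `slide_id`, `tissue_px`, `stained_px`,
#' `area_fraction`, `threshold`, `override_flag`.
#'
#' @param results A named list of `quant_result` objects (names are slide
#'   IDs).
#' @param path Output path.
#' @return Invisibly, the written tibble.
#' @export
write_quant_csv <- function(results, path) {
  rows <- lapply(names(results), function(id) {
    q <- results[[id]]
    tibble::tibble(
      slide_id = id,
      tissue_px = q$total_tissue_area,
      stained_px = q$total_stained_area,
      area_fraction = q$area_fraction,
      threshold = q$threshold_used %||% NA_real_,
      override_flag = q$manual_override
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(out)
}
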
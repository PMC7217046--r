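# Digital image analysis of DAB immunohistochemistry: ROI restriction,
# H-DAB color deconvolution, isodata ("Default") auto-thresholding on the
# DAB channel, and stained area-fraction computation.

#' Default H-DAB stain matrix
#'
#' Returns the Ruifrok–Johnston optical-density unit vectors for hematoxylin
#' and DAB, with the residual channel as their normalized cross product.
#' Columns are stains (`hematoxylin`, `dab`, `residual`), rows are RGB
#' optical-density components.
#'
#' @param hematoxylin,dab Numeric length-3 OD direction vectors; normalized
#'   internally to unit length.
#' @return A 3x3 numeric matrix of class `stain_matrix` with unit-norm
#'   columns.
#' @export
#' @examples
#' hdab_stain_matrix()
hdab_stain_matrix <- function(hematoxylin = c(0.650, 0.704, 0.286),
                              dab = c(0.269, 0.568, 0.872)) {
  stopifnot(length(hematoxylin) == 3, length(dab) == 3)
  h <- hematoxylin / sqrt(sum(hematoxylin^2))
  d <- dab / sqrt(sum(dab^2))
  res <- c(
    h[2] * d[3] - h[3] * d[2],
    h[3] * d[1] - h[1] * d[3],
    h[1] * d[2] - h[2] * d[1]
  )
  nres <- sqrt(sum(res^2))
  if (nres < 1e-8) stop("hematoxylin and DAB vectors are collinear")
  m <- cbind(hematoxylin = h, dab = d, residual = res / nres)
  rownames(m) <- c("R", "G", "B")
  class(m) <- c("stain_matrix", class(m))
  m
}

#' Read a stain matrix from a YAML file
#'
#' The file must contain `hematoxylin` and `dab` entries, each a length-3
#' RGB optical-density vector.
#'
#' @param path Path to a YAML file.
#' @return A `stain_matrix` (see [hdab_stain_matrix()]).
#' @export
read_stain_matrix <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$hematoxylin) || is.null(y$dab)) {
    stop("stain YAML must define 'hematoxylin' and 'dab' vectors")
  }
  hdab_stain_matrix(as.numeric(y$hematoxylin), as.numeric(y$dab))
}

validate_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an h x w x 3 array of 8-bit RGB values")
  }
  if (min(image) < 0 || max(image) > 255) {
    stop("image values must lie in [0, 255]")
  }
  invisible(image)
}

# Scanline rasterization of one polygon (even-odd rule). Polygon vertices are
# 0-based pixel coordinates (x, y); a pixel belongs to the polygon when its
# center (col - 0.5, row - 0.5 in 1-based terms) is inside. Vertices may lie
# off-canvas; the raster is clipped to the canvas.
rasterize_polygon <- function(poly, h, w) {
  if (!is.matrix(poly) || ncol(poly) != 2L || nrow(poly) < 3L) {
    stop("each polygon must be an n x 2 matrix (x, y) with n >= 3")
  }
  mask <- matrix(FALSE, h, w)
  px <- poly[, 1]
  py <- poly[, 2]
  n <- length(px)
  nxt <- c(2:n, 1L)
  for (row in seq_len(h)) {
    yc <- row - 0.5
    crosses <- (py <= yc & py[nxt] > yc) | (py[nxt] <= yc & py > yc)
    if (!any(crosses)) next
    i <- which(crosses)
    xi <- px[i] + (yc - py[i]) * (px[nxt][i] - px[i]) / (py[nxt][i] - py[i])
    xi <- sort(xi)
    for (k in seq(1L, length(xi) - 1L, by = 2L)) {
      # pixel centers c - 0.5 with xi[k] <= c - 0.5 < xi[k+1]
      c0 <- ceiling(xi[k] + 0.5 - 1e-9)
      c1 <- floor(xi[k + 1L] + 0.5 - 1e-9)
      if (c1 >= c0) {
        c0 <- max(1L, c0)
        c1 <- min(w, c1)
        if (c1 >= c0) mask[row, c0:c1] <- TRUE
      }
    }
  }
  mask
}

#' Restrict an image to operator-selected regions of interest
#'
#' Rasterizes one or more ROI polygons (pixel coordinates, even-odd fill,
#' pixel-center rule) and returns the tissue mask as their union. Pixels
#' outside every polygon are excluded from all downstream counting.
#'
#' @param image An h x w x 3 8-bit RGB array.
#' @param roi_polygons A list of n x 2 numeric matrices with columns (x, y)
#'   in 0-based pixel coordinates; polygons may extend beyond the canvas and
#'   are clipped.
#' @return A list with `image` (unchanged) and `tissue_mask` (h x w logical).
#' @export
apply_roi <- function(image, roi_polygons) {
  validate_rgb_image(image)
  if (!is.list(roi_polygons) || length(roi_polygons) == 0L) {
    stop("at least one ROI polygon is required")
  }
  h <- dim(image)[1]
  w <- dim(image)[2]
  mask <- matrix(FALSE, h, w)
  for (p in roi_polygons) {
    pm <- rasterize_polygon(p, h, w)
    if (!any(pm)) stop("ROI polygon rasterizes to zero area")
    mask <- mask | pm
  }
  list(image = image, tissue_mask = mask)
}

#' H-DAB color deconvolution
#'
#' Converts an 8-bit RGB brightfield image to per-pixel optical densities
#' (`OD = -log10(max(I, 1) / 255)` channel-wise) and inverts the stain
#' mixing matrix (Beer–Lambert model) to recover per-stain concentration
#' planes. Negative concentrations are clamped to zero.
#'
#' @param image An h x w x 3 8-bit RGB array.
#' @param stains A `stain_matrix`; defaults to [hdab_stain_matrix()].
#' @return A list of h x w numeric matrices: `hematoxylin`, `dab`,
#'   `residual`.
#' @export
deconvolve_hdab <- function(image, stains = hdab_stain_matrix()) {
  validate_rgb_image(image)
  if (!is.matrix(stains) || any(dim(stains) != c(3L, 3L))) {
    stop("stains must be a 3x3 stain matrix")
  }
  if (rcond(unclass(stains)) < 1e-10) stop("singular stain matrix")
  h <- dim(image)[1]
  w <- dim(image)[2]
  od <- -log10(pmax(image, 1) / 255)             # h x w x 3
  odm <- rbind(
    as.vector(od[, , 1]),
    as.vector(od[, , 2]),
    as.vector(od[, , 3])
  )                                              # 3 x (h*w)
  conc <- solve(unclass(stains), odm)
  conc[conc < 0] <- 0
  list(
    hematoxylin = matrix(conc[1, ], h, w),
    dab = matrix(conc[2, ], h, w),
    residual = matrix(conc[3, ], h, w)
  )
}

# Intermeans iteration on a 256-bin histogram (bin centers 0..255).
# Returns the converged threshold in bin units.
intermeans_fixed_point <- function(counts) {
  bins <- 0:255
  total <- sum(counts)
  t <- sum(bins * counts) / total
  for (iter in 1:256) {
    c0 <- floor(t)
    below <- counts[bins <= c0]
    above <- counts[bins > c0]
    if (sum(below) == 0 || sum(above) == 0) {
      # all mass on one side: nudge toward the occupied side
      occ <- range(bins[counts > 0])
      t <- mean(occ)
      c0 <- floor(t)
      below <- counts[bins <= c0]
      above <- counts[bins > c0]
      if (sum(below) == 0 || sum(above) == 0) {
        stop("degenerate histogram")
      }
    }
    mb <- sum(bins[bins <= c0] * below) / sum(below)
    ma <- sum(bins[bins > c0] * above) / sum(above)
    t_new <- (mb + ma) / 2
    if (floor(t_new) == c0) {
      return(t_new)
    }
    t <- t_new
  }
  t
}

#' Isodata ("Default") automatic threshold
#'
#' Builds a 256-bin histogram of the masked plane rescaled to 0–255 and
#' iterates the intermeans rule `t <- (mean_below(t) + mean_above(t)) / 2`
#' to its fixed point. This is the classic histogram-based "Default"
#' auto-threshold applied to the DAB concentration channel.
#'
#' @param plane An h x w numeric matrix (e.g., the DAB concentration plane).
#' @param mask Optional h x w logical mask restricting the histogram (the
#'   tissue mask); defaults to all pixels.
#' @return A list with `threshold` (on the original plane scale),
#'   `threshold_8bit` (bin units 0–255), and the rescaling `range`.
#' @export
isodata_threshold <- function(plane, mask = NULL) {
  stopifnot(is.matrix(plane))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(plane), ncol(plane))
  stopifnot(identical(dim(mask), dim(plane)))
  v <- plane[mask]
  if (length(v) < 2L) stop("mask must contain at least 2 pixels")
  mn <- min(v)
  mx <- max(v)
  if (mx - mn < 1e-6) stop("degenerate histogram: plane is constant within mask")
  v8 <- (v - mn) / (mx - mn) * 255
  counts <- tabulate(pmin(floor(v8), 255) + 1L, nbins = 256L)
  t8 <- intermeans_fixed_point(counts)
  list(
    threshold = mn + t8 / 255 * (mx - mn),
    threshold_8bit = t8,
    range = c(mn, mx)
  )
}

#' Quantify DAB-stained area fraction on one slide
#'
#' Composes the digital image analysis pipeline: ROI restriction, H-DAB
#' color deconvolution, isodata thresholding of the DAB channel within the
#' tissue mask, and pixel counting. The area fraction is
#' `100 * total_stained_area / total_tissue_area`. A pixel is stained when
#' its DAB concentration is strictly greater than the threshold.
#'
#' Stain-free slides are legitimate inputs: when the DAB plane is constant
#' within tolerance inside the tissue, or never exceeds the 8-bit
#' quantization floor (0.02 OD), the slide is reported with area fraction 0
#' and a warning rather than an error.
#'
#' @param image An h x w x 3 8-bit RGB array.
#' @param roi Either a list of ROI polygons (see [apply_roi()]) or an
#'   h x w logical tissue mask.
#' @param stains A `stain_matrix`.
#' @param override_threshold Optional manual threshold (original DAB
#'   concentration scale) replacing the automatic one; recorded via
#'   `manual_override`.
#' @param px_per_um Optional resolution (pixels per micrometer); when given,
#'   areas are also reported in square micrometers.
#' @return A list of class `quant_result`: `total_tissue_area`,
#'   `total_stained_area` (px), `area_fraction` (percent), `threshold_used`,
#'   `manual_override`, and optionally `tissue_area_um2`, `stained_area_um2`.
#' @export
quantify_slide <- function(image, roi, stains = hdab_stain_matrix(),
                           override_threshold = NULL, px_per_um = NULL) {
  validate_rgb_image(image)
  if (is.list(roi)) {
    tissue_mask <- apply_roi(image, roi)$tissue_mask
  } else if (is.logical(roi) && is.matrix(roi)) {
    stopifnot(identical(dim(roi), dim(image)[1:2]))
    tissue_mask <- roi
  } else {
    stop("roi must be a list of polygons or a logical tissue mask")
  }
  n_tissue <- sum(tissue_mask)
  if (n_tissue == 0L) stop("zero tissue area inside ROI")

  dab <- deconvolve_hdab(image, stains)$dab
  v <- dab[tissue_mask]

  manual <- !is.null(override_threshold)
  degenerate <- (max(v) - min(v) < 1e-6) || max(v) < 0.02
  if (manual) {
    thr <- override_threshold
  } else if (degenerate) {
    warning("DAB channel carries no signal above the quantization floor; area fraction set to 0")
    thr <- NA_real_
  } else {
    thr <- isodata_threshold(dab, tissue_mask)$threshold
  }
  n_stained <- if (is.na(thr %||% NA_real_)) 0L else sum(v > thr)

  out <- list(
    total_tissue_area = n_tissue,
    total_stained_area = n_stained,
    area_fraction = 100 * n_stained / n_tissue,
    threshold_used = thr,
    manual_override = manual
  )
  if (!is.null(px_per_um)) {
    out$tissue_area_um2 <- n_tissue / px_per_um^2
    out$stained_area_um2 <- n_stained / px_per_um^2
  }
  class(out) <- "quant_result"
  out
}

#' @export
print.quant_result <- function(x, ...) {
  cat("DAB quantification:\n")
  cat(sprintf("  tissue area:  %d px\n", x$total_tissue_area))
  cat(sprintf("  stained area: %d px\n", x$total_stained_area))
  cat(sprintf("  area fraction: %.3f%%\n", x$area_fraction))
  cat(sprintf(
    "  threshold: %s%s\n",
    ifelse(is.na(x$threshold_used), "none (no signal)",
           format(x$threshold_used, digits = 4)),
    if (x$manual_override) " (manual override)" else ""
  ))
  invisible(x)
}
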
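# Independent oracles used to check the implementation by a different route.

# Forward Beer-Lambert synthesis of one pixel from stain concentrations.
synth_pixel <- function(c_h, c_d, stains = hdab_stain_matrix()) {
  od <- c_h * unclass(stains)[, "hematoxylin"] + c_d * unclass(stains)[, "dab"]
  array(pmin(pmax(round(255 * 10^(-od)), 0), 255), dim = c(1, 1, 3))
}

# Render a full image from tissue/DAB masks through the forward model.
render_image <- function(tissue, dab, c_h = 0.6, c_d = 0.9,
                         stains = hdab_stain_matrix()) {
  h <- nrow(tissue); w <- ncol(tissue)
  img <- array(255, dim = c(h, w, 3))
  vh <- unclass(stains)[, "hematoxylin"]
  vd <- unclass(stains)[, "dab"]
  for (ch in 1:3) {
    od <- ifelse(tissue, c_h, 0) * vh[ch] + ifelse(dab, c_d, 0) * vd[ch]
    img[, , ch] <- pmin(pmax(round(255 * 10^(-od)), 0), 255)
  }
  img
}

# Exhaustive intermeans fixed-point scan over all integer cut points of a
# 256-bin histogram; returns every threshold value whose intermeans update
# maps its own bin onto itself.
oracle_intermeans_scan <- function(counts) {
  bins <- 0:255
  out <- numeric(0)
  for (cc in 0:254) {
    below <- bins <= cc
    if (sum(counts[below]) == 0 || sum(counts[!below]) == 0) next
    mb <- sum(bins[below] * counts[below]) / sum(counts[below])
    ma <- sum(bins[!below] * counts[!below]) / sum(counts[!below])
    m <- (mb + ma) / 2
    if (floor(m) == cc) out <- c(out, m)
  }
  out
}

# Point-in-polygon raster by the crossing-number rule, evaluated pixel by
# pixel (a different algorithm than the package's scanline fill).
oracle_polygon_mask <- function(poly, h, w) {
  mask <- matrix(FALSE, h, w)
  n <- nrow(poly)
  for (r in seq_len(h)) {
    y <- r - 0.5
    for (cl in seq_len(w)) {
      x <- cl - 0.5
      inside <- FALSE
      j <- n
      for (i in seq_len(n)) {
        if ((poly[i, 2] > y) != (poly[j, 2] > y)) {
          xint <- poly[i, 1] +
            (y - poly[i, 2]) * (poly[j, 1] - poly[i, 1]) / (poly[j, 2] - poly[i, 2])
          if (x < xint) inside <- !inside
        }
        j <- i
      }
      mask[r, cl] <- inside
    }
  }
  mask
}

# ICC(2,1) through stats::aov mean squares (independent of the closed-form
# computation in the package).
oracle_icc_aov <- function(a, b) {
  n <- length(a)
  d <- data.frame(
    y = c(a, b),
    subj = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  ms <- summary(stats::aov(y ~ subj + rater, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins (minimum-likelihood rule).
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  x_obs <- tab[1, 1]
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(x_obs, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Level-1 panel table encoding a fixed disposition (n_rich <= n_graded).
make_disposition_panels <- function(n_total, n_graded, n_rich) {
  graded <- seq_len(n_total) <= n_graded
  rich <- seq_len(n_total) <= n_rich
  tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n_total)),
    level = 1L,
    cd20 = ifelse(rich, 3L, 0L),
    cd3 = NA_integer_, cd68_lining = NA_integer_,
    cd68_sublining = NA_integer_,
    cd138 = 0L, krenn = NA_integer_,
    has_lining = graded, has_sublining = graded, artifact = FALSE
  )
}
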
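# Color deconvolution, isodata thresholding, ROI rasterization, and slide
# quantification, each checked against an independent route.

test_that("stain matrix has unit columns and rejects collinear vectors", {
  m <- hdab_stain_matrix()
  expect_equal(unname(sqrt(colSums(unclass(m)^2))), rep(1, 3), tolerance = 1e-6)
  expect_error(hdab_stain_matrix(dab = c(0.650, 0.704, 0.286)), "collinear")
})

test_that("deconvolution inverts the forward Beer-Lambert synthesis", {
  # white pixel carries zero optical density
  white <- array(255, dim = c(1, 1, 3))
  d <- deconvolve_hdab(white)
  expect_equal(d$hematoxylin[1, 1], 0)
  expect_equal(d$dab[1, 1], 0)

  # pure DAB at concentration 1
  d1 <- deconvolve_hdab(synth_pixel(0, 1))
  expect_lt(abs(d1$dab[1, 1] - 1), 1e-2)
  expect_lt(abs(d1$hematoxylin[1, 1]), 1e-2)

  # mixed stain recovered within 8-bit rounding
  d2 <- deconvolve_hdab(synth_pixel(0.5, 0.5))
  expect_lt(abs(d2$dab[1, 1] - 0.5), 1e-2)
  expect_lt(abs(d2$hematoxylin[1, 1] - 0.5), 1e-2)

  # property: mean absolute error below the quantization bound on a grid
  grid <- expand.grid(ch = seq(0, 1, by = 0.1), cd = seq(0, 1, by = 0.1))
  errs <- mapply(function(ch, cd) {
    d <- deconvolve_hdab(synth_pixel(ch, cd))
    abs(d$hematoxylin[1, 1] - ch) + abs(d$dab[1, 1] - cd)
  }, grid$ch, grid$cd)
  expect_lt(mean(errs) / 2, 0.02)

  expect_error(
    deconvolve_hdab(white, stains = matrix(1, 3, 3)),
    "singular"
  )
})

test_that("isodata threshold matches hand iteration and the exhaustive oracle", {
  # equal masses at 50 and 200: fixed point midway
  plane <- matrix(c(rep(50, 128), rep(200, 128)), 16, 16)
  thr <- isodata_threshold(plane)
  expect_equal(thr$threshold, 125)

  # bimodal 0 vs 200 separates the two masses
  plane2 <- matrix(c(rep(0, 200), rep(200, 56)), 16, 16)
  thr2 <- isodata_threshold(plane2)
  expect_gt(thr2$threshold, 0)
  expect_lt(thr2$threshold, 200)

  expect_error(isodata_threshold(matrix(3, 8, 8)), "degenerate histogram")

  # random histograms: converged threshold is an intermeans fixed point
  set.seed(101)
  for (i in 1:200) {
    n_modes <- sample(2:4, 1)
    v <- unlist(lapply(seq_len(n_modes), function(m) {
      stats::rnorm(sample(20:200, 1), mean = stats::runif(1, 0, 255),
                   sd = stats::runif(1, 1, 40))
    }))
    v <- pmin(pmax(v, 0), 255)
    if (max(v) - min(v) < 1) next
    plane <- matrix(v[1:(16 * floor(length(v) / 16) )], nrow = 16)
    thr <- isodata_threshold(plane)
    v8 <- (plane - min(plane)) / (max(plane) - min(plane)) * 255
    counts <- tabulate(pmin(floor(v8), 255) + 1L, nbins = 256L)
    fixed <- oracle_intermeans_scan(counts)
    expect_true(any(abs(fixed - thr$threshold_8bit) < 1e-9),
                info = sprintf("iteration %d", i))
  }
})

test_that("ROI rasterization agrees with a point-in-polygon oracle", {
  img <- array(255L, dim = c(40, 40, 3))

  # polygon covering the whole canvas selects every pixel
  full <- matrix(c(-1, -1, 41, -1, 41, 41, -1, 41), ncol = 2, byrow = TRUE)
  expect_equal(sum(apply_roi(img, list(full))$tissue_mask), 40 * 40)

  # two disjoint 10 x 10 rectangles give tissue area 200
  r1 <- matrix(c(0, 0, 10, 0, 10, 10, 0, 10), ncol = 2, byrow = TRUE)
  r2 <- matrix(c(20, 20, 30, 20, 30, 30, 20, 30), ncol = 2, byrow = TRUE)
  expect_equal(sum(apply_roi(img, list(r1, r2))$tissue_mask), 200)

  # irregular polygon partially off-canvas: clipped mask equals the oracle
  poly <- matrix(c(-5.3, 10.2, 25.7, -3.4, 44.1, 20.6, 18.9, 47.2),
                 ncol = 2, byrow = TRUE)
  got <- apply_roi(img, list(poly))$tissue_mask
  expect_identical(got, oracle_polygon_mask(poly, 40, 40))

  expect_error(apply_roi(img, list()), "at least one")
  degenerate <- matrix(c(5, 5, 5, 5, 5, 5), ncol = 2, byrow = TRUE)
  expect_error(apply_roi(img, list(degenerate)), "zero area")
})

test_that("quantification round-trips generator ground truth at zero noise", {
  for (grade in 1:4) {
    s <- generate_slide(slide_spec(grade = grade, seed = 20L + grade))
    q <- quantify_slide(s$image, s$tissue_mask)
    expect_lt(abs(q$area_fraction - s$truth_area_fraction), 0.5)
    # thresholded mask matches ground truth pixel for pixel inside tissue
    dab <- deconvolve_hdab(s$image)$dab
    recovered <- dab > q$threshold_used & s$tissue_mask
    expect_identical(recovered, s$dab_mask)
  }
})

test_that("stain-free slides quantify to zero with a warning", {
  s <- generate_slide(slide_spec(grade = 0, seed = 2L))
  expect_warning(q <- quantify_slide(s$image, s$tissue_mask), "no signal")
  expect_equal(q$area_fraction, 0)
  expect_false(q$manual_override)
})

test_that("area fraction is invariant to 90-degree rotation and translation", {
  s <- generate_slide(slide_spec(grade = 2, seed = 33L))
  q <- quantify_slide(s$image, s$tissue_mask)

  rot_img <- array(0L, dim = c(dim(s$image)[2], dim(s$image)[1], 3))
  for (ch in 1:3) rot_img[, , ch] <- t(s$image[, , ch])[, nrow(s$image):1]
  rot_mask <- t(s$tissue_mask)[, nrow(s$tissue_mask):1]
  q_rot <- quantify_slide(rot_img, rot_mask)
  expect_equal(q_rot$area_fraction, q$area_fraction)

  # translation: pad by 10 background pixels on two sides
  h <- dim(s$image)[1]; w <- dim(s$image)[2]
  pad_img <- array(255, dim = c(h + 10, w + 10, 3))
  pad_img[11:(h + 10), 11:(w + 10), ] <- s$image
  pad_mask <- matrix(FALSE, h + 10, w + 10)
  pad_mask[11:(h + 10), 11:(w + 10)] <- s$tissue_mask
  q_pad <- quantify_slide(pad_img, pad_mask)
  expect_equal(q_pad$area_fraction, q$area_fraction)
})

test_that("adding DAB-positive pixels never decreases the area fraction", {
  tissue <- matrix(FALSE, 60, 60)
  tissue[6:55, 6:55] <- TRUE
  dab <- matrix(FALSE, 60, 60)
  dab[20:26, 20:26] <- TRUE
  af <- function(dab_mask) {
    quantify_slide(render_image(tissue, dab_mask), tissue)$area_fraction
  }
  a1 <- af(dab)
  dab2 <- dab
  dab2[40:44, 40:44] <- TRUE
  expect_gte(af(dab2), a1)
  # manual override is recorded
  q <- quantify_slide(render_image(tissue, dab), tissue, override_threshold = 0.3)
  expect_true(q$manual_override)
  expect_equal(q$threshold_used, 0.3)
})

test_that("quantification errors on empty tissue", {
  img <- array(255L, dim = c(10, 10, 3))
  expect_error(quantify_slide(img, matrix(FALSE, 10, 10)), "zero tissue")
})
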
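# Generators: determinism, mask consistency, and convergence to the
# specified study conditions.

test_that("slide generator is deterministic and ground truth is self-consistent", {
  sp <- slide_spec(grade = 3, seed = 11L, noise_sd = 0.05)
  s1 <- generate_slide(sp)
  s2 <- generate_slide(sp)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$dab_mask, s2$dab_mask)

  s3 <- generate_slide(slide_spec(grade = 3, seed = 12L, noise_sd = 0.05))
  expect_false(identical(s1$image, s3$image))

  # dab mask inside tissue, truth equals the area-fraction definition
  expect_true(all(s1$tissue_mask[s1$dab_mask]))
  expect_equal(
    s1$truth_area_fraction,
    100 * sum(s1$dab_mask) / sum(s1$tissue_mask)
  )
  expect_identical(dim(s1$image)[1:2], dim(s1$tissue_mask))
})

test_that("grade 0 yields an empty DAB mask and zero truth area fraction", {
  s <- generate_slide(slide_spec(grade = 0, seed = 1L))
  expect_false(any(s$dab_mask))
  expect_identical(s$truth_area_fraction, 0)
})

test_that("aggregates that cannot fit inside the tissue raise an error", {
  plan <- tibble::tibble(n_cells = 10L, cell_radius = 5, spread = 500)
  expect_error(
    generate_slide(slide_spec(grade = 2, image_size = c(64L, 64L),
                              aggregate_plan = plan, seed = 1L)),
    "cannot fit inside tissue"
  )
})

test_that("atlas generator is deterministic and markers behave as planted", {
  sp <- atlas_spec(n_markers = 10L, noise_sd = 0.3, seed = 5L)
  a1 <- generate_atlas(sp)
  a2 <- generate_atlas(sp)
  expect_identical(a1$expr, a2$expr)
  expect_length(a1$markers, 10L)

  # markers sit log2(fold) above their own level in the other columns
  noiseless <- generate_atlas(atlas_spec(n_markers = 5L, marker_fold = 8,
                                         noise_sd = 0, seed = 2L))
  m <- noiseless$expr[noiseless$markers[1], ]
  tgt <- noiseless$target_cell
  expect_equal(unname(m[tgt] - m[names(m) != tgt][1]), log2(8))

  # with no planted markers and no noise, no gene meets the module criteria
  empty <- generate_atlas(atlas_spec(n_markers = 0L, noise_sd = 0, seed = 3L))
  expect_identical(nrow(derive_cell_module(empty)), 0L)
})

test_that("bulk mixtures are monotone in the B cell fraction and stay positive", {
  a <- generate_atlas(atlas_spec(n_markers = 10L, noise_sd = 0, seed = 4L))
  mx <- generate_bulk_mixtures(a, c(0, 0.5), noise_sd = 0, seed = 1L)
  markers <- a$markers
  expect_true(all(mx$expr[markers, 2] > mx$expr[markers, 1]))
  expect_true(all(is.finite(mx$expr)))        # log2 defined => linear scale > 0

  # fraction 0 everywhere leaves module genes at background level
  bg <- log2(rowMeans(2^a$expr[, colnames(a$expr) != a$target_cell]))
  mx0 <- generate_bulk_mixtures(a, rep(0, 3), noise_sd = 0, seed = 1L)
  expect_equal(unname(mx0$expr[, 1]), unname(bg), tolerance = 1e-12)

  expect_error(generate_bulk_mixtures(a, c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("paired readings are deterministic and collapse to truth at zero noise", {
  truth <- c(0.2, 1.5, 3.8)
  p0 <- generate_paired_readings(truth, noise_sd = 0, seed = 9L)
  expect_equal(p0$observer_a, truth)
  expect_equal(p0$observer_b, truth)
  p1 <- generate_paired_readings(truth, noise_sd = 0.2, seed = 9L)
  p2 <- generate_paired_readings(truth, noise_sd = 0.2, seed = 9L)
  expect_identical(p1, p2)
  expect_true(all(p1$observer_a >= 0))
})

test_that("cohort stratum means converge to the specified parameters", {
  eff <- table_effects("early")
  co <- generate_cohort(cohort_spec(
    n_patients = 10000L, prevalence_rich = 0.5,
    effects = eff, gradable_rate = 1, seed = 42L
  ))
  rich <- co[co$b_cell_status == "rich", ]
  poor <- co[co$b_cell_status == "poor", ]
  for (nm in c("das28", "esr", "global_health_vas")) {
    expect_equal(mean(rich[[nm]]), eff[[nm]]$rich[["mean"]],
                 tolerance = 0.02)
    expect_equal(mean(poor[[nm]]), eff[[nm]]$poor[["mean"]],
                 tolerance = 0.02)
  }
  expect_equal(mean(rich$acpa_pos), eff$acpa_pos$rich, tolerance = 0.02)
})

test_that("observed cohort prevalence falls inside the exact binomial CI", {
  co <- generate_cohort(cohort_spec(
    n_patients = 155L, prevalence_rich = 0.477, gradable_rate = 1, seed = 7L
  ))
  n_rich <- sum(co$b_cell_status == "rich")
  ci <- stats::binom.test(n_rich, nrow(co))$conf.int
  expect_true(ci[1] <= 0.477 && 0.477 <= ci[2])

  co0 <- generate_cohort(cohort_spec(
    n_patients = 50L, prevalence_rich = 0, gradable_rate = 1, seed = 1L
  ))
  expect_true(all(co0$b_cell_status == "poor"))
})
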
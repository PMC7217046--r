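# Agreement and association statistics against formula and enumeration
# oracles.

test_that("ICC(2,1) matches the ANOVA oracle and its identities", {
  set.seed(51)
  truth <- stats::runif(40, 0, 5)
  p <- paired_measurements(
    seq_len(40),
    truth + stats::rnorm(40, 0, 0.3),
    truth + 0.1 + stats::rnorm(40, 0, 0.3)
  )
  got <- icc_two_way(p)
  expect_equal(got$icc, oracle_icc_aov(p$observer_a, p$observer_b),
               tolerance = 1e-10)

  # duplicated observers: perfect agreement
  dup <- paired_measurements(1:5, c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(icc_two_way(dup)$icc, 1)

  # common affine rescaling of both observers leaves the ICC unchanged
  resc <- paired_measurements(p$sample_id, 3 * p$observer_a + 7,
                              3 * p$observer_b + 7)
  expect_equal(icc_two_way(resc)$icc, got$icc, tolerance = 1e-10)

  expect_error(icc_two_way(paired_measurements(1:3, rep(2, 3), rep(2, 3))),
               "zero total variance")
})

test_that("ICC is near zero when observers share no subject signal", {
  set.seed(52)
  p <- paired_measurements(1:200, stats::rnorm(200), stats::rnorm(200))
  expect_lt(abs(icc_two_way(p)$icc), 0.1)
})

test_that("ICC on simulated paired readings sits in the reported high-agreement regime", {
  set.seed(53)
  truth <- stats::runif(100, 0, 5)
  p <- generate_paired_readings(truth, noise_sd = 0.15, seed = 54L)
  got <- icc_two_way(p)$icc
  expect_equal(got, oracle_icc_aov(p$observer_a, p$observer_b), tolerance = 1e-10)
  expect_gte(got, 0.95)
})

test_that("Bland-Altman limits follow the mean ± 1.96 SD construction", {
  same <- paired_measurements(1:4, c(1, 2, 3, 4), c(1, 2, 3, 4))
  ba <- bland_altman(same)
  expect_equal(c(ba$ba_lower, ba$ba_mean_diff, ba$ba_upper), c(0, 0, 0))

  offset <- paired_measurements(1:4, c(1, 2, 3, 4), c(2, 3, 4, 5))
  ba2 <- bland_altman(offset)
  expect_equal(ba2$ba_mean_diff, -1)
  expect_equal(ba2$sd_diff, 0)

  tri <- paired_measurements(1:3, c(0, 1, 2), c(1, 1, 1))  # diffs -1, 0, 1
  ba3 <- bland_altman(tri)
  expect_equal(ba3$ba_mean_diff, 0)
  expect_equal(ba3$ba_upper, 1.96 * stats::sd(c(-1, 0, 1)))
  expect_true(ba3$ba_lower <= ba3$ba_mean_diff & ba3$ba_mean_diff <= ba3$ba_upper)
})

test_that("Bland-Altman limits cover about 95% of Gaussian differences", {
  set.seed(55)
  n <- 10000
  truth <- stats::runif(n, 0, 5)
  p <- paired_measurements(seq_len(n), truth + stats::rnorm(n, 0, 0.5),
                           truth + stats::rnorm(n, 0, 0.5))
  ba <- bland_altman(p)
  inside <- mean(ba$points$difference >= ba$ba_lower &
                 ba$points$difference <= ba$ba_upper)
  expect_equal(inside, 0.95, tolerance = 0.011)
})

test_that("Mann-Whitney matches exact enumeration on small samples", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1 / 20)           # 1 of choose(6,3) arrangements
  expect_identical(mw$method, "exact")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.9)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("chi-square equals the textbook 2x2 formula", {
  set.seed(56)
  for (i in 1:50) {
    tab <- matrix(sample(5:80, 4), 2)
    a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    manual <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    expect_equal(chi_square_2x2(tab)$statistic, manual, tolerance = 1e-10)
  }
  flat <- matrix(c(10, 10, 10, 10), 2)
  expect_equal(chi_square_2x2(flat)$statistic, 0)
  expect_equal(chi_square_2x2(flat)$p_value, 1)
  expect_error(chi_square_2x2(matrix(c(-1, 2, 3, 4), 2)), "nonnegative")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  diag5 <- matrix(c(5, 0, 0, 5), 2)
  expect_equal(fisher_exact_2x2(diag5)$p_value, oracle_fisher_p(diag5))
  set.seed(57)
  for (i in 1:40) {
    tab <- matrix(stats::rpois(4, 5), 2)
    if (sum(tab) == 0 || sum(tab) > 40) next
    expect_equal(fisher_exact_2x2(tab)$p_value, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("null Mann-Whitney p values give nominal type-I error", {
  set.seed(58)
  rej <- mean(replicate(400, {
    mann_whitney(stats::rnorm(30), stats::rnorm(30))$p_value < 0.05
  }))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("the clinical report picks tests by variable type and flags small strata", {
  co <- generate_cohort(cohort_spec(
    n_patients = 143L, prevalence_rich = 0.35,
    effects = table_effects("early"), gradable_rate = 1, seed = 61L
  ))
  rep_ <- cohort_report(co)
  expect_true(all(c("das28", "crp", "acpa_pos", "krenn_score") %in% rep_$variable))
  expect_identical(rep_$test[rep_$variable == "das28"], "Mann-Whitney")
  expect_true(rep_$test[rep_$variable == "acpa_pos"] %in%
                c("chi-square", "Fisher's exact"))
  expect_true(all(rep_$p_value >= 0 & rep_$p_value <= 1, na.rm = TRUE))
  # the synovitis score separates strata decisively in this design
  expect_lt(rep_$p_value[rep_$variable == "krenn_score"], 1e-4)

  # empty rich stratum: summaries survive, tests are skipped
  co_poor <- generate_cohort(cohort_spec(
    n_patients = 30L, prevalence_rich = 0,
    effects = table_effects("early"), gradable_rate = 1, seed = 62L
  ))
  rep0 <- cohort_report(co_poor)
  expect_true(all(is.na(rep0$p_value)))
  expect_true(all(grepl("skipped", rep0$flag)))
})

test_that("a larger standardized effect is detected more often", {
  # DAS28 (5.6 vs 6.1, SD ~1.3) versus CRP (17.5 vs 21.5, SD ~30) at the
  # early-RA cohort size: the DAS28 row must reject more often
  set.seed(63)
  hits <- replicate(120, {
    co <- generate_cohort(cohort_spec(
      n_patients = 143L, prevalence_rich = 0.35,
      effects = table_effects("early"), gradable_rate = 1,
      seed = sample.int(2^30, 1)
    ))
    poor <- co[co$b_cell_status == "poor", ]
    rich <- co[co$b_cell_status == "rich", ]
    c(
      das28 = mann_whitney(poor$das28, rich$das28)$p_value < 0.05,
      crp = mann_whitney(poor$crp, rich$crp)$p_value < 0.05
    )
  })
  expect_gt(mean(hits["das28", ]), mean(hits["crp", ]))
  expect_gt(mean(hits["das28", ]), 0.5)      # majority rejection for DAS28
})
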
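test_that("Lin's CCC matches hand-computed oracle values", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  expect_equal(lin_ccc(x, x), 1)
  # x = (1,2,3), y = (2,3,4): 2*(2/3) / ((2/3) + (2/3) + 1) = 4/7
  expect_equal(lin_ccc(1:3, 2:4), 4 / 7, tolerance = 1e-12)
  # perfect negative agreement around a common mean
  expect_equal(lin_ccc(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_error(lin_ccc(1:4, 1:5), "pairing")
  expect_warning(expect_true(is.nan(lin_ccc(rep(2, 5), rep(2, 5)))), "undefined")
})

test_that("CCC is symmetric and attenuated relative to Pearson", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(3:20, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 3)) + runif(1, -2, 2)
    y <- 0.5 * x + rnorm(n, sd = runif(1, 0.2, 2)) + runif(1, -2, 2)
    ccc <- lin_ccc(x, y)
    expect_equal(ccc, lin_ccc(y, x), tolerance = 1e-12)
    expect_lte(abs(ccc), abs(stats::cor(x, y)) + 1e-12)
    expect_lte(abs(ccc), 1 + 1e-12)
  }
})

test_that("CCC heuristic bands reproduce the published labels", {
  expect_equal(ccc_band(0.996), "almost complete")
  expect_equal(ccc_band(0.527), "moderate")
  expect_equal(ccc_band(0.108), "weak")
  expect_equal(ccc_band(0.05), "none")
  expect_equal(ccc_band(0.734), "strong")
  expect_error(ccc_band(1.2), "\\[-1, 1\\]")
})

test_that("coefficient of variation matches the printed benchmark arithmetic", {
  expect_equal(round(coefficient_of_variation(104.312, 5.009), 3), 4.802)
  expect_equal(coefficient_of_variation(10, 0), 0)
  expect_equal(coefficient_of_variation(3 * 10, 3 * 2),
               coefficient_of_variation(10, 2))
  expect_error(coefficient_of_variation(0, 1), "zero mean")
})

test_that("Bland-Altman statistics follow their definitions", {
  x <- c(1.1, 2.3, 3.1, 4.0)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  expect_equal(ba0$n_outside, 0)

  # differences (+1, -1): mean 0, sd sqrt(2), LoA +/- 2.772
  ba <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_upper, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(round(ba$loa_upper, 3), 2.772)
  expect_error(bland_altman(1:3, 1:4), "pairing")
})

test_that("assumption checks behave as calibrated hypothesis tests", {
  set.seed(11)
  # normal n=50: Shapiro-Wilk retains normality in at least 90% of replicates
  p_norm <- replicate(100, stats::shapiro.test(rnorm(50))$p.value)
  expect_gte(mean(p_norm > 0.05), 0.90)
  # the package's own wrapper agrees with shapiro.test
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.2)
  ac <- assumption_checks(x, y)
  expect_equal(ac$shapiro_x, stats::shapiro.test(x)$p.value)
  expect_true(ac$breusch_pagan >= 0 && ac$breusch_pagan <= 1)

  # exponential n=200: normality rejected in at least 95% of replicates
  p_exp <- replicate(100, {
    x <- rexp(200); y <- rexp(200)
    assumption_checks(x, y)$shapiro_x
  })
  expect_gte(mean(p_exp < 0.05), 0.95)

  # homoscedastic pairs: Breusch-Pagan rejection near the nominal 5%
  rej <- replicate(400, {
    x <- rnorm(50, 10); y <- x + rnorm(50, 0, 0.5)
    assumption_checks(x, y)$breusch_pagan < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
  expect_error(assumption_checks(1:2, 1:2), "insufficient")
})

make_sets <- function(values, plane, device, jitter = 0) {
  lapply(seq_len(nrow(values)), function(i) {
    m <- unlist(values[i, plane_metrics(plane)])
    if (jitter > 0) m <- m + rnorm(length(m), 0, jitter)
    gait_metric_set(plane, device, m, subject = sprintf("S%02d", i))
  })
}

random_cohort_values <- function(n, plane) {
  base <- data.frame(
    cadence = rnorm(n, 104, 5), double_support = rnorm(n, 0.29, 0.02),
    gait_symmetry = rnorm(n, 97, 2.8), gait_variability = rnorm(n, 3, 1.5),
    stance_time = rnorm(n, 0.72, 0.04), step_length = rnorm(n, 62, 3.3),
    step_time = rnorm(n, 0.576, 0.03), step_width = rnorm(n, 10.6, 2.7)
  )
  base[, plane_metrics(plane)]
}

test_that("agreement table pairs subjects and has the published row structure", {
  set.seed(21)
  vals <- random_cohort_values(16, "sagittal")
  ref <- make_sets(vals, "sagittal", "VIC")
  tab <- agreement_table(ref, ref, "sagittal")
  expect_equal(nrow(tab), 7)
  expect_true(all(tab$ccc == 1))
  expect_true(all(tab$mean_diff == 0))
  # CV columns recompute from the table's own mean and SD
  expect_equal(tab$cv_ref, 100 * tab$sd_ref / abs(tab$mean_ref))

  valsf <- random_cohort_values(16, "frontal")
  tabf <- agreement_table(make_sets(valsf, "frontal", "VIC"),
                          make_sets(valsf, "frontal", "OV"), "frontal")
  expect_equal(nrow(tabf), 5)

  # LoA invariants
  test <- make_sets(vals, "sagittal", "OV", jitter = 0.3)
  tab2 <- agreement_table(ref, test, "sagittal")
  expect_equal(tab2$loa_upper, tab2$mean_diff + 1.96 * tab2$sd_diff)
  expect_equal(tab2$loa_lower, tab2$mean_diff - 1.96 * tab2$sd_diff)
  expect_true(all(abs(tab2$ccc) <= 1))

  bad <- test
  bad[[1]]$subject <- "S99"
  expect_error(agreement_table(ref, bad, "sagittal"), "S99")
  expect_error(agreement_table(ref[1:2], test[1:2], "sagittal"), "at least 3")
})

test_that("a high-variance cohort with small inter-device noise gives CCC > 0.9 for cadence", {
  set.seed(5)
  vals <- random_cohort_values(16, "sagittal")
  ref <- make_sets(vals, "sagittal", "VIC")
  test <- make_sets(vals, "sagittal", "OV", jitter = 0.2)
  tab <- agreement_table(ref, test, "sagittal")
  expect_gt(tab$ccc[tab$metric == "cadence"], 0.9)
})

test_that("shrinking between-subject variance attenuates the CCC at fixed device noise", {
  set.seed(31)
  mean_ccc <- vapply(c(2, 1, 0.5, 0.25), function(sigma_b) {
    mean(replicate(40, {
      truth <- rnorm(16, 100, sigma_b)
      lin_ccc(truth + rnorm(16, 0, 0.5), truth + rnorm(16, 0, 0.5))
    }))
  }, numeric(1))
  expect_true(all(diff(mean_ccc) < 0))
})
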
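const_series <- function(plane, channels, n = 400, fps = 100) {
  coords <- as.data.frame(lapply(channels, rep, n), check.names = FALSE)
  landmark_series((0:(n - 1)) / fps, coords, "X", plane, fps, "meters")
}

test_that("step table reproduces hand-computed step quantities", {
  # leading toe at +0.31 m, trailing at -0.31 m at every IC -> step length 0.62
  ev <- data.frame(
    event_type = rep(c("IC", "TO"), 10),
    side = rep(c("left", "right"), each = 2, length.out = 20),
    time_s = c(t(cbind(seq(1, by = 0.576, length.out = 10),
                       seq(1, by = 0.576, length.out = 10) + 0.723)))
  )
  s <- const_series("sagittal", list("toe.left.ap" = 0.31, "toe.right.ap" = -0.31,
                                     "heel.left.ap" = 0.06, "heel.right.ap" = -0.56))
  st <- build_step_table(ev, s)
  expect_s3_class(st, "step_table")
  expect_equal(unique(stats::na.omit(st$step_length)), 0.62)
  # stance 0.723 s each side, step time 0.576 s -> double support 0.294 s
  expect_equal(unique(round(stats::na.omit(st$double_support), 10)),
               2 * 0.723 - 2 * 0.576)
  # stance_pct = 100 * stance / stride
  expect_equal(unique(round(stats::na.omit(st$stance_pct), 6)),
               round(100 * 0.723 / 1.152, 6))

  # frontal: heels at +/- 0.053 m -> step width 0.106 m
  sf <- const_series("frontal", list("heel.left.ml" = 0.053, "heel.right.ml" = -0.053))
  stf <- build_step_table(ev, sf)
  expect_equal(unique(stf$step_width), 0.106)
})

test_that("alternation violations raise a sequence error naming the offending pair", {
  ev <- data.frame(event_type = "IC",
                   side = c("left", "right", "left", "left", "right", "left"),
                   time_s = 1:6)
  expect_error(build_step_table(ev, NULL), "consecutive left-side")
})

test_that("cadence follows its closed forms", {
  expect_equal(cadence(seq(0, by = 0.6, length.out = 11)), 100)
  expect_equal(cadence(seq(0, by = 0.576, length.out = 53)), 60 / 0.576)
  expect_equal(round(cadence(seq(0, by = 0.576, length.out = 53)), 2), 104.17)
  expect_equal(cadence(c(0, 1)), 60)
  expect_error(cadence(c(0, 1), duration = 0), "duration")
  expect_error(cadence(1), "at least two")
})

test_that("gait variability is the mean per-side CV of step length", {
  expect_equal(gait_variability(rep(0.62, 5), rep(0.62, 5)), 0)
  # lengths (60, 62, 64) cm: sample SD 2 -> 100 * 2 / 62
  expect_equal(gait_variability(c(60, 62, 64), c(60, 62, 64)), 100 * 2 / 62)
  expect_equal(round(gait_variability(c(60, 62, 64), c(60, 62, 64)), 2), 3.23)
  # scale invariance
  expect_equal(gait_variability(2 * c(60, 62, 64), 2 * c(60, 62, 64)),
               gait_variability(c(60, 62, 64), c(60, 62, 64)))
  expect_error(gait_variability(c(0.62), c(0.6, 0.64)), "at least 2")
})

test_that("gait symmetry matches the index definition and its properties", {
  expect_equal(gait_symmetry(0.62, 0.62), 100)
  expect_equal(gait_symmetry(0.62, 0.60), 100 * (1 - 0.04 / 1.22))
  expect_equal(round(gait_symmetry(0.62, 0.60), 2), 96.72)
  expect_equal(gait_symmetry(0.62, 0.60), gait_symmetry(0.60, 0.62))
  expect_error(gait_symmetry(-1, 1), "positive")
  # bounded by 100, attained only at equality
  set.seed(1)
  for (i in 1:50) {
    xr <- runif(1, 0.3, 1); xl <- runif(1, 0.3, 1)
    s <- gait_symmetry(xr, xl)
    expect_lte(s, 100)
    if (abs(xr - xl) > 1e-12) expect_lt(s, 100)
  }
})

test_that("summaries carry exactly 7 sagittal and 5 frontal metrics", {
  sim <- simulate_subject(small_config(seed = 2))
  an_s <- run_analyze(sim$series$VIC_sagittal)
  an_f <- run_analyze(sim$series$VIC_frontal)
  expect_equal(length(an_s$metrics$metrics), 7)
  expect_equal(length(an_f$metrics$metrics), 5)
  expect_named(an_s$metrics$metrics,
               c("cadence", "double_support", "gait_symmetry",
                 "gait_variability", "stance_time", "step_length", "step_time"))
  expect_named(an_f$metrics$metrics,
               c("cadence", "gait_symmetry", "stance_time", "step_time",
                 "step_width"))
  # cadence x mean step time ~ 60 within 2% for contiguous steps
  expect_equal(an_s$metrics$metrics[["cadence"]] * an_s$metrics$metrics[["step_time"]],
               60, tolerance = 0.02)
  # requesting the wrong plane from a step table is refused
  expect_error(gait_summary(an_s$step_table, "frontal"), "plane error")
})

test_that("summarizing exact ground-truth events reproduces true_metrics", {
  specs <- list(device_spec("REF", fps = 100, units = "meters",
                            plane = "sagittal", noise_sd = 0))
  sim <- simulate_subject(small_config(seed = 4, device_specs = specs))
  gt_ev <- sim$truth$events
  st <- build_step_table(gt_ev, sim$series$REF_sagittal)
  got <- gait_summary(st, "sagittal", device = "REF")
  want <- true_metrics(sim$truth, "sagittal")
  expect_equal(got$metrics, want$metrics, tolerance = 1e-6)
})

test_that("the pipeline recovers true parameters through noisy 30 fps video", {
  # scaled-down sweep of the module-level recovery contract; the 16-subject
  # acceptance study repeats it at full protocol length
  errs <- list(cadence = c(), step_time = c(), step_length = c())
  for (seed in 1:10) {
    sim <- simulate_subject(small_config(seed = 2000 + seed, n_strides = 8,
                                         device_specs = pair_specs()))
    an <- run_analyze(sim$series$OV_sagittal)
    tm <- true_metrics(sim$truth, "sagittal")
    d <- an$metrics$metrics - tm$metrics
    errs$cadence <- c(errs$cadence, d[["cadence"]])
    errs$step_time <- c(errs$step_time, d[["step_time"]])
    errs$step_length <- c(errs$step_length, d[["step_length"]])
  }
  expect_true(all(abs(errs$cadence) <= 1))     # steps/min
  expect_true(all(abs(errs$step_time) <= 0.010)) # s
  expect_true(all(abs(errs$step_length) <= 1))   # cm
})
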
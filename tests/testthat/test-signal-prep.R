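# Coefficients and a filtered trace for a 2nd-order 3 Hz low-pass at 30 fps
# were computed with an independent reference implementation
# (scipy.signal.butter / filtfilt, default odd padding) and frozen here.
scipy_b <- c(0.0674552738890719, 0.1349105477781438, 0.0674552738890719)
scipy_a <- c(1.0, -1.1429805025399011, 0.41280159809618877)
scipy_x <- c(0.030471707975443, 0.10391328019371, 0.481781762656446,
  0.681841723931595, 0.54804130661201, 0.735807453098207, 0.963840556611882,
  0.962897636133915, 0.992841779617844, 0.865752123537796, 0.953965201270722,
  0.820924019020289, 0.594388322048595, 0.519460763772603, 0.254662625042964,
  -0.085929246288323, -0.171036612409509, -0.5026249031587, -0.499940222161746,
  -0.748137416576019, -0.884511640138964, -1.019149470735548, -0.87226776150087,
  -1.009974843575154, -0.993889298511464, -0.901238758833262, -0.689913906922059,
  -0.551240845856065, -0.365463381916201, -0.164829590516971, 0.214164760087045,
  0.167270189179297, 0.355512370168646, 0.506407979467685, 0.804742767734944,
  0.978922633056527, 0.939661770529666, 0.91050624767202, 0.912073773799149,
  1.016115795077624)
scipy_y <- c(0.029025764589541, 0.21417621549679, 0.390431496290195,
  0.548244492557807, 0.683721201185111, 0.798003277434172, 0.888203388303552,
  0.946272404422335, 0.965974896399345, 0.945178641217092, 0.882389050803684,
  0.77587620929017, 0.627098943534782, 0.442236767366556, 0.231785632093705,
  0.010395819830053, -0.206572600413854, -0.407793227352869, -0.586861704646896,
  -0.739426654224019, -0.859819255364301, -0.942094662411005, -0.983573576455502,
  -0.98326300529052, -0.938248065573352, -0.846388690335151, -0.711421689968307,
  -0.542666937358366, -0.351608178597171, -0.150729846183452, 0.047641948253387,
  0.236180876573793, 0.414187403967628, 0.580182391206678, 0.725144795786415,
  0.836868037101806, 0.911176165640107, 0.956872540101833, 0.988961683640803,
  1.018743537552357)

test_that("Butterworth design and zero-phase filtering match the reference implementation", {
  cf <- butter_lowpass(3, 30, 2)
  expect_equal(cf$b, scipy_b, tolerance = 1e-12)
  expect_equal(cf$a, scipy_a, tolerance = 1e-12)
  expect_equal(filtfilt_zerophase(cf$b, cf$a, scipy_x), scipy_y, tolerance = 1e-10)
})

test_that("filter has unit DC gain and the analytic two-pass frequency response", {
  cf <- butter_lowpass(3, 30, 2)
  expect_equal(filtfilt_zerophase(cf$b, cf$a, rep(3.7, 60)), rep(3.7, 60))

  fs <- 30
  t <- (0:1799) / fs
  for (f in c(0.5, 10)) {
    y <- filtfilt_zerophase(cf$b, cf$a, sin(2 * pi * f * t))
    expect_equal(fitted_amplitude(y, f, fs), butter_gain(f, 3, fs),
                 tolerance = 1e-3)
  }
  # in-band passage and stop-band attenuation at the spec'd levels
  expect_gte(butter_gain(0.5, 3, fs), 0.999)
  expect_lte(butter_gain(10, 3, fs), 0.01)
})

test_that("filtering is zero-phase and idempotent well inside the gait band", {
  cf <- butter_lowpass(3, 30, 2)
  t <- (0:899) / 30
  x <- sin(2 * pi * 0.8 * t) + 0.4 * cos(2 * pi * 0.5 * t)
  y1 <- filtfilt_zerophase(cf$b, cf$a, x)
  # cross-correlation peak lag between input and output is 0
  cc <- stats::ccf(y1, x, lag.max = 10, plot = FALSE)
  expect_equal(as.vector(cc$lag)[which.max(cc$acf)], 0)
  # refiltering a signal at/below the gait fundamental changes it by
  # < 0.5% RMS (at 0.8 Hz the two-pass gain is 0.99974; the rolloff is too
  # gentle for this to hold right up to 1.5 Hz, where the gain is 0.94)
  y2 <- filtfilt_zerophase(cf$b, cf$a, y1)
  expect_lt(sqrt(mean((y2 - y1)^2)) / sqrt(mean(y1^2)), 0.005)
})

test_that("filter rejects bad cutoffs and too-short series", {
  sim <- simulate_subject(small_config(seed = 1))
  expect_error(butterworth_lowpass(sim$series$OV_sagittal, cutoff = 15), "Nyquist")
  cf <- butter_lowpass(3, 30, 2)
  expect_error(filtfilt_zerophase(cf$b, cf$a, rnorm(8)), "too short")
})

test_that("pixel-to-meter conversion is a pure rescaling with unit bookkeeping", {
  sim <- simulate_subject(small_config(seed = 6))
  px <- sim$series$OV_sagittal
  m <- pixels_to_meters(px, 1.74, 870) # 0.002 m per px
  expect_equal(m$units, "meters")
  expect_equal(m$coords$`toe.left.ap`, px$coords$`toe.left.ap` * 0.002,
               tolerance = 1e-12)
  # a 100 px displacement becomes 0.200 m
  expect_equal(diff(c(0, 100)) * 1.74 / 870, 0.2)
  # round trip restores the original values
  back <- m
  back$units <- "pixels"
  back <- pixels_to_meters(back, 1.74, 1 / 870 * 1.74^2) # inverse scale
  expect_equal(back$coords$`heel.right.vert`, px$coords$`heel.right.vert`,
               tolerance = 1e-9)
  # metric series are refused
  expect_error(pixels_to_meters(sim$series$VIC_sagittal, 1.74, 870), "pixel")
})

test_that("conversion commutes with filtering (both linear)", {
  sim <- simulate_subject(small_config(seed = 8))
  px <- sim$series$OV_sagittal
  a <- pixels_to_meters(butterworth_lowpass(px), 1.74, 870)
  b <- butterworth_lowpass(pixels_to_meters(px, 1.74, 870))
  expect_equal(a$coords, b$coords, tolerance = 1e-10)
})

test_that("reference span estimation recovers the pixel height robustly", {
  # synthetic standing pose of known pixel height
  n <- 200
  standing <- function(noise_sd = 0) {
    set.seed(42)
    coords <- data.frame(
      "head.center.vert" = 870 + rnorm(n, 0, noise_sd),
      "heel.left.vert" = rnorm(n, 0, noise_sd),
      "heel.right.vert" = rnorm(n, 0, noise_sd),
      check.names = FALSE
    )
    landmark_series((0:(n - 1)) / 30, coords, "OV", "sagittal", 30, "pixels")
  }
  expect_equal(estimate_reference_span(standing(0)), 870)
  # with 2 px noise, taking the lower of two noisy heels biases the span by
  # E[min(N1, N2)] = sigma / sqrt(pi) ~ 1.13 px; the median estimate sits at
  # that closed-form value and within 2 px of the truth
  est <- estimate_reference_span(standing(2))
  expect_lt(abs(est - 870), 2)
  expect_lt(abs(est - (870 + 2 / sqrt(pi))), 0.6)
  # a single-frame window equals the instantaneous span
  s <- standing(2)
  expect_equal(estimate_reference_span(s, window = 1),
               s$coords[[1]][1] - min(s$coords[[2]][1], s$coords[[3]][1]))
  s$coords$`head.center.vert` <- NULL
  expect_error(estimate_reference_span(s), "missing landmark")
})

test_that("event-based synchronization recovers clock offsets", {
  ev <- data.frame(event_type = rep(c("IC", "TO"), each = 26),
                   side = rep(c("left", "right"), 26),
                   time_s = c(seq(1, by = 0.576, length.out = 26),
                              seq(1.33, by = 0.576, length.out = 26)))
  expect_equal(sync_by_events(ev, ev), 0)
  expect_equal(sync_by_events(ev, shift_events(ev, 0.25)), -0.25)
  # +/- 10 ms uniform jitter: offset recovered within 5 ms
  set.seed(99)
  jit <- ev
  jit$time_s <- jit$time_s + 0.25 + runif(nrow(ev), -0.01, 0.01)
  expect_lt(abs(sync_by_events(ev, jit) + 0.25), 0.005)
  to_only <- ev[ev$event_type == "TO", ]
  to_only$event_type <- "XX"
  expect_error(sync_by_events(ev[ev$event_type == "IC", ], to_only),
               "cannot synchronize")
})

test_that("short gaps are interpolated and long gaps reject the trial", {
  sim <- simulate_subject(small_config(seed = 9))
  s <- sim$series$VIC_sagittal
  v <- s$coords$`toe.left.ap`
  s$coords$`toe.left.ap`[100:103] <- NA
  filled <- fill_gaps(s)
  expect_false(anyNA(filled$coords))
  expect_equal(filled$coords$`toe.left.ap`[c(99, 104)], v[c(99, 104)])
  s$coords$`toe.left.ap`[200:210] <- NA
  expect_error(fill_gaps(s), "gap longer")
})
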
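#' Capture-device specification for the gait simulator
#'
#' Describes one observation stream of the shared continuous gait model: its
#' sampling rate, output units, anatomical plane and additive landmark noise.
#' The defaults in [simulation_config()] emulate the two systems of a
#' treadmill validation study: a 100 fps metric marker-based reference and a
#' 30 fps full-HD video stream reporting pixel coordinates.
#'
#' @param name device label.
#' @param fps sampling rate in Hz.
#' @param units `"meters"` or `"pixels"`.
#' @param plane `"sagittal"` or `"frontal"`.
#' @param noise_sd additive i.i.d. Gaussian noise SD per coordinate per frame,
#'   in the device's output units.
#' @param pixel_scale pixels per meter (required when `units = "pixels"`).
#' @param dropout_rate probability that a sample is missing (default 0).
#' @return An object of class `device_spec`.
#' @export
device_spec <- function(name, fps, units = c("meters", "pixels"),
                        plane = c("sagittal", "frontal"), noise_sd = 0,
                        pixel_scale = NULL, dropout_rate = 0) {
  units <- match.arg(units)
  plane <- match.arg(plane)
  if (fps <= 0) stop("device fps must be positive", call. = FALSE)
  if (noise_sd < 0) stop("device noise_sd must be >= 0", call. = FALSE)
  if (units == "pixels" && (is.null(pixel_scale) || pixel_scale <= 0)) {
    stop("pixel devices need a positive pixel_scale (px per meter)", call. = FALSE)
  }
  structure(list(name = name, fps = fps, units = units, plane = plane,
                 noise_sd = noise_sd, pixel_scale = pixel_scale,
                 dropout_rate = dropout_rate),
            class = "device_spec")
}

#' Simulation configuration for synthetic treadmill gait
#'
#' The defaults state the conditions of the emulated protocol: walking at
#' 4 km/h for about one minute, 26 strides per side (52 consecutive steps),
#' mean step time 0.576 s, stance time 0.723 s (stance fraction
#' 0.723 / 1.152 of the stride), step length 62 cm, step width 10.6 cm, and a
#' 1.74 m subject. Step-to-step variability SDs are not reported by typical
#' summary tables; the defaults (12 ms step time, 1.9 cm step length, 1.2 cm
#' step width) give a within-subject step-length coefficient of variation of
#' about 3%, the scale reported for healthy treadmill walking.
#'
#' @param subject_height body height, m.
#' @param belt_speed treadmill belt speed, m/s (default 4 km/h).
#' @param n_strides strides per side (initial contacts per leg).
#' @param mean_step_time_left,mean_step_time_right mean step time per side, s.
#' @param step_time_sd step-to-step SD of step time, s.
#' @param mean_step_length_left,mean_step_length_right mean step length per
#'   side, m.
#' @param step_length_sd step-to-step SD of step length, m.
#' @param stance_fraction stance time as a fraction of the stride; must exceed
#'   0.5 (walking implies double support).
#' @param step_width_mean,step_width_sd mediolateral heel-to-heel distance at
#'   initial contact, m.
#' @param swing_peak_height peak heel height during swing, m.
#' @param swing_lift_frac,swing_descent_frac fraction of the swing spent in
#'   the vertical lift / final descent ramps. Short ramps concentrate the
#'   vertical foot velocity extrema within one video frame of the true
#'   initial-contact and toe-off instants, which is the property kinematic
#'   event detectors exploit in real gait.
#' @param foot_length anteroposterior heel-to-toe distance, m.
#' @param device_specs list of [device_spec()] objects (default: 100 fps
#'   metric reference and 30 fps pixel test stream, both planes each).
#' @param seed integer RNG seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(subject_height = 1.74,
                              belt_speed = 4 / 3.6,
                              n_strides = 26L,
                              mean_step_time_left = 0.576,
                              mean_step_time_right = 0.576,
                              step_time_sd = 0.012,
                              mean_step_length_left = 0.62,
                              mean_step_length_right = 0.62,
                              step_length_sd = 0.019,
                              stance_fraction = 0.723 / (2 * 0.576),
                              step_width_mean = 0.106,
                              step_width_sd = 0.012,
                              swing_peak_height = 0.05,
                              swing_lift_frac = 0.10,
                              swing_descent_frac = 0.10,
                              foot_length = 0.25,
                              device_specs = default_device_specs(),
                              seed = 1L) {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @export
default_device_specs <- function() {
  list(
    device_spec("VIC", fps = 100, units = "meters", plane = "sagittal", noise_sd = 5e-4),
    device_spec("VIC", fps = 100, units = "meters", plane = "frontal", noise_sd = 5e-4),
    device_spec("OV", fps = 30, units = "pixels", plane = "sagittal", noise_sd = 2, pixel_scale = 500),
    device_spec("OV", fps = 30, units = "pixels", plane = "frontal", noise_sd = 2, pixel_scale = 500)
  )
}

validate_simulation_config <- function(cfg) {
  fail <- function(msg) stop("invalid simulation config: ", msg, call. = FALSE)
  if (cfg$stance_fraction <= 0.5) {
    fail("stance_fraction must exceed 0.5 (walking implies double support)")
  }
  if (cfg$stance_fraction >= 1) fail("stance_fraction must be below 1")
  for (nm in c("step_time_sd", "step_length_sd", "step_width_sd")) {
    if (cfg[[nm]] < 0) fail(sprintf("%s must be >= 0", nm))
  }
  for (nm in c("subject_height", "belt_speed", "mean_step_time_left",
               "mean_step_time_right", "mean_step_length_left",
               "mean_step_length_right", "step_width_mean", "foot_length")) {
    if (cfg[[nm]] <= 0) fail(sprintf("%s must be positive", nm))
  }
  if (cfg$n_strides < 3) fail("n_strides must be at least 3")
  if (cfg$swing_lift_frac <= 0 || cfg$swing_descent_frac <= 0 ||
      cfg$swing_lift_frac + cfg$swing_descent_frac >= 1) {
    fail("swing ramp fractions must be positive and sum to less than 1")
  }
  if (!length(cfg$device_specs) ||
      !all(vapply(cfg$device_specs, inherits, logical(1), "device_spec"))) {
    fail("device_specs must be a non-empty list of device_spec objects")
  }
  invisible(cfg)
}

# normal draw truncated at +/- 3 SD (clamped) with a physical floor
rnorm_trunc <- function(n, mean, sd, floor = -Inf) {
  x <- stats::rnorm(n, mean, sd)
  pmax(pmin(pmax(x, mean - 3 * sd), mean + 3 * sd), floor)
}

smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Simulate one subject walking on a treadmill
#'
#' Draws a stochastic gait event schedule (alternating left/right initial
#' contacts with per-step timing, length and width variability), builds a
#' shared continuous-time kinematic model of heel/toe/hip/head landmarks, and
#' samples it once per configured capture device at that device's frame rate,
#' units and noise level. During stance the foot translates backward at belt
#' speed with the heel on the ground; during swing the heel follows a plateau
#' height profile with short smooth lift and descent ramps, and the
#' anteroposterior coordinate follows a smoothstep transfer curve whose
#' boundary velocities match the belt. Pixel devices scale coordinates by
#' `pixel_scale` before adding noise.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `series` (named list of [landmark_series()],
#'   one per device spec, named `<device>_<plane>`) and `truth` (a
#'   `gait_ground_truth` with exact event times and per-step true values).
#' @export
simulate_subject <- function(config) {
  validate_simulation_config(config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  n <- as.integer(config$n_strides)
  n_ic <- 2L * n
  sides <- rep(c("left", "right"), n)
  sf <- config$stance_fraction
  v <- config$belt_speed

  # event schedule: interval after IC of side s is that side's step time
  st_mean <- ifelse(sides == "left", config$mean_step_time_left,
                    config$mean_step_time_right)
  step_times <- rnorm_trunc(n_ic - 1L, st_mean[-n_ic], config$step_time_sd,
                            floor = 0.1)
  t_ic <- 1 + cumsum(c(0, step_times))

  # toe landing positions: step length realised at each landing (leading toe
  # minus trailing toe, the trailing foot having moved back with the belt)
  sl_mean <- ifelse(sides == "left", config$mean_step_length_left,
                    config$mean_step_length_right)
  step_lengths <- c(NA_real_,
                    rnorm_trunc(n_ic - 1L, sl_mean[-1L], config$step_length_sd,
                                floor = 0.05))
  q <- numeric(n_ic)
  q[1] <- 0
  for (k in 2:n_ic) q[k] <- q[k - 1] - v * step_times[k - 1] + step_lengths[k]

  # mediolateral landing offsets (left positive, right negative)
  ml_off <- rnorm_trunc(n_ic, config$step_width_mean / 2,
                        config$step_width_sd / sqrt(2), floor = 0.01)
  ml_off <- ifelse(sides == "left", ml_off, -ml_off)

  basic <- lapply(c(left = "left", right = "right"), function(s) {
    idx <- which(sides == s)
    ic <- t_ic[idx]
    strides <- diff(ic)
    stance <- sf * c(strides, mean(strides))
    list(idx = idx, ic = ic, strides = strides, stance = stance,
         to = ic + stance)
  })
  last_to <- max(basic$left$to, basic$right$to)
  t_end <- last_to + 0.30

  per_side <- lapply(basic, function(ps) {
    # extended cycle arrays with a virtual pre-cycle and a virtual final
    # landing placed beyond the trial end, so no untracked touchdown is
    # sampled inside the analyzed window
    stride1 <- ps$strides[1]
    ic_ext <- c(ps$ic[1] - stride1, ps$ic, last_to + 0.60)
    to_ext <- c(ic_ext[1] + sf * stride1, ps$to, Inf)
    q_ext <- c(q[ps$idx][1], q[ps$idx], q[ps$idx][length(ps$idx)])
    ml_ext <- c(ml_off[ps$idx][1], ml_off[ps$idx], ml_off[ps$idx][length(ps$idx)])
    list(ic = ps$ic, to = c(to_ext[1], ps$to), stance = ps$stance,
         ic_ext = ic_ext, to_ext = to_ext, q_ext = q_ext, ml_ext = ml_ext,
         swing_typ = (1 - sf) * mean(ps$strides))
  })

  traj <- function(s, tq) {
    ps <- per_side[[s]]
    m <- length(ps$ic_ext)
    idx <- pmin(pmax(findInterval(tq, ps$ic_ext), 1L), m - 1L)
    ic0 <- ps$ic_ext[idx]; ic1 <- ps$ic_ext[idx + 1L]; to0 <- ps$to_ext[idx]
    in_stance <- tq <= to0
    # ramp lengths are fixed per side (fractions of the typical swing), so
    # every lift and descent has the same speed profile regardless of
    # step-to-step timing variation or the open-ended final cycle
    lift_dur <- config$swing_lift_frac * ps$swing_typ
    desc_dur <- config$swing_descent_frac * ps$swing_typ
    H <- config$swing_peak_height
    # vertical: plateau hump with smoothstep lift/descent ramps
    vert <- ifelse(in_stance, 0,
                   ifelse(tq - to0 < lift_dur,
                          H * smoothstep((tq - to0) / lift_dur),
                          ifelse(ic1 - tq < desc_dur,
                                 H * smoothstep((ic1 - tq) / desc_dur),
                                 H)))
    # anteroposterior toe: belt-speed translation except during the swing
    # transfer (smoothstep deviation, belt-matched boundary velocities),
    # which is completed before the final vertical descent so positions at
    # initial contact extrapolate linearly through the descent
    e0 <- ps$q_ext[idx] - v * (to0 - ic0)
    t_m0 <- to0 + lift_dur / 2
    t_m1 <- ic1 - desc_dur
    d2 <- t_m1 - t_m0
    x0 <- e0 - v * (lift_dur / 2)
    x1 <- ps$q_ext[idx + 1L] + v * desc_dur
    A <- (x1 - x0) + v * d2
    w <- pmin(pmax((tq - t_m0) / d2, 0), 1)
    ap_swing <- ifelse(tq < t_m0, e0 - v * (tq - to0),
                       ifelse(tq > t_m1, ps$q_ext[idx + 1L] - v * (tq - ic1),
                              x0 - v * (tq - t_m0) + A * smoothstep(w)))
    ap_toe <- ifelse(in_stance, ps$q_ext[idx] - v * (tq - ic0), ap_swing)
    ml <- ifelse(in_stance, ps$ml_ext[idx],
                 ps$ml_ext[idx] + (ps$ml_ext[idx + 1L] - ps$ml_ext[idx]) * smoothstep(w))
    list(ap_toe = ap_toe, ap_heel = ap_toe - config$foot_length,
         vert = vert, ml = ml)
  }

  sample_plane <- function(plane, tq) {
    L <- traj("left", tq); R <- traj("right", tq)
    hip_ap <- (L$ap_toe + R$ap_toe) / 2 - config$foot_length / 2
    hip_ml <- (L$ml + R$ml) / 2
    if (plane == "sagittal") {
      data.frame(
        "heel.left.ap" = L$ap_heel, "heel.left.vert" = L$vert,
        "toe.left.ap" = L$ap_toe, "toe.left.vert" = L$vert,
        "heel.right.ap" = R$ap_heel, "heel.right.vert" = R$vert,
        "toe.right.ap" = R$ap_toe, "toe.right.vert" = R$vert,
        "hip.center.ap" = hip_ap, "hip.center.vert" = 0.53 * config$subject_height,
        "head.center.ap" = hip_ap, "head.center.vert" = config$subject_height,
        check.names = FALSE
      )
    } else {
      data.frame(
        "heel.left.ml" = L$ml, "heel.left.vert" = L$vert,
        "toe.left.ml" = L$ml, "toe.left.vert" = L$vert,
        "heel.right.ml" = R$ml, "heel.right.vert" = R$vert,
        "toe.right.ml" = R$ml, "toe.right.vert" = R$vert,
        "hip.center.ml" = hip_ml, "hip.center.vert" = 0.53 * config$subject_height,
        "head.center.ml" = hip_ml, "head.center.vert" = config$subject_height,
        check.names = FALSE
      )
    }
  }

  series <- list()
  for (ds in config$device_specs) {
    tq <- seq(0, t_end, by = 1 / ds$fps)
    coords <- sample_plane(ds$plane, tq)
    if (ds$units == "pixels") coords[] <- lapply(coords, function(x) x * ds$pixel_scale)
    if (ds$noise_sd > 0) {
      coords[] <- lapply(coords, function(x) x + stats::rnorm(length(x), 0, ds$noise_sd))
    }
    if (ds$dropout_rate > 0) {
      coords[] <- lapply(coords, function(x) {
        x[stats::runif(length(x)) < ds$dropout_rate] <- NA_real_
        x
      })
    }
    series[[paste(ds$name, ds$plane, sep = "_")]] <-
      landmark_series(tq, coords, device = ds$name, plane = ds$plane,
                      fps = ds$fps, units = ds$units,
                      subject_height = config$subject_height)
  }

  # exact ground truth ------------------------------------------------------
  ev <- rbind(
    data.frame(event_type = "IC", side = sides, time_s = t_ic),
    do.call(rbind, lapply(c("left", "right"), function(s) {
      ps <- per_side[[s]]
      data.frame(event_type = "TO", side = s, time_s = ps$to[seq_len(length(ps$ic) + 1L)])
    }))
  )
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL

  stance_by_ic <- sf * c(t_ic[seq(3, n_ic)] - t_ic[seq(1, n_ic - 2L)], NA, NA)
  stance_by_ic[n_ic - 1L] <- per_side[[sides[n_ic - 1L]]]$stance[n]
  stance_by_ic[n_ic] <- per_side[[sides[n_ic]]]$stance[n]
  stride_by_ic <- c(t_ic[seq(3, n_ic)] - t_ic[seq(1, n_ic - 2L)], NA, NA)
  steps <- data.frame(
    index = seq_len(n_ic),
    side = sides,
    t_ic = t_ic,
    step_time = c(step_times, NA),
    step_length = step_lengths,
    step_width = abs(ml_off - c(NA, ml_off[-n_ic])),
    stance_time = stance_by_ic,
    stance_pct = 100 * stance_by_ic / stride_by_ic,
    stride_time = stride_by_ic,
    double_support = c(stance_by_ic[-n_ic] + stance_by_ic[-1L] - stride_by_ic[-n_ic], NA)
  )
  steps$double_support_pct <- 100 * steps$double_support / steps$stride_time
  steps$step_width[1] <- abs(ml_off[1] - ml_off[2])

  truth <- structure(
    list(events = ev, steps = steps, config = config, t_end = t_end),
    class = "gait_ground_truth"
  )
  list(series = series, truth = truth)
}

#' @export
print.gait_ground_truth <- function(x, ...) {
  cat(sprintf("<gait_ground_truth> %d events (%d IC), %d steps, %.1f s trial\n",
              nrow(x$events), sum(x$events$event_type == "IC"),
              nrow(x$steps), x$t_end))
  invisible(x)
}

#' True gait metrics from simulation ground truth
#'
#' Computes the spatio-temporal gait parameter summary directly from the
#' exact continuous-time ground truth (no sampling, filtering or detection),
#' using the same per-side-then-average aggregation as [gait_summary()]. This
#' is the oracle against which parameter recovery through the full pipeline
#' is judged.
#'
#' @param gt a `gait_ground_truth` from [simulate_subject()].
#' @param plane `"sagittal"` or `"frontal"`.
#' @return A [gait_metric_set()].
#' @export
true_metrics <- function(gt, plane = c("sagittal", "frontal")) {
  plane <- match.arg(plane)
  if (sum(gt$steps$side == "left") < 2 || sum(gt$steps$side == "right") < 2) {
    stop("insufficient data: ground truth must contain at least 2 strides per side",
         call. = FALSE)
  }
  aggregate_steps(gt$steps, plane = plane, device = "truth")
}

#' Simulate a cohort of subjects
#'
#' Draws per-subject gait characteristics from cohort-level distributions at
#' the scale reported for healthy adults on a treadmill (cadence about
#' 104 steps/min with SD 5, step time 0.576 +/- 0.029 s, step length
#' 62.2 +/- 3.3 cm, step width 10.6 +/- 2.7 cm, height 1.74 +/- 0.06 m), with
#' mild left/right asymmetry calibrated so that mean gait symmetry is near
#' 97%, then runs [simulate_subject()] per subject.
#'
#' @param n_subjects number of subjects (default 16).
#' @param seed integer cohort seed; per-subject seeds are derived from it.
#' @param base_config a [simulation_config()] used as the template.
#' @return A list of per-subject lists (`series`, `truth`, `config`).
#' @export
simulate_cohort <- function(n_subjects = 16L, seed = 1L,
                            base_config = simulation_config()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  height <- rnorm_trunc(n_subjects, 1.74, 0.06, floor = 1.4)
  st_base <- rnorm_trunc(n_subjects, 0.576, 0.029, floor = 0.35)
  st_asym <- rnorm_trunc(n_subjects, 0, 0.0217)
  sl_base <- rnorm_trunc(n_subjects, 0.62188, 0.0329, floor = 0.3)
  sl_asym <- rnorm_trunc(n_subjects, 0, 0.0234)
  sw <- rnorm_trunc(n_subjects, 0.10625, 0.0267, floor = 0.04)
  lapply(seq_len(n_subjects), function(i) {
    cfg <- base_config
    cfg$subject_height <- height[i]
    cfg$mean_step_time_left <- st_base[i] - st_asym[i] / 2
    cfg$mean_step_time_right <- st_base[i] + st_asym[i] / 2
    cfg$mean_step_length_left <- sl_base[i] - sl_asym[i] / 2
    cfg$mean_step_length_right <- sl_base[i] + sl_asym[i] / 2
    cfg$step_width_mean <- sw[i]
    cfg$seed <- (as.integer(seed) * 1009L + i * 9973L) %% 2147483647L
    validate_simulation_config(cfg)
    out <- simulate_subject(cfg)
    out$config <- cfg
    out$subject <- sprintf("S%02d", i)
    out
  })
}
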
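#' Gait metric set
#'
#' One subject x device x plane summary of the spatio-temporal gait
#' parameters. Sagittal summaries hold seven metrics (cadence, double
#' support, gait symmetry, gait variability, stance time, step length, step
#' time); frontal summaries hold five (cadence, gait symmetry, stance time,
#' step width, step time). Step length and width are reported in cm, times in
#' seconds, cadence in steps/min, symmetry and variability in percent.
#'
#' @param plane `"sagittal"` or `"frontal"`.
#' @param device device label.
#' @param metrics named numeric vector of metric values.
#' @param xr,xl the per-side aggregates entering the symmetry index (right and
#'   left mean step length for sagittal, mean step time for frontal).
#' @param n_steps number of steps summarized.
#' @param subject optional subject identifier.
#' @return An object of class `gait_metric_set`.
#' @export
gait_metric_set <- function(plane, device, metrics, xr = NA_real_,
                            xl = NA_real_, n_steps = NA_integer_,
                            subject = NA_character_) {
  expected <- plane_metrics(plane)
  miss <- setdiff(expected, names(metrics))
  if (length(miss)) {
    stop(sprintf("%s metric set is missing: %s", plane,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  structure(list(plane = plane, device = device,
                 metrics = metrics[expected], xr = xr, xl = xl,
                 n_steps = n_steps, subject = subject),
            class = "gait_metric_set")
}

#' @rdname gait_metric_set
#' @param plane anatomical plane.
#' @export
plane_metrics <- function(plane) {
  switch(match.arg(plane, c("sagittal", "frontal")),
    sagittal = c("cadence", "double_support", "gait_symmetry",
                 "gait_variability", "stance_time", "step_length", "step_time"),
    frontal = c("cadence", "gait_symmetry", "stance_time", "step_time",
                "step_width")
  )
}

#' @export
print.gait_metric_set <- function(x, ...) {
  cat(sprintf("<gait_metric_set> %s / %s (%s steps)\n", x$device, x$plane,
              x$n_steps))
  print(round(x$metrics, 3))
  invisible(x)
}

#' @export
as.data.frame.gait_metric_set <- function(x, ...) {
  data.frame(subject = x$subject, device = x$device, plane = x$plane,
             metric = names(x$metrics), value = unname(x$metrics))
}

#' Build a per-step table from detected gait events
#'
#' Converts an ordered sequence of initial-contact (IC) and toe-off (TO)
#' events into per-step records. For the step ending conventions: the step
#' time of side *s* runs from IC of foot *s* to IC of the contralateral foot;
#' stance time runs from IC to the next TO of the same foot; double support
#' per stride is `stance_left + stance_right - stride_time`. Step length
#' (sagittal plane) is the anteroposterior distance between the two toes at
#' each IC; step width (frontal plane) is the mediolateral distance between
#' the heels at each IC, both interpolated from the synchronized landmark
#' series at the refined event time.
#'
#' @param events data frame of gait events (columns `event_type`, `side`,
#'   `time_s`), e.g. from [detect_events()] on both sides.
#' @param series the metric-unit [landmark_series()] the events refer to.
#' @return A data frame of class `step_table` with one row per IC.
#' @export
build_step_table <- function(events, series) {
  if (!is.null(series) && series$units != "meters") {
    stop("step table requires a metric-unit series; convert pixels first",
         call. = FALSE)
  }
  ics <- events[events$event_type == "IC", ]
  ics <- ics[order(ics$time_s), ]
  if (nrow(ics) < 4) {
    stop("insufficient data: need at least 4 initial contacts", call. = FALSE)
  }
  if (any(ics$side[-1] == ics$side[-nrow(ics)])) {
    k <- which(ics$side[-1] == ics$side[-nrow(ics)])[1]
    stop(sprintf(
      "event sequence error: consecutive %s-side initial contacts at %.3f s and %.3f s",
      ics$side[k], ics$time_s[k], ics$time_s[k + 1]), call. = FALSE)
  }
  for (s in c("left", "right")) {
    es <- events[events$side == s, ]
    es <- es[order(es$time_s), ]
    if (any(es$event_type[-1] == es$event_type[-nrow(es)])) {
      k <- which(es$event_type[-1] == es$event_type[-nrow(es)])[1]
      stop(sprintf(
        "event sequence error: %s side has consecutive %s events at %.3f s and %.3f s",
        s, es$event_type[k], es$time_s[k], es$time_s[k + 1]), call. = FALSE)
    }
  }

  n <- nrow(ics)
  t_ic <- ics$time_s
  side <- ics$side
  step_time <- c(diff(t_ic), NA)
  stride_time <- c(t_ic[seq(3, n)] - t_ic[seq(1, n - 2)], NA, NA)
  stance_time <- vapply(seq_len(n), function(k) {
    tos <- events$time_s[events$event_type == "TO" & events$side == side[k] &
                           events$time_s > t_ic[k]]
    if (!length(tos)) return(NA_real_)
    st <- min(tos) - t_ic[k]
    if (!is.na(stride_time[k]) && st >= stride_time[k]) NA_real_ else st
  }, numeric(1))
  double_support <- c(stance_time[-n] + stance_time[-1] - stride_time[-n], NA)

  step_length <- rep(NA_real_, n)
  step_width <- rep(NA_real_, n)
  if (!is.null(series)) {
    interp <- function(landmark, s, axis, tq) {
      stats::approx(series$time, get_channel(series, landmark, s, axis),
                    xout = tq, rule = 2)$y
    }
    if (series$plane == "sagittal") {
      for (k in seq(2, n)) {
        lead <- interp("toe", side[k], "ap", t_ic[k])
        trail <- interp("toe", other_side(side[k]), "ap", t_ic[k])
        step_length[k] <- abs(lead - trail)
      }
    } else {
      for (k in seq_len(n)) {
        step_width[k] <- abs(interp("heel", "left", "ml", t_ic[k]) -
                               interp("heel", "right", "ml", t_ic[k]))
      }
    }
  }

  structure(
    data.frame(index = seq_len(n), side = side, t_ic = t_ic,
               step_time = step_time, step_length = step_length,
               step_width = step_width, stance_time = stance_time,
               stance_pct = 100 * stance_time / stride_time,
               stride_time = stride_time, double_support = double_support,
               double_support_pct = 100 * double_support / stride_time),
    class = c("step_table", "data.frame")
  )
}

other_side <- function(s) ifelse(s == "left", "right", "left")

#' Cadence in steps per minute
#'
#' `60 * (n_IC - 1) / (time from first to last IC)`.
#'
#' @param events gait event data frame, or a numeric vector of IC times.
#' @param duration optional total duration used only for validation.
#' @return Cadence in steps/min.
#' @export
cadence <- function(events, duration = NULL) {
  t_ic <- if (is.numeric(events)) events else
    events$time_s[events$event_type == "IC"]
  t_ic <- sort(t_ic)
  if (!is.null(duration) && duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  if (length(t_ic) < 2) {
    stop("cadence needs at least two initial contacts", call. = FALSE)
  }
  60 * (length(t_ic) - 1) / (t_ic[length(t_ic)] - t_ic[1])
}

#' Step-to-step gait variability
#'
#' Per side, 100 x SD / mean of step length (sample SD, n - 1); the returned
#' value is the mean of the two sides.
#'
#' @param step_lengths_left,step_lengths_right numeric vectors of per-step
#'   lengths.
#' @return Variability in percent.
#' @export
gait_variability <- function(step_lengths_left, step_lengths_right) {
  cv_side <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) stop("gait variability needs at least 2 steps per side",
                            call. = FALSE)
    if (mean(x) == 0) stop("gait variability undefined for zero mean step length",
                           call. = FALSE)
    100 * stats::sd(x) / mean(x)
  }
  (cv_side(step_lengths_left) + cv_side(step_lengths_right)) / 2
}

#' Gait symmetry index
#'
#' `100 * (1 - 2 * |Xr - Xl| / (Xr + Xl))`, where `Xr` and `Xl` are the
#' per-side aggregates: mean step length for the sagittal analysis, mean step
#' time for the frontal analysis. 100% means perfect left/right symmetry; the
#' absolute difference keeps the index at or below 100 and independent of
#' side labelling.
#'
#' @param xr,xl positive per-side aggregates (right, left).
#' @return Symmetry in percent.
#' @export
gait_symmetry <- function(xr, xl) {
  if (!is.numeric(xr) || !is.numeric(xl) || xr <= 0 || xl <= 0) {
    stop("gait symmetry requires positive inputs", call. = FALSE)
  }
  100 * (1 - 2 * abs(xr - xl) / (xr + xl))
}

# shared aggregation: per-side means first, then the mean of both sides
aggregate_steps <- function(steps, plane, device, subject = NA_character_) {
  side_mean <- function(col) {
    l <- mean(steps[[col]][steps$side == "left"], na.rm = TRUE)
    r <- mean(steps[[col]][steps$side == "right"], na.rm = TRUE)
    c(left = l, right = r)
  }
  st <- side_mean("step_time")
  stance <- side_mean("stance_time")
  cad <- cadence(steps$t_ic)
  if (plane == "sagittal") {
    sl <- side_mean("step_length")
    ds <- side_mean("double_support")
    gv <- gait_variability(steps$step_length[steps$side == "left"],
                           steps$step_length[steps$side == "right"])
    xr <- sl[["right"]]; xl <- sl[["left"]]
    metrics <- c(cadence = cad,
                 double_support = mean(ds),
                 gait_symmetry = gait_symmetry(xr, xl),
                 gait_variability = gv,
                 stance_time = mean(stance),
                 step_length = 100 * mean(sl),
                 step_time = mean(st))
  } else {
    xr <- st[["right"]]; xl <- st[["left"]]
    metrics <- c(cadence = cad,
                 gait_symmetry = gait_symmetry(xr, xl),
                 stance_time = mean(stance),
                 step_time = mean(st),
                 step_width = 100 * mean(steps$step_width, na.rm = TRUE))
  }
  gait_metric_set(plane = plane, device = device, metrics = metrics,
                  xr = xr, xl = xl, n_steps = nrow(steps), subject = subject)
}

#' Summarize a step table into a gait metric set
#'
#' Per-side means are computed first and then averaged across sides (the
#' "mean of both sides" convention), so mild left/right asymmetry does not
#' bias the summary toward the side with more recorded steps.
#'
#' @param step_table a [build_step_table()] result.
#' @param plane `"sagittal"` or `"frontal"`.
#' @param device device label recorded in the output.
#' @param subject optional subject identifier.
#' @return A [gait_metric_set()].
#' @export
gait_summary <- function(step_table, plane = c("sagittal", "frontal"),
                         device = "unknown", subject = NA_character_) {
  plane <- match.arg(plane)
  for (s in c("left", "right")) {
    if (sum(!is.na(step_table$stride_time[step_table$side == s])) < 2) {
      stop("insufficient data: need at least 2 complete strides per side",
           call. = FALSE)
    }
  }
  if (plane == "sagittal" && all(is.na(step_table$step_length))) {
    stop("plane error: step length unavailable; was the step table built from a frontal series?",
         call. = FALSE)
  }
  if (plane == "frontal" && all(is.na(step_table$step_width))) {
    stop("plane error: step width unavailable; was the step table built from a sagittal series?",
         call. = FALSE)
  }
  aggregate_steps(step_table, plane = plane, device = device, subject = subject)
}
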
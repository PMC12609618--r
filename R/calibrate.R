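#' Convert a pixel-unit landmark series to meters
#'
#' Markerless video capture reports landmark positions in image pixels; the
#' subject's known body height serves as the metric reference. All coordinates
#' are multiplied by `subject_height / reference_span_px`, where the reference
#' span is the subject's height measured in pixels (see
#' [estimate_reference_span()]).
#'
#' @param series a [landmark_series()] with `units = "pixels"`.
#' @param subject_height body height in meters.
#' @param reference_span_px the subject's height in pixels.
#' @return The series with coordinates in meters and `units = "meters"`.
#' @export
pixels_to_meters <- function(series, subject_height, reference_span_px) {
  if (series$units != "pixels") {
    stop("pixels_to_meters() called on a series that is not in pixel units",
         call. = FALSE)
  }
  if (!is.numeric(reference_span_px) || reference_span_px <= 0) {
    stop("`reference_span_px` must be positive", call. = FALSE)
  }
  if (!is.numeric(subject_height) || subject_height <= 0) {
    stop("`subject_height` must be positive", call. = FALSE)
  }
  scale <- subject_height / reference_span_px
  series$coords[] <- lapply(series$coords, function(v) v * scale)
  series$units <- "meters"
  series$subject_height <- subject_height
  series
}

#' Estimate the subject's height in pixels
#'
#' Returns the median, over the first `window` frames, of the vertical pixel
#' distance from the head-top landmark to the lower of the two heel
#' landmarks. The median makes the estimate robust to per-frame landmark
#' noise of a few pixels.
#'
#' @param series a pixel-unit [landmark_series()] containing `head` and both
#'   `heel` landmarks.
#' @param window number of frames to aggregate over (default: all frames).
#' @return Estimated vertical span in pixels.
#' @export
estimate_reference_span <- function(series, window = length(series$time)) {
  head_v <- get_channel(series, "head", "center", "vert")
  heel_l <- get_channel(series, "heel", "left", "vert")
  heel_r <- get_channel(series, "heel", "right", "vert")
  window <- min(window, length(head_v))
  if (window < 1) stop("window must cover at least one frame", call. = FALSE)
  idx <- seq_len(window)
  stats::median(head_v[idx] - pmin(heel_l[idx], heel_r[idx]))
}

#' Time-synchronize two event lists
#'
#' The two capture systems run on independent clocks, so their event times
#' differ by an unknown offset. Events of the same type and side are matched
#' by rank order, and the offset is the median signed time difference
#' (reference minus test) over all matched pairs: adding it to the test event
#' times makes the median signed difference zero. The median is robust to a
#' few misdetections and to per-event jitter.
#'
#' @param ref_events,test_events gait event data frames (columns `event_type`,
#'   `side`, `time_s`) from [detect_events()].
#' @return The time offset in seconds to add to the test events.
#' @export
sync_by_events <- function(ref_events, test_events) {
  diffs <- c()
  for (ty in intersect(unique(ref_events$event_type), unique(test_events$event_type))) {
    for (sd in intersect(unique(ref_events$side), unique(test_events$side))) {
      r <- sort(ref_events$time_s[ref_events$event_type == ty & ref_events$side == sd])
      t <- sort(test_events$time_s[test_events$event_type == ty & test_events$side == sd])
      k <- min(length(r), length(t))
      if (k > 0) diffs <- c(diffs, r[seq_len(k)] - t[seq_len(k)])
    }
  }
  if (!length(diffs)) {
    stop("no common event types/sides between the two lists; cannot synchronize",
         call. = FALSE)
  }
  stats::median(diffs)
}

#' Apply a time offset to an event list
#'
#' @param events gait event data frame.
#' @param offset seconds to add to `time_s` (from [sync_by_events()]).
#' @return The shifted event data frame.
#' @export
shift_events <- function(events, offset) {
  events$time_s <- events$time_s + offset
  events
}
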
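#' Detect initial-contact and toe-off events from landmark kinematics
#'
#' The default `velocity` method follows the foot-velocity tradition of
#' kinematic event detection: the foot centre is the midpoint of heel and
#' toe, its vertical velocity is obtained by central differences, and initial
#' contacts (IC) are the prominent local minima while toe-offs (TO) are the
#' prominent local maxima of that velocity, one per gait cycle. The dominant
#' stride period, estimated from the autocorrelation of the heel height
#' signal, imposes a minimum peak separation of half a stride. The
#' alternative `coordinate` method uses the anteroposterior position of heel
#' (IC = maxima) and toe (TO = minima) relative to the hip, and is only
#' available for sagittal-plane series. Event times are refined to sub-frame
#' precision by a quadratic fit through the extremum and its two neighbours;
#' at 30 fps the raw frame quantization (+/- 17 ms) would otherwise consume
#' most of the timing-error budget of a validation study.
#'
#' @param series a filtered, metric-unit [landmark_series()].
#' @param side `"left"` or `"right"`.
#' @param method `"velocity"` (default) or `"coordinate"`.
#' @return Data frame of events: `event_type`, `side`, `frame` (0-based),
#'   `time_s` (refined), `device`.
#' @export
detect_events <- function(series, side = c("left", "right"),
                          method = c("velocity", "coordinate")) {
  side <- match.arg(side)
  method <- match.arg(method)
  if (series$units != "meters") {
    stop("detect_events() requires a metric-unit series; convert pixels first",
         call. = FALSE)
  }
  fps <- series$fps
  heel_v <- get_channel(series, "heel", side, "vert")
  period <- dominant_period(heel_v, fps)
  min_sep <- 0.5 * period

  if (method == "velocity") {
    toe_v <- get_channel(series, "toe", side, "vert")
    foot <- (heel_v + toe_v) / 2
    vel <- central_diff(foot) * fps
    ic <- find_extrema(-vel, fps, min_sep)
    to <- find_extrema(vel, fps, min_sep)
  } else {
    if (series$plane != "sagittal") {
      stop("coordinate method needs anteroposterior data (sagittal plane)",
           call. = FALSE)
    }
    hip <- get_channel(series, "hip", "center", "ap")
    heel_rel <- get_channel(series, "heel", side, "ap") - hip
    toe_rel <- get_channel(series, "toe", side, "ap") - hip
    ic <- find_extrema(heel_rel, fps, min_sep)
    to <- find_extrema(-toe_rel, fps, min_sep)
  }

  ev <- rbind(
    if (length(ic$time)) data.frame(event_type = "IC", side = side,
                                    frame = ic$frame, time_s = ic$time),
    if (length(to$time)) data.frame(event_type = "TO", side = side,
                                    frame = to$frame, time_s = to$time)
  )
  if (is.null(ev) || !nrow(ev)) {
    stop("no gait detected: no periodic foot motion found", call. = FALSE)
  }
  ev$device <- series$device
  ev <- ev[order(ev$time_s), ]
  rownames(ev) <- NULL
  ev
}

central_diff <- function(x) {
  n <- length(x)
  c(x[2] - x[1], (x[seq(3, n)] - x[seq(1, n - 2)]) / 2, x[n] - x[n - 1])
}

# dominant stride period (s) from the autocorrelation of a cyclic signal
dominant_period <- function(x, fps, min_period = 0.4, max_period = 2.5) {
  x <- x - mean(x)
  if (stats::sd(x) == 0) {
    stop("no gait detected: trajectory is constant", call. = FALSE)
  }
  max_lag <- min(length(x) - 2L, ceiling(max_period * fps))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = FALSE)$acf[, 1, 1]
  lags <- seq(ceiling(min_period * fps), max_lag)
  if (!length(lags)) {
    stop("no gait detected: series shorter than one stride", call. = FALSE)
  }
  best <- lags[which.max(ac[lags + 1L])]
  if (ac[best + 1L] < 0.2) {
    stop("no gait detected: no periodicity in the trajectory (flat autocorrelation)",
         call. = FALSE)
  }
  best / fps
}

# prominent local maxima of x with a minimum separation, sub-frame refined by
# a quadratic through the extremum and its neighbours; returns 0-based frames
find_extrema <- function(x, fps, min_sep_s) {
  n <- length(x)
  i <- seq(2, n - 1)
  cand <- i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
  thr <- 0.25 * stats::quantile(abs(x), 0.98, names = FALSE)
  cand <- cand[x[cand] > thr]
  if (!length(cand)) return(list(frame = integer(0), time = numeric(0)))
  # greedy by peak height under the separation constraint
  cand <- cand[order(x[cand], decreasing = TRUE)]
  sep <- max(1L, round(min_sep_s * fps))
  keep <- integer(0)
  for (c0 in cand) {
    if (!length(keep) || all(abs(keep - c0) >= sep)) keep <- c(keep, c0)
  }
  keep <- sort(keep)
  delta <- vapply(keep, function(k) {
    denom <- x[k - 1] - 2 * x[k] + x[k + 1]
    if (denom == 0) 0 else 0.5 * (x[k - 1] - x[k + 1]) / denom
  }, numeric(1))
  delta <- pmin(pmax(delta, -0.5), 0.5)
  list(frame = keep - 1L, time = (keep - 1L + delta) / fps)
}

#' Match detected events against a reference list
#'
#' Greedy nearest-in-time one-to-one matching within `+/- window` seconds,
#' separately per event type and side. Unmatched reference events count as
#' misses; the detection rate is `100 * n_matched / n_reference`. Signed
#' errors are reference minus test.
#'
#' @param ref,test gait event data frames (the two lists must already be
#'   time-synchronized, see [sync_by_events()]).
#' @param window matching half-window in seconds (default 0.100, below half
#'   of the shortest plausible step time).
#' @return An `event_match_report`: list with `summary` (per type x side) and
#'   `pairs` (matched pairs with signed errors).
#' @export
match_events <- function(ref, test, window = 0.100) {
  if (!is.numeric(window) || window <= 0) {
    stop("matching window must be positive", call. = FALSE)
  }
  summaries <- list()
  pairs <- list()
  for (ty in unique(ref$event_type)) {
    for (sd in unique(ref$side[ref$event_type == ty])) {
      r <- sort(ref$time_s[ref$event_type == ty & ref$side == sd])
      t <- sort(test$time_s[test$event_type == ty & test$side == sd])
      cand <- expand.grid(i = seq_along(r), j = seq_along(t))
      if (nrow(cand)) {
        cand$dt <- abs(r[cand$i] - t[cand$j])
        cand <- cand[cand$dt <= window, ]
        cand <- cand[order(cand$dt), ]
      }
      used_i <- logical(length(r)); used_j <- logical(length(t))
      m_i <- integer(0); m_j <- integer(0)
      for (k in seq_len(nrow(cand))) {
        i <- cand$i[k]; j <- cand$j[k]
        if (!used_i[i] && !used_j[j]) {
          used_i[i] <- TRUE; used_j[j] <- TRUE
          m_i <- c(m_i, i); m_j <- c(m_j, j)
        }
      }
      err <- r[m_i] - t[m_j]
      summaries[[paste(ty, sd)]] <- data.frame(
        event_type = ty, side = sd,
        n_reference = length(r), n_detected = length(t),
        n_matched = length(m_i),
        detection_rate = if (length(r)) 100 * length(m_i) / length(r) else NA_real_,
        mean_error = if (length(err)) mean(err) else NA_real_,
        mean_absolute_error = if (length(err)) mean(abs(err)) else NA_real_,
        sd_error = if (length(err) > 1) stats::sd(err) else NA_real_
      )
      if (length(err)) {
        pairs[[paste(ty, sd)]] <- data.frame(
          event_type = ty, side = sd, ref_time = r[m_i], test_time = t[m_j],
          error = err)
      }
    }
  }
  structure(list(summary = do.call(rbind, c(summaries, list(make.row.names = FALSE))),
                 pairs = if (length(pairs))
                   do.call(rbind, c(pairs, list(make.row.names = FALSE)))
                 else NULL),
            class = "event_match_report")
}

#' @export
print.event_match_report <- function(x, ...) {
  cat("<event_match_report>\n")
  s <- x$summary
  s$mean_error <- round(1000 * s$mean_error, 2)
  s$mean_absolute_error <- round(1000 * s$mean_absolute_error, 2)
  s$sd_error <- round(1000 * s$sd_error, 2)
  names(s)[names(s) %in% c("mean_error", "mean_absolute_error", "sd_error")] <-
    c("mean_ms", "mae_ms", "sd_ms")
  print(s, row.names = FALSE)
  invisible(x)
}

#' Pool event-timing errors across subjects
#'
#' Pools the matched event pairs of several match reports and returns, per
#' event type and side, the mean absolute error and the SD of the signed
#' errors in milliseconds, plus pooled detection counts.
#'
#' @param reports list of `event_match_report` objects from [match_events()].
#' @return Data frame with one row per event type x side.
#' @export
timing_error_stats <- function(reports) {
  if (!length(reports)) stop("insufficient data: no match reports", call. = FALSE)
  pairs <- do.call(rbind, lapply(reports, function(r) r$pairs))
  sums <- do.call(rbind, lapply(reports, function(r) r$summary))
  if (is.null(pairs) || !nrow(pairs)) {
    stop("insufficient data: no matched event pairs to pool", call. = FALSE)
  }
  out <- do.call(rbind, lapply(split(pairs, list(pairs$event_type, pairs$side)),
                               function(p) {
    ss <- sums[sums$event_type == p$event_type[1] & sums$side == p$side[1], ]
    data.frame(event_type = p$event_type[1], side = p$side[1],
               n_reference = sum(ss$n_reference), n_matched = nrow(p),
               detection_rate = 100 * sum(ss$n_matched) / sum(ss$n_reference),
               mean_ms = 1000 * mean(p$error),
               mae_ms = 1000 * mean(abs(p$error)),
               sd_ms = 1000 * stats::sd(p$error))
  }))
  rownames(out) <- NULL
  out[order(out$event_type, out$side), ]
}
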
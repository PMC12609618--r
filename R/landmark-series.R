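#' Landmark trajectory series
#'
#' A `landmark_series` holds the time-indexed 2D positions of named body
#' landmarks as observed by one capture device in one anatomical plane.
#' Sagittal-plane series carry anteroposterior (`ap`) and vertical (`vert`)
#' coordinates; frontal-plane series carry mediolateral (`ml`) and vertical
#' coordinates. Coordinates are stored as one numeric column per channel,
#' named `<landmark>.<side>.<axis>` (e.g. `heel.left.vert`).
#'
#' @param time numeric vector of sample times in seconds (uniformly spaced).
#' @param coords data frame of coordinate channels, one row per sample.
#' @param device device label (e.g. `"VIC"`, `"OV"`).
#' @param plane `"sagittal"` or `"frontal"`.
#' @param fps sampling rate in Hz.
#' @param units `"meters"` or `"pixels"`.
#' @param subject_height subject body height in meters.
#'
#' @return An object of class `landmark_series`.
#' @export
landmark_series <- function(time, coords, device, plane, fps, units,
                            subject_height = NA_real_) {
  plane <- match.arg(plane, c("sagittal", "frontal"))
  units <- match.arg(units, c("meters", "pixels"))
  coords <- as.data.frame(coords)
  if (length(time) != nrow(coords)) {
    stop("`time` and `coords` must have the same length", call. = FALSE)
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a single positive number", call. = FALSE)
  }
  structure(
    list(time = as.numeric(time), coords = coords, device = device,
         plane = plane, fps = fps, units = units,
         subject_height = subject_height),
    class = "landmark_series"
  )
}

#' @export
print.landmark_series <- function(x, ...) {
  cat(sprintf(
    "<landmark_series> device=%s plane=%s fps=%g units=%s\n  %d samples (%.2f s), %d channels: %s\n",
    x$device, x$plane, x$fps, x$units, length(x$time),
    diff(range(x$time)), ncol(x$coords),
    paste(utils::head(names(x$coords), 6), collapse = ", ")
  ))
  invisible(x)
}

channel_name <- function(landmark, side, axis) paste(landmark, side, axis, sep = ".")

#' Extract a coordinate channel
#'
#' @param series a [landmark_series()].
#' @param landmark landmark name (`"heel"`, `"toe"`, `"hip"`, `"head"`).
#' @param side `"left"`, `"right"` or `"center"`.
#' @param axis `"ap"`, `"ml"` or `"vert"`.
#' @return Numeric vector of coordinate values.
#' @export
get_channel <- function(series, landmark, side, axis) {
  nm <- channel_name(landmark, side, axis)
  if (!nm %in% names(series$coords)) {
    stop(sprintf("missing landmark channel '%s' in %s-plane series", nm, series$plane),
         call. = FALSE)
  }
  series$coords[[nm]]
}

has_channel <- function(series, landmark, side, axis) {
  channel_name(landmark, side, axis) %in% names(series$coords)
}

#' Write a landmark series to long-format CSV
#'
#' Columns are `frame,time_s,landmark,side,axis,value,confidence` (frames are
#' 0-based). Device metadata (device, plane, fps, units, subject height) is
#' written to a JSON sidecar `<path>.meta.json` so the series round-trips.
#'
#' @param series a [landmark_series()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(series, path) {
  parts <- strsplit(names(series$coords), ".", fixed = TRUE)
  n <- length(series$time)
  long <- do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    data.frame(frame = seq_len(n) - 1L, time_s = series$time,
               landmark = p[1], side = p[2], axis = p[3],
               value = series$coords[[i]], confidence = 1)
  }))
  long <- long[order(long$frame, long$landmark, long$side, long$axis), ]
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(device = series$device, plane = series$plane, fps = series$fps,
               units = series$units, subject_height = series$subject_height)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a landmark series from long-format CSV
#'
#' @param path CSV path as written by [write_landmarks()].
#' @param device,plane,fps,units,subject_height metadata overrides; when `NULL`
#'   they are taken from the `<path>.meta.json` sidecar (fps falls back to the
#'   median frame interval).
#' @return A [landmark_series()].
#' @export
read_landmarks <- function(path, device = NULL, plane = NULL, fps = NULL,
                           units = NULL, subject_height = NULL) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "landmark", "side", "axis", "value")
  miss <- setdiff(need, names(long))
  if (length(miss)) {
    stop("landmark CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  pick <- function(arg, key, default = NULL) {
    if (!is.null(arg)) arg else if (!is.null(meta[[key]])) meta[[key]] else default
  }
  frames <- sort(unique(long$frame))
  time <- long$time_s[match(frames, long$frame)]
  chan <- channel_name(long$landmark, long$side, long$axis)
  coords <- as.data.frame(lapply(split(seq_len(nrow(long)), chan), function(idx) {
    rows <- long[idx, ]
    rows$value[match(frames, rows$frame)]
  }), check.names = FALSE)
  fps_val <- pick(fps, "fps", 1 / stats::median(diff(time)))
  landmark_series(
    time = time, coords = coords,
    device = pick(device, "device", "unknown"),
    plane = pick(plane, "plane", "sagittal"),
    fps = as.numeric(fps_val),
    units = pick(units, "units", "meters"),
    subject_height = as.numeric(pick(subject_height, "subject_height", NA_real_))
  )
}

#' Fill short gaps in landmark channels
#'
#' Linear interpolation across runs of missing samples up to `max_gap` frames;
#' any longer run rejects the series (the trial is considered unusable).
#'
#' @param series a [landmark_series()] whose coords may contain `NA`.
#' @param max_gap longest run of missing frames to interpolate (default 5).
#' @return The gap-filled [landmark_series()].
#' @export
fill_gaps <- function(series, max_gap = 5L) {
  coords <- series$coords
  for (nm in names(coords)) {
    v <- coords[[nm]]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    if (any(r$lengths[r$values] > max_gap)) {
      stop(sprintf("channel '%s' has a gap longer than %d frames; trial rejected",
                   nm, max_gap), call. = FALSE)
    }
    if (is.na(v[1]) || is.na(v[length(v)])) {
      stop(sprintf("channel '%s' has missing samples at the series boundary", nm),
           call. = FALSE)
    }
    coords[[nm]] <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                                  xout = seq_along(v))$y
  }
  series$coords <- coords
  series
}
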
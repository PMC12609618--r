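#' Analyze one landmark series into gait events and metrics
#'
#' Runs the single-subject processing chain: gap filling, zero-phase
#' Butterworth low-pass filtering (by default only for pixel-unit video
#' streams; the near-noise-free metric reference stream is left unfiltered
#' unless `apply_filter = TRUE`), pixel-to-meter conversion using the
#' subject's height against the estimated head-to-heel pixel span, event
#' detection on both sides, step-table construction and the per-plane gait
#' parameter summary.
#'
#' @param series a [landmark_series()].
#' @param subject optional subject identifier carried into the metric set.
#' @param cutoff,order Butterworth settings (defaults 3 Hz, order 2).
#' @param method event detection method, see [detect_events()].
#' @param apply_filter force (`TRUE`) or suppress (`FALSE`) filtering;
#'   `NULL` (default) filters pixel streams only.
#' @param max_gap longest missing-sample run to interpolate, frames.
#' @return List with `series` (processed), `events`, `step_table`, `metrics`.
#' @export
run_analyze <- function(series, subject = NA_character_, cutoff = 3,
                        order = 2L, method = c("velocity", "coordinate"),
                        apply_filter = NULL, max_gap = 5L) {
  method <- match.arg(method)
  series <- fill_gaps(series, max_gap = max_gap)
  do_filter <- if (is.null(apply_filter)) series$units == "pixels" else apply_filter
  if (do_filter) series <- butterworth_lowpass(series, cutoff = cutoff, order = order)
  if (series$units == "pixels") {
    span <- estimate_reference_span(series)
    series <- pixels_to_meters(series, series$subject_height, span)
  }
  events <- rbind(detect_events(series, "left", method),
                  detect_events(series, "right", method))
  events <- events[order(events$time_s), ]
  steps <- build_step_table(events, series)
  metrics <- gait_summary(steps, plane = series$plane, device = series$device,
                          subject = subject)
  list(series = series, events = events, step_table = steps, metrics = metrics)
}

#' Compare reference and test analyses across a cohort
#'
#' Synchronizes each subject's test events to the reference events, matches
#' them within the tolerance window, pools the timing errors, and assembles
#' the per-metric agreement table (CCC, CV, Bland-Altman).
#'
#' @param ref_analyses,test_analyses lists of [run_analyze()] results, same
#'   subjects in the same order.
#' @param plane `"sagittal"` or `"frontal"`.
#' @param window event matching half-window in seconds.
#' @return List with `agreement` ([agreement_table()]), `event_stats`
#'   (pooled [timing_error_stats()]), `reports` and `offsets` per subject.
#' @export
run_compare <- function(ref_analyses, test_analyses,
                        plane = c("sagittal", "frontal"), window = 0.100) {
  plane <- match.arg(plane)
  if (length(ref_analyses) != length(test_analyses)) {
    stop("pairing error: reference and test cohorts differ in size", call. = FALSE)
  }
  if (length(ref_analyses) < 2) {
    stop("insufficient data: comparison needs at least 2 subjects", call. = FALSE)
  }
  reports <- vector("list", length(ref_analyses))
  offsets <- numeric(length(ref_analyses))
  for (i in seq_along(ref_analyses)) {
    offsets[i] <- sync_by_events(ref_analyses[[i]]$events,
                                 test_analyses[[i]]$events)
    shifted <- shift_events(test_analyses[[i]]$events, offsets[i])
    reports[[i]] <- match_events(ref_analyses[[i]]$events, shifted,
                                 window = window)
  }
  agreement <- agreement_table(lapply(ref_analyses, `[[`, "metrics"),
                               lapply(test_analyses, `[[`, "metrics"),
                               plane = plane)
  list(agreement = agreement, event_stats = timing_error_stats(reports),
       reports = reports, offsets = offsets)
}

#' End-to-end synthetic validation study
#'
#' Simulates a cohort on the treadmill protocol, analyzes the reference
#' (100 fps metric) and test (30 fps pixel) streams independently for the
#' requested planes, and compares them. Also tabulates parameter recovery of
#' each device against the simulation ground truth.
#'
#' @param n_subjects cohort size (default 16).
#' @param seed integer seed for the whole study.
#' @param base_config template [simulation_config()].
#' @param planes which planes to analyze.
#' @param window event matching half-window, s.
#' @param method event detection method.
#' @return List with one element per plane (each as in [run_compare()], plus
#'   `recovery`, a per-subject data frame of estimated vs true metrics) and
#'   the simulated `cohort`.
#' @export
run_validation_study <- function(n_subjects = 16L, seed = 1L,
                                 base_config = simulation_config(),
                                 planes = c("sagittal", "frontal"),
                                 window = 0.100,
                                 method = "velocity") {
  cohort <- simulate_cohort(n_subjects = n_subjects, seed = seed,
                            base_config = base_config)
  out <- list(cohort = cohort)
  for (plane in planes) {
    ref_an <- lapply(cohort, function(subj) {
      run_analyze(subj$series[[paste0("VIC_", plane)]],
                  subject = subj$subject, method = method)
    })
    test_an <- lapply(cohort, function(subj) {
      run_analyze(subj$series[[paste0("OV_", plane)]],
                  subject = subj$subject, method = method)
    })
    cmp <- run_compare(ref_an, test_an, plane = plane, window = window)
    cmp$recovery <- do.call(rbind, lapply(seq_along(cohort), function(i) {
      tm <- true_metrics(cohort[[i]]$truth, plane = plane)
      rbind(
        recovery_rows(ref_an[[i]]$metrics, tm, cohort[[i]]$subject, "VIC", plane),
        recovery_rows(test_an[[i]]$metrics, tm, cohort[[i]]$subject, "OV", plane)
      )
    }))
    cmp$ref_analyses <- ref_an
    cmp$test_analyses <- test_an
    out[[plane]] <- cmp
  }
  out
}

recovery_rows <- function(est, truth, subject, device, plane) {
  m <- plane_metrics(plane)
  data.frame(subject = subject, device = device, plane = plane, metric = m,
             estimate = unname(est$metrics[m]), truth = unname(truth$metrics[m]),
             error = unname(est$metrics[m] - truth$metrics[m]))
}

#' Write simulated recordings to disk
#'
#' One directory per subject containing a long-format landmark CSV per
#' device/plane, the ground-truth events CSV (`event_type,side,time_s`) and
#' the true metrics JSON for both planes.
#'
#' @param out_dir output directory (created if needed).
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param base_config template [simulation_config()].
#' @return Invisibly, the vector of subject directories.
#' @export
run_simulate <- function(out_dir, n_subjects = 1L, seed = 1L,
                         base_config = simulation_config()) {
  cohort <- simulate_cohort(n_subjects = n_subjects, seed = seed,
                            base_config = base_config)
  dirs <- vapply(cohort, function(subj) {
    d <- file.path(out_dir, subj$subject)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(subj$series)) {
      write_landmarks(subj$series[[nm]], file.path(d, paste0(nm, ".csv")))
    }
    utils::write.csv(subj$truth$events, file.path(d, "events_truth.csv"),
                     row.names = FALSE)
    truths <- lapply(c(sagittal = "sagittal", frontal = "frontal"), function(p) {
      as.list(true_metrics(subj$truth, plane = p)$metrics)
    })
    jsonlite::write_json(truths, file.path(d, "true_metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    d
  }, character(1))
  invisible(dirs)
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [simulation_config()];
#' `device_specs` is a list of mappings with the [device_spec()] fields.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$device_specs)) {
    raw$device_specs <- lapply(raw$device_specs, function(d) do.call(device_spec, d))
  }
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("config error: unknown keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(simulation_config, raw)
}

#' Write comparison outputs to disk
#'
#' Writes the agreement table CSV, the pooled event-error CSV, a short
#' markdown report, and (optionally) per-metric Bland-Altman and scatter
#' plots.
#'
#' @param comparison a [run_compare()] result.
#' @param out_dir output directory.
#' @param plots if `TRUE`, also write one Bland-Altman and one scatter plot
#'   (PNG) per metric.
#' @return Invisibly, the output directory.
#' @export
write_comparison <- function(comparison, out_dir, plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ag <- comparison$agreement
  plane <- attr(ag, "plane")
  utils::write.csv(as.data.frame(ag),
                   file.path(out_dir, paste0("agreement_", plane, ".csv")),
                   row.names = FALSE)
  utils::write.csv(comparison$event_stats,
                   file.path(out_dir, "event_errors.csv"), row.names = FALSE)
  md <- c(
    sprintf("# Device agreement report (%s plane)", plane),
    "",
    sprintf("Subjects: %d; metrics: %d.", ag$n[1], nrow(ag)),
    "",
    "| Metric | CCC | Band | CV ref | CV test | Mean diff | LoA |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %.3f | %s | %.3f | %.3f | %.3f | %.3f / %.3f |",
            ag$metric, ag$ccc, ag$ccc_band, ag$cv_ref, ag$cv_test,
            ag$mean_diff, ag$loa_upper, ag$loa_lower),
    "",
    "## Event timing",
    "",
    "| Event | Side | Detection rate | MAE (ms) | SD (ms) |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %.1f%% | %.2f | %.2f |",
            comparison$event_stats$event_type, comparison$event_stats$side,
            comparison$event_stats$detection_rate,
            comparison$event_stats$mae_ms, comparison$event_stats$sd_ms)
  )
  writeLines(md, file.path(out_dir, paste0("report_", plane, ".md")))
  if (plots) {
    vals <- agreement_pairs(comparison)
    for (metric in unique(vals$metric)) {
      v <- vals[vals$metric == metric, ]
      p1 <- plot_bland_altman(v$ref, v$test, metric)
      p2 <- plot_scatter(v$ref, v$test, metric)
      ggplot2::ggsave(file.path(out_dir, sprintf("ba_%s_%s.png", plane, metric)),
                      p1, width = 5, height = 4, dpi = 120)
      ggplot2::ggsave(file.path(out_dir, sprintf("scatter_%s_%s.png", plane, metric)),
                      p2, width = 5, height = 4, dpi = 120)
    }
  }
  invisible(out_dir)
}

agreement_pairs <- function(comparison) {
  ref <- lapply(comparison$ref_analyses, `[[`, "metrics")
  test <- lapply(comparison$test_analyses, `[[`, "metrics")
  if (is.null(ref[[1]])) stop("comparison lacks per-subject analyses", call. = FALSE)
  do.call(rbind, lapply(seq_along(ref), function(i) {
    m <- names(ref[[i]]$metrics)
    data.frame(subject = ref[[i]]$subject, metric = m,
               ref = unname(ref[[i]]$metrics), test = unname(test[[i]]$metrics))
  }))
}
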
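#' Published benchmark values for a treadmill validation study
#'
#' Summary statistics (per-device mean, SD, CCC with band, CV and limits of
#' agreement per metric, and pooled event-detection errors) as printed by a
#' published validation of a 30 fps markerless pose-estimation system ("OV")
#' against a 100 fps marker-based reference ("VIC") in 16 healthy adults
#' walking at 4 km/h (26 strides per leg analyzed per subject). These rows
#' are inputs for arithmetic cross-checks — e.g. recomputing the printed CV
#' from the printed mean and SD — and for benchmarking simulated cohorts;
#' the package does not treat them as reproducible targets, since the
#' underlying per-subject data are not public.
#'
#' @param which `"sagittal"` or `"frontal"` metric tables, or `"events"` for
#'   the event-detection error table.
#' @return A data frame.
#' @export
benchmark_values <- function(which = c("sagittal", "frontal", "events")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("benchmark_", which, ".csv"),
                      package = "gaitval", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
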
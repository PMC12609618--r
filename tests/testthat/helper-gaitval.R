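# shared fixtures: small, fast simulation configs built in code

small_config <- function(seed = 1L, n_strides = 8L, device_specs = NULL, ...) {
  if (is.null(device_specs)) device_specs <- default_device_specs()
  simulation_config(n_strides = n_strides, device_specs = device_specs,
                    seed = seed, ...)
}

# one sagittal metric device pair: noise-free reference + configurable test
pair_specs <- function(test_fps = 30, test_noise = 2, test_units = "pixels",
                       plane = "sagittal") {
  list(
    device_spec("VIC", fps = 100, units = "meters", plane = plane, noise_sd = 0),
    device_spec("OV", fps = test_fps, units = test_units, plane = plane,
                noise_sd = test_noise,
                pixel_scale = if (test_units == "pixels") 500 else NULL)
  )
}

# the full paper-scale validation study is reused by several acceptance
# checks; compute it once per test run
study_cache <- new.env(parent = emptyenv())
cached_study <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(study_cache[[key]])) {
    study_cache[[key]] <- run_validation_study(n_subjects = 16L, seed = seed)
  }
  study_cache[[key]]
}

# amplitude of a sinusoid at known frequency via least squares on the
# interior of the series (avoids edge transients)
fitted_amplitude <- function(x, f, fs, trim = 60) {
  n <- length(x)
  idx <- seq(trim, n - trim)
  t <- (idx - 1) / fs
  fit <- stats::lm(x[idx] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}
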
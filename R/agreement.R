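#' Lin's concordance correlation coefficient
#'
#' The original moment estimator:
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments. Unlike the Pearson correlation, the CCC
#' penalizes location and scale shifts between the two measurement methods as
#' well as decorrelation, so `|ccc| <= |pearson|` on every input. With very
#' low between-subject variance the CCC cannot reach a high value even when
#' the methods agree well, which is why the coefficient of variation is
#' reported alongside it.
#'
#' @param x,y paired numeric vectors (same subjects measured by two methods).
#' @return The concordance correlation coefficient in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pairing error: x and y must have the same length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("lin_ccc needs at least 3 paired observations", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0) {
    warning("CCC undefined: both variances zero and equal means")
    return(NaN)
  }
  2 * sxy / denom
}

#' Heuristic agreement band for a CCC value
#'
#' Maps a concordance correlation coefficient to the conventional verbal
#' band: below 0.10 "none", 0.10-0.40 "weak", 0.41-0.60 "moderate",
#' 0.61-0.80 "strong", 0.81-1.00 "almost complete".
#'
#' @param ccc a CCC value in `[-1, 1]`.
#' @return Character label.
#' @export
ccc_band <- function(ccc) {
  if (is.na(ccc)) return(NA_character_)
  if (abs(ccc) > 1) stop("ccc must lie in [-1, 1]", call. = FALSE)
  if (ccc < 0.10) "none"
  else if (ccc <= 0.40) "weak"
  else if (ccc <= 0.60) "moderate"
  else if (ccc <= 0.80) "strong"
  else "almost complete"
}

#' Coefficient of variation in percent
#'
#' `100 * sd / |mean|`.
#'
#' @param mean,sd summary statistics of one measurement series.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  if (mean == 0) stop("CV undefined for zero mean", call. = FALSE)
  100 * sd / abs(mean)
}

#' Bland-Altman statistics for paired measurements
#'
#' Differences `d = x - y`; limits of agreement (LoA) are
#' `mean(d) +/- 1.96 * sd(d)` (sample SD), the range expected to contain 95%
#' of the differences. Points strictly outside the LoA are counted as
#' outside; ties count as inside.
#'
#' @param x,y paired numeric vectors.
#' @return List with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `n_outside`, `n_total`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pairing error: x and y must have the same length", call. = FALSE)
  }
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("bland_altman needs at least 2 paired differences",
                          call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 1.96 * s
  up <- m + 1.96 * s
  list(mean_diff = m, sd_diff = s, loa_lower = lo, loa_upper = up,
       n_outside = sum(d < lo | d > up), n_total = length(d))
}

#' Distributional assumption checks for paired data
#'
#' Shapiro-Wilk normality p-value per input vector, and a Breusch-Pagan test
#' of homoscedasticity of the paired differences: the squared residuals of
#' `x - y` regressed on `(x + y) / 2` are regressed on the same mean, and the
#' LM statistic `n * R^2` is referred to a chi-square with 1 df. The results
#' annotate the agreement analysis; they never block it.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return List with `shapiro_x`, `shapiro_y`, `breusch_pagan` p-values.
#' @export
assumption_checks <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pairing error: x and y must have the same length", call. = FALSE)
  }
  if (length(x) < 3) stop("insufficient data: need n >= 3", call. = FALSE)
  d <- x - y
  m <- (x + y) / 2
  fit <- stats::lm(d ~ m)
  aux <- stats::lm(I(stats::resid(fit)^2) ~ m)
  r2 <- summary(aux)$r.squared
  stat <- length(d) * r2
  list(
    shapiro_x = stats::shapiro.test(x)$p.value,
    shapiro_y = stats::shapiro.test(y)$p.value,
    breusch_pagan = stats::pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

#' Cross-device agreement table over a cohort
#'
#' Pairs per-subject gait metric values across the reference and test
#' devices and computes, per metric: per-device mean, SD and CV, Lin's CCC
#' with its heuristic band, and Bland-Altman statistics (reference minus
#' test). The result is shaped like the summary tables of a method-comparison
#' study: 7 rows for the sagittal plane, 5 for the frontal.
#'
#' @param metric_sets_ref,metric_sets_test lists of [gait_metric_set()]
#'   objects (one per subject; subjects matched by their `subject` field).
#' @param plane `"sagittal"` or `"frontal"`.
#' @return Data frame of class `agreement_table`, one row per metric.
#' @export
agreement_table <- function(metric_sets_ref, metric_sets_test,
                            plane = c("sagittal", "frontal")) {
  plane <- match.arg(plane)
  to_mat <- function(sets) {
    ids <- vapply(sets, function(s) s$subject, character(1))
    if (anyNA(ids)) ids <- sprintf("S%02d", seq_along(sets))
    m <- do.call(rbind, lapply(sets, function(s) s$metrics[plane_metrics(plane)]))
    rownames(m) <- ids
    m
  }
  ref <- to_mat(metric_sets_ref)
  test <- to_mat(metric_sets_test)
  unmatched <- c(setdiff(rownames(ref), rownames(test)),
                 setdiff(rownames(test), rownames(ref)))
  if (length(unmatched)) {
    stop("pairing error: unmatched subjects: ",
         paste(unique(unmatched), collapse = ", "), call. = FALSE)
  }
  test <- test[rownames(ref), , drop = FALSE]
  if (nrow(ref) < 3) {
    stop("insufficient data: agreement analysis needs at least 3 subjects",
         call. = FALSE)
  }
  rows <- lapply(plane_metrics(plane), function(metric) {
    x <- ref[, metric]; y <- test[, metric]
    ccc <- lin_ccc(x, y)
    ba <- bland_altman(x, y)
    data.frame(
      metric = metric,
      n = length(x),
      mean_ref = mean(x), sd_ref = stats::sd(x),
      mean_test = mean(y), sd_test = stats::sd(y),
      cv_ref = coefficient_of_variation(mean(x), stats::sd(x)),
      cv_test = coefficient_of_variation(mean(y), stats::sd(y)),
      ccc = ccc, ccc_band = ccc_band(ccc),
      mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      n_outside = ba$n_outside
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "plane") <- plane
  class(out) <- c("agreement_table", "data.frame")
  out
}

#' @export
print.agreement_table <- function(x, ...) {
  cat(sprintf("<agreement_table> plane=%s, n=%d subjects\n",
              attr(x, "plane"), x$n[1]))
  disp <- as.data.frame(x)
  num <- vapply(disp, is.numeric, logical(1))
  disp[num] <- lapply(disp[num], round_half_away, digits = 3)
  print(disp, row.names = FALSE)
  invisible(x)
}

# round half away from zero (display convention; internal values stay exact)
round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
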
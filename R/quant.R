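#' Standard-addition linearity fit
#'
#' Ordinary least squares of the NMR-measured concentration (response) on the
#' known added amount (predictor). The report carries the slope and intercept
#' with standard errors, adjusted R-squared, the two-sided t-test p-value of
#' the slope, the residual standard error (RSE) and the prediction error
#' (RSE divided by the mean NMR-measured concentration).
#'
#' @param added Known added concentrations (>= 3 distinct levels).
#' @param measured NMR-measured concentrations, same length.
#' @return A one-row tibble of class `linearity_report`.
#' @export
fit_standard_addition <- function(added, measured) {
  stopifnot(length(added) == length(measured))
  if (length(unique(added)) < 3) stop("need at least 3 distinct added levels")
  if (stats::sd(added) == 0) stop("constant predictor")
  fit <- stats::lm(measured ~ added)
  # noise-free validation inputs legitimately produce exact fits
  s <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  co <- s$coefficients
  out <- tibble::tibble(
    slope = co["added", "Estimate"],
    intercept = co["(Intercept)", "Estimate"],
    se_slope = co["added", "Std. Error"],
    se_intercept = co["(Intercept)", "Std. Error"],
    adj_r_squared = s$adj.r.squared,
    slope_p_value = co["added", "Pr(>|t|)"],
    rse = s$sigma,
    prediction_error = s$sigma / mean(measured),
    n = length(added)
  )
  class(out) <- c("linearity_report", class(out))
  out
}

#' Limit of detection and quantification from a standard-addition fit
#'
#' `LOD = 3.3 * SE(intercept) / slope`; `LOQ = 3.3 * LOD` (so LOQ/LOD is
#' exactly 3.3 for every fit).
#'
#' @param report A [fit_standard_addition()] report.
#' @return Concentration in the units of `added`.
#' @export
lod <- function(report) {
  if (report$slope == 0) stop("zero slope: LOD undefined")
  3.3 * report$se_intercept / report$slope
}

#' @rdname lod
#' @export
loq <- function(report) 3.3 * lod(report)

#' Recovery of the NMR method against a reference assay
#'
#' Per concentration level, recovery is the ratio of replicate means,
#' `100 * mean(NMR) / mean(reference)`, together with the RSD
#' (`100 * sd / mean`) of the NMR replicates. An alternative difference-based
#' definition, `100 * (1 + (mean(NMR) - mean(ref)) / mean(ref))` expressed as
#' `100 - percent difference`, is available via `form = "difference"` (it
#' equals the ratio form; the option reports
#' `100 * (mean(NMR) - mean(ref)) / mean(ref)` as `percent_difference`
#' alongside).
#'
#' @param measured_by_nmr Numeric vector of NMR replicate values.
#' @param reference Numeric vector of reference replicate values.
#' @param level Level labels aligning replicates (recycled if scalar).
#' @param form `"ratio"` (default) or `"difference"`.
#' @return Tibble per level: `recovery_pct`, `rsd_pct`, and
#'   `percent_difference` when requested.
#' @export
recovery <- function(measured_by_nmr, reference, level = "level1",
                     form = c("ratio", "difference")) {
  form <- match.arg(form)
  lev <- rep_len(level, length(measured_by_nmr))
  stopifnot(length(reference) == length(measured_by_nmr))
  df <- tibble::tibble(nmr = measured_by_nmr, ref = reference, level = lev)
  out <- df |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(
      mean_nmr = mean(.data$nmr), mean_ref = mean(.data$ref),
      rsd_pct = 100 * stats::sd(.data$nmr) / mean(.data$nmr),
      n = dplyr::n(), .groups = "drop"
    )
  if (any(out$mean_ref == 0)) stop("zero reference mean")
  out$recovery_pct <- 100 * out$mean_nmr / out$mean_ref
  if (form == "difference")
    out$percent_difference <- 100 * (out$mean_nmr - out$mean_ref) / out$mean_ref
  out
}

#' Bland-Altman agreement between two methods
#'
#' Differences are `a - b` with `a` the NMR method and `b` the reference, so
#' a positive bias means the NMR method reads high. Limits of agreement are
#' `bias +/- 1.96 sd` of the differences.
#'
#' @param method_a,method_b Paired measurements (equal length >= 2).
#' @return List of class `bland_altman`: `bias`, `sd_diff`, `limits`
#'   (length 2), and `pairs` (tibble of per-pair mean and difference).
#' @export
bland_altman <- function(method_a, method_b) {
  if (length(method_a) != length(method_b)) stop("length mismatch")
  if (length(method_a) < 2) stop("need at least 2 pairs")
  d <- method_a - method_b
  bias <- mean(d); sdd <- stats::sd(d)
  structure(list(bias = bias, sd_diff = sdd,
                 limits = c(lower = bias - 1.96 * sdd, upper = bias + 1.96 * sdd),
                 pairs = tibble::tibble(mean = (method_a + method_b) / 2,
                                        difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4g, limits of agreement [%.4g, %.4g] (n = %d)\n",
              x$bias, x$limits[1], x$limits[2], nrow(x$pairs)))
  invisible(x)
}

#' Repeatability RSD of QC peaks
#'
#' Per-peak relative standard deviation (`100 * sd / mean`) over repeated QC
#' runs, with the median RSD and the count and fraction of peaks below the
#' acceptability cutoff.
#'
#' @param qc_table Runs-by-peaks numeric matrix or feature table (>= 3 runs).
#' @param cutoff RSD acceptability cutoff in percent (default 30).
#' @return List of class `repeatability_report`: `per_peak` (tibble),
#'   `median_rsd`, `n_below_cutoff`, `fraction_below_cutoff`, `cutoff`.
#' @export
repeatability_rsd <- function(qc_table, cutoff = 30) {
  m <- if (inherits(qc_table, "feature_table")) ft_values(qc_table) else
    as.matrix(qc_table)
  if (nrow(m) < 3) stop("need at least 3 runs")
  mu <- colMeans(m, na.rm = TRUE)
  if (any(mu == 0)) stop("zero-mean peak: RSD undefined")
  rsd <- 100 * apply(m, 2, stats::sd, na.rm = TRUE) / mu
  per_peak <- tibble::tibble(peak = colnames(m) %||% as.character(seq_along(rsd)),
                             mean = mu, rsd_pct = rsd)
  structure(list(per_peak = per_peak,
                 median_rsd = stats::median(rsd),
                 n_below_cutoff = sum(rsd < cutoff),
                 fraction_below_cutoff = mean(rsd < cutoff),
                 cutoff = cutoff),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("Repeatability: median RSD %.1f%%; %d/%d peaks (%.0f%%) below %g%%\n",
              x$median_rsd, x$n_below_cutoff, nrow(x$per_peak),
              100 * x$fraction_below_cutoff, x$cutoff))
  invisible(x)
}
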
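#' Construct a spectrum
#'
#' A spectrum is a tibble with columns `ppm` (strictly increasing) and
#' `intensity`, plus a metadata attribute (sample id, group, batch, method
#' tag, gradient fraction, spectrometer frequency). A descending axis is
#' reversed into ascending order and the reversal recorded in the metadata.
#'
#' @param ppm Numeric chemical-shift axis.
#' @param intensity Numeric intensities, same length as `ppm`.
#' @param meta Named list of metadata.
#' @return A tibble of class `nmr_spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, meta = list()) {
  stopifnot(length(ppm) == length(intensity), length(ppm) >= 2)
  if (!all(is.finite(ppm)) || !all(is.finite(intensity)))
    stop("spectrum values must be finite")
  d <- diff(ppm)
  if (all(d < 0)) {
    ppm <- rev(ppm); intensity <- rev(intensity)
    meta$axis_reversed <- TRUE
  } else if (!all(d > 0)) {
    stop("ppm axis must be strictly monotone")
  }
  out <- tibble::tibble(ppm = ppm, intensity = intensity)
  attr(out, "meta") <- meta
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  m <- spectrum_meta(x)
  cat(sprintf("<nmr_spectrum> %d points, %.3f..%.3f ppm", nrow(x),
              min(x$ppm), max(x$ppm)))
  if (!is.null(m$sample_id)) cat("  sample:", m$sample_id)
  if (!is.null(m$method)) cat("  method:", m$method)
  cat("\n")
  NextMethod()
}

#' Spectrum metadata
#' @param spec A spectrum.
#' @return Named list of metadata.
#' @export
spectrum_meta <- function(spec) attr(spec, "meta") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

set_meta <- function(spec, ...) {
  attr(spec, "meta") <- utils::modifyList(spectrum_meta(spec), list(...))
  spec
}

spectrum_freq <- function(spec) spectrum_meta(spec)$spectrometer_freq %||% 500.13

#' Write / read a spectrum as two-column text
#'
#' The on-disk format is two whitespace-separated numeric columns
#' (`ppm`, `intensity`) with a header line, plus an optional JSON metadata
#' sidecar at `<path>.json`. Round-tripping preserves values to full double
#' precision. Files with a descending axis are accepted and normalized to
#' ascending order on read (recorded in the metadata).
#'
#' @param spec Spectrum to write.
#' @param path File path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum` returns
#'   the spectrum.
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  df <- tibble::tibble(ppm = spec$ppm, intensity = spec$intensity)
  readr::write_tsv(df, path)
  meta <- spectrum_meta(spec)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (ncol(df) < 2) stop("spectrum file must have two numeric columns")
  if (ncol(df) > 2) stop("spectrum file has more than two columns")
  if (!all(purrr::map_lgl(df, is.numeric))) stop("non-numeric spectrum columns")
  if (anyNA(df)) stop("ragged or missing values in spectrum file")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  new_spectrum(df[[1]], df[[2]], meta = meta)
}

#' Write a cohort of spectra plus a manifest
#'
#' @param cohort An `nmr_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- purrr::imap(cohort$spectra, function(sp, nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    write_spectrum(sp, f)
    m <- spectrum_meta(sp)
    tibble::tibble(file = basename(f), sample_id = m$sample_id %||% nm,
                   group = m$group %||% NA_character_,
                   batch = m$batch %||% NA_integer_,
                   method = m$method %||% NA_character_)
  })
  manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

check_same_axis <- function(a, b) {
  if (nrow(a) != nrow(b) || any(a$ppm != b$ppm))
    stop("spectra must share an identical ppm axis")
}

#' Diffusion-edit subtraction
#'
#' Subtracts the high-gradient LED spectrum from its low-gradient partner,
#' pointwise. Because signal attenuation grows with gradient strength and
#' diffusion coefficient, the high-gradient spectrum contains mostly
#' slow-diffusing macromolecule signal; the difference therefore retains the
#' small-molecule signal while cancelling most of the macromolecule envelope.
#'
#' @param low Spectrum acquired at low gradient fraction (e.g. 2%).
#' @param high Spectrum at high gradient fraction (e.g. 70%), same axis.
#' @param check Verify LED method tags and gradient ordering (default TRUE).
#' @return The difference spectrum, tagged `method = "led_diff"`.
#' @export
subtract_diffusion_pair <- function(low, high, check = TRUE) {
  check_same_axis(low, high)
  if (check) {
    ml <- spectrum_meta(low); mh <- spectrum_meta(high)
    if (!grepl("^led", ml$method %||% "") || !grepl("^led", mh$method %||% ""))
      stop("both spectra must carry an LED method tag")
    gl <- ml$gradient_fraction; gh <- mh$gradient_fraction
    if (is.null(gl) || is.null(gh) || !(gl < gh))
      stop("gradient fractions must satisfy low < high")
  }
  out <- new_spectrum(low$ppm, low$intensity - high$intensity,
                      meta = spectrum_meta(low))
  set_meta(out, method = "led_diff", gradient_fraction = NULL)
}

roll_stat <- function(x, w, fun) {
  zoo::rollapply(x, width = w, FUN = fun, partial = TRUE, align = "center")
}

filter_width_points <- function(spec, width_hz) {
  freq <- spectrum_freq(spec)
  span_ppm <- max(spec$ppm) - min(spec$ppm)
  pts_per_hz <- nrow(spec) / (freq * span_ppm)
  max(3L, as.integer(round(width_hz * pts_per_hz)))
}

#' Remove broad "underground" baseline signals
#'
#' Estimates the broad baseline as a rolling minimum over a window of
#' `filter_width_hz` (converted to points through the spectrometer frequency)
#' followed by a rolling mean of the same width, and subtracts it. Features
#' much broader than the filter width (macromolecule humps) are removed;
#' features much narrower (metabolite peaks) are preserved.
#'
#' @param spec Spectrum.
#' @param filter_width_hz Filter width in Hz (> 0, and at least 3 grid
#'   points wide).
#' @return Baseline-subtracted spectrum.
#' @export
remove_underground <- function(spec, filter_width_hz = 20) {
  if (filter_width_hz <= 0) stop("filter width must be positive")
  w <- filter_width_points(spec, filter_width_hz)
  freq <- spectrum_freq(spec)
  span_ppm <- max(spec$ppm) - min(spec$ppm)
  if (filter_width_hz * nrow(spec) / (freq * span_ppm) < 3)
    stop("filter width narrower than 3 grid points")
  base <- roll_stat(roll_stat(spec$intensity, w, min), w, mean)
  out <- new_spectrum(spec$ppm, spec$intensity - base, meta = spectrum_meta(spec))
  set_meta(out, underground_removed = filter_width_hz)
}

#' Estimate the noise level of a spectrum
#'
#' Robust spread (1.4826 x median absolute deviation) of intensities in a
#' signal-free region, by default everything above 10 ppm.
#'
#' @param spec Spectrum.
#' @param region Length-2 ppm interval.
#' @return Estimated noise standard deviation.
#' @export
estimate_noise <- function(spec, region = c(10, max(spec$ppm))) {
  idx <- spec$ppm >= min(region) & spec$ppm <= max(region)
  if (!any(idx)) stop("noise region does not overlap the ppm axis")
  if (sum(idx) < 50) stop("noise region must contain at least 50 points")
  stats::mad(spec$intensity[idx])
}

locate_peak <- function(spec, peak_ppm, window = 0.05) {
  idx <- which(spec$ppm >= peak_ppm - window & spec$ppm <= peak_ppm + window)
  if (length(idx) < 3) stop("no points near ", peak_ppm, " ppm")
  i <- idx[which.max(spec$intensity[idx])]
  if (i <= 1 || i >= nrow(spec)) stop("peak truncated at spectrum boundary")
  i
}

#' Signal-to-noise ratio at a reference peak
#'
#' Peak height above the local baseline (10% quantile of intensities within
#' +/- 0.2 ppm of the peak) divided by the noise standard deviation estimated
#' in `noise_region`. A noise-free spectrum yields `Inf`.
#'
#' @param spec Spectrum.
#' @param peak_ppm Nominal peak position (default the maleic acid singlet at
#'   6.0 ppm).
#' @param noise_region Signal-free interval for the noise estimate.
#' @return Signal-to-noise ratio.
#' @export
signal_to_noise <- function(spec, peak_ppm = 6.0, noise_region = c(8.50, 9.99)) {
  i <- locate_peak(spec, peak_ppm)
  local <- spec$intensity[spec$ppm >= spec$ppm[i] - 0.2 &
                          spec$ppm <= spec$ppm[i] + 0.2]
  baseline <- stats::quantile(local, 0.1, names = FALSE)
  height <- spec$intensity[i] - baseline
  noise <- estimate_noise(spec, noise_region)
  if (noise == 0) return(Inf)
  height / noise
}

# Linear interpolation of the half-maximum crossing between grid points.
half_crossing <- function(ppm, y, half, from, to, step) {
  i <- from
  while (i != to && y[i + step] > half) i <- i + step
  if (i == to) return(NA_real_)
  j <- i + step
  ppm[i] + (ppm[j] - ppm[i]) * (half - y[i]) / (y[j] - y[i])
}

#' Peak width at half height
#'
#' Finds the maximum near `peak_ppm`, locates the two half-maximum crossings
#' by linear interpolation between bracketing grid points, and converts the
#' ppm width to Hz through the spectrometer frequency.
#'
#' @param spec Spectrum.
#' @param peak_ppm Nominal position of the peak.
#' @param window Search half-window in ppm.
#' @return Width at half height, in Hz.
#' @export
peak_width_half_height <- function(spec, peak_ppm, window = 0.05) {
  i <- locate_peak(spec, peak_ppm, window)
  y <- spec$intensity
  half <- y[i] / 2
  if (y[i] <= 0 || !any(y[seq_len(i - 1)] < half) || !any(y[(i + 1):length(y)] < half))
    stop("peak unresolved or truncated near ", peak_ppm, " ppm")
  left <- half_crossing(spec$ppm, y, half, i, 1L, -1L)
  right <- half_crossing(spec$ppm, y, half, i, length(y), 1L)
  if (is.na(left) || is.na(right)) stop("half-height crossings not found")
  (right - left) * spectrum_freq(spec)
}

# 3-point parabolic interpolation of a maximum's position.
parabolic_apex <- function(ppm, y, i) {
  if (i <= 1 || i >= length(y)) return(ppm[i])
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom == 0) return(ppm[i])
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  ppm[i] + delta * (ppm[i + 1] - ppm[i])
}

#' Reference the chemical-shift axis to a known peak
#'
#' Locates the reference signal near `observed_peak_ppm` (search window
#' +/- 0.1 ppm) and rigidly shifts the axis so it sits at `target_ppm`. If two
#' resolved maxima of comparable height are found in the window (a doublet,
#' like the anomeric glucose doublet at 5.22 ppm), their midpoint is used as
#' the reference point; a single peak is located by parabolic interpolation.
#'
#' @param spec Spectrum.
#' @param observed_peak_ppm Where the reference signal currently sits.
#' @param target_ppm Where it should sit (default 5.22).
#' @param window Search half-window in ppm.
#' @return The shifted spectrum.
#' @export
reference_axis <- function(spec, observed_peak_ppm = 5.22, target_ppm = 5.22,
                           window = 0.1) {
  idx <- which(spec$ppm >= observed_peak_ppm - window &
               spec$ppm <= observed_peak_ppm + window)
  if (length(idx) < 5) stop("reference peak not found within the search window")
  y <- spec$intensity[idx]
  top <- max(y)
  if (top <= 0) stop("reference peak not found within the search window")
  # strict local maxima above half the window maximum
  loc <- idx[which(diff(sign(diff(spec$intensity[idx]))) == -2) + 1]
  loc <- loc[spec$intensity[loc] >= 0.5 * top]
  if (length(loc) >= 2) {
    loc <- loc[order(spec$intensity[loc], decreasing = TRUE)][1:2]
    ref <- mean(purrr::map_dbl(sort(loc), ~parabolic_apex(spec$ppm, spec$intensity, .x)))
  } else {
    i <- idx[which.max(y)]
    ref <- parabolic_apex(spec$ppm, spec$intensity, i)
  }
  out <- new_spectrum(spec$ppm + (target_ppm - ref), spec$intensity,
                      meta = spectrum_meta(spec))
  set_meta(out, referenced_shift = target_ppm - ref)
}
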
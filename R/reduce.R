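#' Default excluded spectral regions
#'
#' Eleven closed ppm intervals covering macromolecule envelopes, water,
#' glucose and urea, 1-methylhistidine (chemical-shift irregularity) and
#' acetate; features whose centers fall inside any of them are dropped from
#' feature tables.
#'
#' @return A tibble with columns `lo` and `hi`.
#' @export
default_exclusion_regions <- function() {
  tibble::tribble(
    ~lo,  ~hi,
    0.73, 0.90,
    1.09, 1.30,
    1.89, 1.92,
    3.17, 3.27,
    3.35, 3.54,
    3.67, 3.92,
    4.39, 5.17,
    5.23, 5.37,
    5.49, 5.98,
    7.01, 7.08,
    7.75, 7.85
  )
}

in_regions <- function(x, regions) {
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(regions))) {
    if (regions$lo[i] > regions$hi[i]) stop("inverted exclusion interval")
    hit <- hit | (x >= regions$lo[i] & x <= regions$hi[i])
  }
  hit
}

#' Equidistant bucketing of one spectrum
#'
#' Splits `range` into contiguous half-open bins `[lo, lo + width)` and sums
#' the point intensities falling in each bin (no per-bucket scaling).
#'
#' @param spec Spectrum.
#' @param width Bucket width in ppm.
#' @param range Length-2 ppm interval to bucket.
#' @return Tibble with columns `ppm` (bucket centers) and `value`.
#' @export
bucket <- function(spec, width = 0.02, range = c(0, 10)) {
  stopifnot(width > 0)
  if (width >= diff(range)) stop("bucket width must be smaller than the range span")
  edges <- seq(range[1], range[2], by = width)
  n_b <- length(edges) - 1L
  idx <- findInterval(spec$ppm, edges, rightmost.closed = FALSE)
  keep <- idx >= 1 & idx <= n_b & spec$ppm < edges[n_b + 1L]
  sums <- rep(0, n_b)
  agg <- tapply(spec$intensity[keep], idx[keep], sum)
  sums[as.integer(names(agg))] <- agg
  tibble::tibble(ppm = edges[-length(edges)] + width / 2, value = sums)
}

#' Drop features inside excluded regions
#'
#' Works on a per-spectrum feature tibble (columns `ppm`, `value`), on a peak
#' tibble (column `position`), or on a wide feature table from
#' [bucket_table()] / [fill_peaks()], dropping any feature whose center lies
#' inside a closed exclusion interval.
#'
#' @param features Feature tibble, peak tibble, or wide feature table.
#' @param regions Tibble of closed intervals (`lo`, `hi`);
#'   [default_exclusion_regions()] by default.
#' @return Same shape as the input, with excluded features removed.
#' @export
exclude_regions <- function(features, regions = default_exclusion_regions()) {
  if (nrow(regions) == 0) return(features)
  if (inherits(features, "feature_table")) {
    pos <- feature_positions(features)
    drop <- names(pos)[in_regions(pos, regions)]
    out <- features[, setdiff(names(features), drop)]
    return(restore_ft(out, features, step = NULL))
  }
  col <- if ("position" %in% names(features)) "position" else "ppm"
  features[!in_regions(features[[col]], regions), ]
}

#' Pick peaks in a spectrum
#'
#' Local maxima whose height above the local baseline (a running median over
#' `baseline_width` ppm, which tracks broad envelopes but not narrow peaks)
#' exceeds `snr_min` times the noise standard deviation; positions are
#' refined by 3-point parabolic interpolation, widths taken between
#' half-height crossings, and areas by trapezoidal integration over
#' +/- 2 FWHM around the apex.
#'
#' @param spec Spectrum (ideally after underground removal).
#' @param snr_min Minimal baseline-corrected peak height in noise-sd units.
#' @param min_separation Maxima closer than this (ppm) are merged, keeping
#'   the taller.
#' @param noise_sd Noise level; estimated with [estimate_noise()] when `NULL`.
#' @param baseline_width Width (ppm) of the running-median local baseline
#'   used in the detection threshold.
#' @return Tibble of peaks: `position`, `height`, `fwhm` (ppm), `area`,
#'   `sample_id`.
#' @export
pick_peaks <- function(spec, snr_min = 3, min_separation = 0.002,
                       noise_sd = NULL, baseline_width = 0.05) {
  if (nrow(spec) < 5) stop("spectrum shorter than 5 points")
  y <- spec$intensity
  if (is.null(noise_sd)) noise_sd <- estimate_noise(spec)
  npt <- length(y)
  dppm0 <- (spec$ppm[npt] - spec$ppm[1]) / (npt - 1)
  k <- as.integer(round(baseline_width / dppm0))
  k <- min(k - (1 - k %% 2), npt - (1 - npt %% 2))   # odd, <= n
  base_local <- if (k >= 3) stats::runmed(y, k, endrule = "median") else
    numeric(npt)
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  cand <- cand[y[cand] - base_local[cand] > snr_min * noise_sd & y[cand] > 0]
  if (length(cand) == 0)
    return(tibble::tibble(position = numeric(), height = numeric(),
                          fwhm = numeric(), area = numeric(),
                          sample_id = character()))
  # merge maxima closer than min_separation, keeping the taller
  cand <- cand[order(spec$ppm[cand])]
  keep <- logical(length(cand))
  i <- 1L
  while (i <= length(cand)) {
    j <- i
    while (j < length(cand) &&
           spec$ppm[cand[j + 1L]] - spec$ppm[cand[j]] < min_separation) j <- j + 1L
    blk <- cand[i:j]
    keep[i - 1L + which.max(y[blk])] <- TRUE
    i <- j + 1L
  }
  cand <- cand[keep]
  n <- length(y)
  dppm <- (spec$ppm[n] - spec$ppm[1]) / (n - 1)
  yc <- y - base_local                    # baseline-corrected intensities
  # prominence: adjacent maxima are one peak unless the valley between them
  # dips below half the smaller apex (kills noise satellites on peak flanks)
  if (length(cand) > 1) {
    kept_idx <- cand[1]
    for (i in cand[-1]) {
      prev <- kept_idx[length(kept_idx)]
      valley <- min(yc[prev:i])
      if (valley > 0.5 * min(yc[prev], yc[i])) {
        if (yc[i] > yc[prev]) kept_idx[length(kept_idx)] <- i
      } else {
        kept_idx <- c(kept_idx, i)
      }
    }
    cand <- kept_idx
  }
  m <- length(cand)
  pos <- height <- fw <- area <- numeric(m)
  for (k in seq_len(m)) {
    i <- cand[k]
    pos[k] <- parabolic_apex(spec$ppm, y, i)
    height[k] <- yc[i]
    half <- yc[i] / 2
    left <- half_crossing(spec$ppm, yc, half, i, max(1L, i - 400L), -1L)
    right <- half_crossing(spec$ppm, yc, half, i, min(n, i + 400L), 1L)
    fw[k] <- if (is.na(left) || is.na(right)) 2 * dppm else right - left
    i0 <- max(1L, i - as.integer(ceiling(2 * fw[k] / dppm)))
    i1 <- min(n, i + as.integer(ceiling(2 * fw[k] / dppm)))
    area[k] <- if (i1 > i0) trapz(spec$ppm[i0:i1], yc[i0:i1]) else yc[i] * dppm
  }
  tibble::tibble(position = pos, height = height, fwhm = fw, area = area,
                 sample_id = spectrum_meta(spec)$sample_id %||% "sample")
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2

#' Group peaks across samples by chemical shift
#'
#' Single-linkage clustering of peak positions, cut at `tol`. Within a group,
#' when a sample contributed more than one peak the member nearest the group
#' median is kept and the others are returned to the pool for re-grouping, so
#' every group holds at most one peak per sample.
#'
#' @param peaks Row-bound peak tibble from [pick_peaks()] (must carry
#'   `sample_id`).
#' @param tol Dendrogram cut height in ppm.
#' @return Tibble of peaks with added `group_id`, `consensus_position`,
#'   `consensus_width` columns.
#' @export
group_peaks <- function(peaks, tol = 0.0075) {
  if (tol <= 0) stop("grouping tolerance must be positive")
  if (nrow(peaks) == 0) return(dplyr::mutate(peaks, group_id = integer()))
  pool <- peaks
  assigned <- list()
  next_id <- 0L
  # single-linkage clustering of 1-d positions cut at `tol` == splitting the
  # sorted positions at gaps > tol
  repeat {
    if (nrow(pool) == 0) break
    ord <- order(pool$position)
    cl <- integer(nrow(pool))
    cl[ord] <- cumsum(c(1L, as.integer(diff(pool$position[ord]) > tol)))
    pool$cl <- cl
    kept <- pool |>
      dplyr::group_by(.data$cl) |>
      dplyr::mutate(dist_to_med = abs(.data$position - stats::median(.data$position))) |>
      dplyr::group_by(.data$cl, .data$sample_id) |>
      dplyr::slice_min(.data$dist_to_med, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    kept$group_id <- next_id + dplyr::dense_rank(kept$cl)
    next_id <- max(kept$group_id)
    assigned[[length(assigned) + 1L]] <-
      dplyr::select(kept, -"dist_to_med", -"cl")
    pool <- dplyr::anti_join(
      pool, kept[c("cl", "sample_id", "position")],
      by = c("cl", "sample_id", "position"))
    pool$cl <- NULL
  }
  out <- dplyr::bind_rows(assigned)
  out |>
    dplyr::group_by(.data$group_id) |>
    dplyr::mutate(consensus_position = stats::median(.data$position),
                  consensus_width = stats::median(.data$fwhm)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$consensus_position, .data$sample_id)
}

#' Fill missing peaks by targeted integration
#'
#' Builds a wide feature table from grouped peaks: where a sample contributed
#' a member peak, its picked area is used; otherwise the sample's spectrum is
#' integrated over `consensus_position +/- consensus_width`. A filled integral
#' below `3 * noise_sd * consensus_width` is recorded as a non-detect
#' (missing), which feeds the downstream presence filter.
#'
#' @param groups Output of [group_peaks()].
#' @param spectra Named list of spectra (names or metadata `sample_id` must
#'   cover the peaks' sample ids).
#' @param noise_sd Optional named vector of per-sample noise levels; estimated
#'   per spectrum when `NULL`.
#' @param samples Optional tibble with `sample_id`, `group`, `batch` used to
#'   label rows; derived from spectrum metadata otherwise.
#' @param baseline_width Width (ppm) of the running-median local baseline
#'   subtracted before integrating, matching [pick_peaks()].
#' @return A wide [feature_table()].
#' @export
fill_peaks <- function(groups, spectra, noise_sd = NULL, samples = NULL,
                       baseline_width = 0.05) {
  ids <- purrr::map_chr(spectra, function(s) spectrum_meta(s)$sample_id %||% "sample")
  names(spectra) <- ids
  if (!all(unique(groups$sample_id) %in% ids))
    stop("peaks reference samples absent from `spectra`")
  if (is.null(noise_sd))
    noise_sd <- purrr::map_dbl(spectra, estimate_noise)
  ginfo <- groups |>
    dplyr::distinct(.data$group_id, .data$consensus_position, .data$consensus_width) |>
    dplyr::arrange(.data$consensus_position)
  vals <- matrix(NA_real_, nrow = length(ids), ncol = nrow(ginfo),
                 dimnames = list(ids, format_ppm(ginfo$consensus_position)))
  for (r in seq_len(nrow(groups)))
    vals[groups$sample_id[r], match(groups$group_id[r], ginfo$group_id)] <-
      groups$area[r]
  for (id in ids) {
    sp <- spectra[[id]]
    n <- nrow(sp)
    ppm0 <- sp$ppm[1]; dppm <- (sp$ppm[n] - ppm0) / (n - 1)
    # integrate above the same running-median local baseline used in picking
    k <- as.integer(round(baseline_width / dppm))
    k <- min(k - (1 - k %% 2), n - (1 - n %% 2))
    yc <- if (k >= 3) sp$intensity - stats::runmed(sp$intensity, k, endrule = "median")
          else sp$intensity
    for (j in which(is.na(vals[id, ]))) {
      lo <- ginfo$consensus_position[j] - ginfo$consensus_width[j]
      hi <- ginfo$consensus_position[j] + ginfo$consensus_width[j]
      i0 <- max(1L, as.integer(ceiling((lo - ppm0) / dppm)) + 1L)
      i1 <- min(n, as.integer(floor((hi - ppm0) / dppm)) + 1L)
      if (i1 > i0) {
        a <- trapz(sp$ppm[i0:i1], yc[i0:i1])
        if (a >= 3 * noise_sd[[id]] * ginfo$consensus_width[j])
          vals[id, j] <- a
      }
    }
  }
  if (is.null(samples))
    samples <- tibble::tibble(
      sample_id = ids,
      group = purrr::map_chr(spectra, function(s)
        as.character(spectrum_meta(s)$group %||% NA)),
      batch = purrr::map_int(spectra, function(s)
        as.integer(spectrum_meta(s)$batch %||% NA))
    )
  feature_table(vals, samples = samples)
}

#' Bucket a set of spectra into a wide feature table
#'
#' @param spectra Named list of spectra.
#' @param width,range Passed to [bucket()].
#' @param samples Optional sample metadata tibble (as in [fill_peaks()]).
#' @return A wide [feature_table()] of bucket sums.
#' @export
bucket_table <- function(spectra, width = 0.02, range = c(0, 10), samples = NULL) {
  ids <- purrr::map_chr(spectra, function(s) spectrum_meta(s)$sample_id %||% "sample")
  rows <- purrr::map(spectra, bucket, width = width, range = range)
  vals <- do.call(rbind, purrr::map(rows, "value"))
  dimnames(vals) <- list(ids, format_ppm(rows[[1]]$ppm))
  if (is.null(samples))
    samples <- tibble::tibble(
      sample_id = ids,
      group = purrr::map_chr(spectra, function(s)
        as.character(spectrum_meta(s)$group %||% NA)),
      batch = purrr::map_int(spectra, function(s)
        as.integer(spectrum_meta(s)$batch %||% NA))
    )
  feature_table(vals, samples = samples)
}
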
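#' Pipeline run configuration
#'
#' Bundles the simulator settings and every processing parameter of the
#' method-comparison and quantification pipelines, each at its protocol
#' default: 20 Hz underground filter, 0.02 ppm buckets over 0-10 ppm, the 11
#' standard exclusion regions, 80% group-wise presence, maleic acid scaling
#' reference at 6.0 ppm, glog calibration on the PA technical replicates,
#' 0.0075 ppm peak-grouping tolerance and VIP threshold 1. The configuration
#' round-trips losslessly through [write_run_config()].
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param design Cohort design for the method comparison.
#' @param components Component set with ground truth.
#' @param acq Acquisition settings.
#' @param underground_width_hz Baseline filter width.
#' @param bucket_width,bucket_range Bucketing parameters.
#' @param exclusions Excluded regions tibble.
#' @param min_frac Presence-filter threshold.
#' @param ref_position Internal-standard ppm.
#' @param replicate_group Group of technical replicates for glog calibration.
#' @param grouping_tol Peak-grouping tolerance (ppm).
#' @param snr_min Peak-picking SNR threshold.
#' @param vip_threshold VIP importance threshold.
#' @param reference_bias Relative bias of the synthetic reference assay used
#'   in the quantification suite.
#' @param reference_cv Replicate CV of the synthetic reference assay.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1,
                       design = cohort_design(),
                       components = default_components(),
                       acq = acquisition_config(),
                       underground_width_hz = 20,
                       bucket_width = 0.02, bucket_range = c(0, 10),
                       exclusions = default_exclusion_regions(),
                       min_frac = 0.8, ref_position = 6.0,
                       replicate_group = "PA",
                       grouping_tol = 0.0075, snr_min = 3,
                       vip_threshold = 1,
                       reference_bias = 0, reference_cv = 0.03) {
  structure(as.list(environment()), class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Scalar and tabular parameters are written as JSON; component sets and
#' designs are stored structurally and rebuilt on read.
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(serialize_config(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$design <- unclass(cfg$design)
  # named atomic vectors must become named lists to keep names in JSON
  cfg$design$n_replicates <- as.list(cfg$design$n_replicates)
  cfg$design$groups <- purrr::map(cfg$design$groups, as.list)
  cfg$acq <- unclass(cfg$acq)
  cfg$components <- purrr::map(cfg$components, function(c) {
    c$multiplet <- as.data.frame(c$multiplet)
    c$concentration_by_group <- as.list(c$concentration_by_group)
    unclass(c)
  })
  cfg
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  rows_to_tibble <- function(x)
    dplyr::bind_rows(purrr::map(x, tibble::as_tibble))
  comps <- purrr::map(raw$components, function(c) {
    if (identical(c$kind, "macromolecule"))
      macromolecule(c$name, rows_to_tibble(c$multiplet), c$diffusion, c$t2,
                    c$cpmg_residual_fraction,
                    unlist(c$concentration_by_group), c$replicate_cv)
    else
      metabolite(c$name, rows_to_tibble(c$multiplet), c$diffusion, c$t2,
                 unlist(c$concentration_by_group), c$replicate_cv)
  })
  run_config(
    seed = raw$seed,
    design = cohort_design(purrr::map(raw$design$groups,
                                      function(g) unlist(g) %||% c()),
                           unlist(raw$design$n_replicates),
                           raw$design$batches, raw$design$batch_effect_sd),
    components = structure(comps, class = "component_set"),
    acq = acquisition_config(raw$acq$n_points, unlist(raw$acq$ppm_range),
                             raw$acq$spectrometer_freq, raw$acq$noise_sd,
                             raw$acq$heteroscedastic_frac),
    underground_width_hz = raw$underground_width_hz,
    bucket_width = raw$bucket_width, bucket_range = unlist(raw$bucket_range),
    exclusions = rows_to_tibble(raw$exclusions),
    min_frac = raw$min_frac, ref_position = raw$ref_position,
    replicate_group = raw$replicate_group,
    grouping_tol = raw$grouping_tol, snr_min = raw$snr_min,
    vip_threshold = raw$vip_threshold,
    reference_bias = raw$reference_bias, reference_cv = raw$reference_cv
  )
}

# Assemble per-method spectra from a simulated cohort: filtered NOESY and
# CPMG pass through; the LED pair is subtracted and baseline-filtered.
method_spectra <- function(cohort, config) {
  ids <- cohort$samples$sample_id
  get <- function(id, m) cohort$spectra[[paste(id, m, sep = ".")]]
  led <- purrr::map(ids, function(id) {
    d <- subtract_diffusion_pair(get(id, "led_02"), get(id, "led_70"))
    remove_underground(d, config$underground_width_hz)
  })
  names(led) <- ids
  list(uf = purrr::set_names(purrr::map(ids, get, m = "noesy_filtered"), ids),
       cpmg = purrr::set_names(purrr::map(ids, get, m = "cpmg"), ids),
       led = led)
}

reduce_spectra <- function(spectra, mode, config) {
  if (mode == "bucket") {
    tab <- bucket_table(spectra, width = config$bucket_width,
                        range = config$bucket_range)
  } else {
    peaks <- dplyr::bind_rows(purrr::map(spectra, pick_peaks,
                                         snr_min = config$snr_min))
    peaks <- exclude_regions(peaks, config$exclusions)
    groups <- group_peaks(peaks, tol = config$grouping_tol)
    tab <- fill_peaks(groups, spectra)
  }
  exclude_regions(tab, config$exclusions)
}

classify_table <- function(tab, config) {
  cond <- condition_features(tab, min_frac = config$min_frac,
                             ref_position = config$ref_position,
                             replicate_group = config$replicate_group)
  cv <- double_cv(cond)
  a_star <- select_components_loocv(cond)
  fit <- suppressWarnings(plsda_fit(cond, A = as.integer(a_star)))
  sig <- vip_scores(fit, threshold = config$vip_threshold)
  list(table = cond, cv = cv, a_star = as.integer(a_star), signature = sig)
}

#' Run the three-method, two-reduction comparison end-to-end
#'
#' Simulates one replicate cohort, acquires it under the filtered-NOESY,
#' CPMG and LED (2%/70% pair) observation models, assembles the
#' diffusion-edit difference, and for every method x reduction mode runs the
#' full chain: reduction, region exclusion, presence filter,
#' internal-standard scaling, PQN, KNN imputation, glog, double
#' cross-validated PLS-DA and VIP extraction. Signatures are compared with
#' the filtered-NOESY gold standard of the same mode.
#'
#' @param config A [run_config()].
#' @param modes Reduction modes to run (`"peaks"`, `"bucket"` or both).
#' @return List of class `method_comparison`: `summary` (tibble of
#'   misclassification counts, selected components, feature counts and
#'   signature overlap with the gold standard), `results` (nested per
#'   method/mode), and the cohort ground truth.
#' @export
run_method_comparison <- function(config = run_config(),
                                  modes = c("peaks", "bucket")) {
  cohort <- simulate_cohort(config$design, config$components,
                            acq = config$acq, seed = config$seed)
  spectra <- method_spectra(cohort, config)
  results <- list()
  rows <- list()
  for (mode in modes) {
    for (method in names(spectra)) {
      tab <- reduce_spectra(spectra[[method]], mode, config)
      res <- tryCatch(classify_table(tab, config),
        error = function(e) stop("stage failure in method '", method,
                                 "', mode '", mode, "': ", conditionMessage(e)))
      results[[mode]][[method]] <- res
    }
    gold <- results[[mode]][["uf"]]$signature
    for (method in names(spectra)) {
      res <- results[[mode]][[method]]
      ov <- signature_overlap(res$signature, gold, match_tol = config$grouping_tol)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method, mode = mode,
        n_features = length(feature_positions(res$table)),
        misclassifications = res$cv$misclassifications,
        components = res$a_star,
        n_important = sum(res$signature$important),
        shared_with_uf = ov$shared
      )
    }
  }
  structure(list(summary = dplyr::bind_rows(rows), results = results,
                 truth = cohort$truth, seed = config$seed),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("Three-method comparison (seed", x$seed, ")\n")
  print(x$summary)
  invisible(x)
}

#' Quantify metabolites in a spectrum against the internal standard
#'
#' Integrates each target's signal over `center +/- halfwidth` and converts
#' to concentration through the maleic acid integral and its known
#' concentration. Identical line shapes make the truncation of Lorentzian
#' tails cancel in the ratio.
#'
#' @param spec Spectrum.
#' @param targets Tibble with columns `metabolite` and `center` (ppm).
#' @param ma_center,ma_conc Internal-standard position and concentration.
#' @param halfwidth Integration half-window in ppm.
#' @return Tibble with `metabolite` and `conc_mM`.
#' @export
quantify_spectrum <- function(spec, targets, ma_center = 6.0, ma_conc = 0.43,
                              halfwidth = 0.01) {
  integrate_at <- function(center) {
    sel <- which(spec$ppm >= center - halfwidth & spec$ppm <= center + halfwidth)
    trapz(spec$ppm[sel], spec$intensity[sel])
  }
  ma_area <- integrate_at(ma_center)
  if (ma_area <= 0) stop("internal-standard integral is non-positive")
  tibble::tibble(metabolite = targets$metabolite,
                 conc_mM = purrr::map_dbl(targets$center, integrate_at) /
                   ma_area * ma_conc)
}

#' Run the full quantification-validation suite
#'
#' Simulates the 15-sample standard-addition series, quantifies every spiked
#' metabolite from its spectrum against the maleic acid standard, fits the
#' standard-addition regressions (linearity, LOD, LOQ), compares NMR
#' concentrations with a synthetic reference assay (recovery per spike
#' level, Bland-Altman agreement), and measures inter- and intra-batch
#' repeatability RSD on peak-reduced QC batches.
#'
#' @param config A [run_config()]; `reference_bias` and `reference_cv`
#'   control the synthetic reference assay.
#' @param qc Standard-addition ground truth from
#'   [standard_addition_components()].
#' @return List of class `quant_report`: `linearity` (per-metabolite tibble
#'   incl. LOD/LOQ), `recovery` (per metabolite x level), `agreement`
#'   (per-metabolite Bland-Altman), `repeatability` (inter and intra), and
#'   `measurements` (long tibble of NMR vs reference concentrations).
#' @export
run_quant_suite <- function(config = run_config(),
                            qc = standard_addition_components()) {
  seeds <- sample_seeds(config$seed, 4)
  sa <- simulate_standard_addition(qc, acq = config$acq, seed = seeds[1])
  targets <- tibble::tibble(
    metabolite = names(qc$stock),
    center = purrr::map_dbl(qc$components, function(c) c$multiplet$center[1])
  )
  measured <- purrr::imap(sa$spectra, function(sp, id) {
    q <- quantify_spectrum(sp, targets, ma_center = 6.0,
                           ma_conc = internal_standard()$concentration)
    q$sample_id <- id
    q
  })
  measured <- dplyr::bind_rows(measured)
  meas <- dplyr::left_join(measured, sa$truth,
                           by = c("sample_id", "metabolite"))
  # synthetic reference assay on total (bound + free) concentration
  set.seed(seeds[2])
  meas$reference_mM <- meas$total_mM * (1 + config$reference_bias) *
    exp(stats::rnorm(nrow(meas), sd = sqrt(log(1 + config$reference_cv^2))))
  linearity <- meas |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(d, key) {
      rep_ <- fit_standard_addition(d$added_mM, d$conc_mM)
      rep_$lod <- lod(rep_); rep_$loq <- loq(rep_)
      rep_
    }) |>
    dplyr::ungroup()
  spiked <- meas[meas$level != "blank", ]
  rec <- spiked |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(d, key)
      recovery(d$conc_mM, d$reference_mM, level = d$level)) |>
    dplyr::ungroup()
  agreement <- meas |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::group_modify(function(d, key) {
      ba <- bland_altman(d$conc_mM, d$reference_mM)
      tibble::tibble(bias = ba$bias, sd_diff = ba$sd_diff,
                     lower = ba$limits[1], upper = ba$limits[2])
    }) |>
    dplyr::ungroup()
  repeatability <- list(
    inter = qc_repeatability(n_batches = 45, per_batch = 1, config, seeds[3]),
    intra = qc_repeatability(n_batches = 1, per_batch = 19, config, seeds[4])
  )
  structure(list(linearity = linearity, recovery = rec, agreement = agreement,
                 repeatability = repeatability, measurements = meas),
            class = "quant_report")
}

qc_repeatability <- function(n_batches, per_batch, config, seed) {
  cohort <- simulate_repeatability(n_batches = n_batches, per_batch = per_batch,
                                   acq = config$acq, seed = seed)
  spectra <- cohort$spectra
  peaks <- dplyr::bind_rows(purrr::map(spectra, pick_peaks,
                                       snr_min = config$snr_min))
  peaks <- exclude_regions(peaks, config$exclusions)
  groups <- group_peaks(peaks, tol = config$grouping_tol)
  tab <- fill_peaks(groups, spectra)
  tab <- presence_filter(tab, min_frac = config$min_frac)
  tab <- scale_to_reference_feature(tab, ref_position = config$ref_position)
  tab <- pqn_normalize(tab)
  repeatability_rsd(tab)
}

#' @export
print.quant_report <- function(x, ...) {
  cat("Quantification validation\n")
  cat(sprintf("  linearity: adj. R^2 %.4f-%.4f over %d metabolites\n",
              min(x$linearity$adj_r_squared), max(x$linearity$adj_r_squared),
              nrow(x$linearity)))
  cat(sprintf("  recovery: mean %.1f%% over %d metabolite x level cells\n",
              mean(x$recovery$recovery_pct), nrow(x$recovery)))
  cat(sprintf("  repeatability: inter median RSD %.1f%%, intra %.1f%%\n",
              x$repeatability$inter$median_rsd, x$repeatability$intra$median_rsd))
  invisible(x)
}
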
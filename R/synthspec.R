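# Observation-model attenuation for a single component.
attenuation_factor <- function(component, obs) {
  is_macro <- identical(component$kind, "macromolecule")
  switch(obs$kind,
    noesy_filtered = if (is_macro) 0 else 1,
    cpmg = {
      f <- exp(-obs$cpmg_loops * obs$echo_spacing / component$t2)
      if (is_macro) f * component$cpmg_residual_fraction else f
    },
    led = exp(-obs$gradient_constant * obs$gradient_fraction^2 *
                component$diffusion)
  )
}

# Sum of Lorentzian lines; `fwhm` arrives in Hz and is converted to ppm.
# Lines have unit height at their center times relative_area, so peak height
# scales as concentration * relative_area and line integral as
# concentration * relative_area * pi * fwhm_ppm / 2.
lorentzian_profile <- function(ppm, multiplet, freq_mhz) {
  out <- numeric(length(ppm))
  for (i in seq_len(nrow(multiplet))) {
    hw <- (multiplet$fwhm[i] / freq_mhz) / 2   # half width in ppm
    out <- out + multiplet$relative_area[i] * hw^2 /
      ((ppm - multiplet$center[i])^2 + hw^2)
  }
  out
}

component_multiplet <- function(component, obs) {
  if (identical(component$kind, "internal_standard")) {
    fw <- if (obs$kind == "noesy_filtered") component$fwhm_filtered
          else component$fwhm_unfiltered
    multiplet_lines(component$center, relative_area = 1, fwhm = fw)
  } else {
    component$multiplet
  }
}

component_concentration <- function(component, group) {
  if (identical(component$kind, "internal_standard"))
    return(component$concentration)
  conc <- component$concentration_by_group
  if (is.null(names(conc)) || length(conc) == 1) return(unname(conc[1]))
  if (!group %in% names(conc))
    stop("component '", component$name, "' has no concentration for group '",
         group, "'")
  unname(conc[[group]])
}

#' Render a single spectrum under an observation model
#'
#' Digitizes the noise-free sum of all component line shapes, weighted by
#' concentration and by the observation model's attenuation factor, then adds
#' iid Gaussian noise of standard deviation `acq$noise_sd` (optionally with an
#' intensity-proportional part, see [acquisition_config()]).
#'
#' @param components A `component_set` (list of specs from [metabolite()],
#'   [macromolecule()]); the internal standard may be included here or passed
#'   separately.
#' @param standard An [internal_standard()] spec, or `NULL`.
#' @param acq An [acquisition_config()].
#' @param obs An [observation_model()].
#' @param group Group label used to look up per-group concentrations.
#' @param concentrations Optional named numeric vector overriding the
#'   per-component concentration (names are component names); used by the
#'   cohort simulator to inject replicate-level ground truth.
#' @param meta Named list merged into the spectrum metadata.
#' @return A [new_spectrum()] tibble with `ppm` and `intensity` columns.
#' @examples
#' acq <- acquisition_config(n_points = 2048, ppm_range = c(0, 10), noise_sd = 0)
#' sp <- render_spectrum(default_components(), internal_standard(), acq,
#'                       observation_model("noesy_filtered"))
#' @export
render_spectrum <- function(components, standard = internal_standard(),
                            acq = acquisition_config(),
                            obs = observation_model("noesy_filtered"),
                            group = "QC", concentrations = NULL, meta = list()) {
  comps <- unclass(components)
  if (!is.null(standard)) comps <- c(comps, list(standard))
  ppm <- seq(acq$ppm_range[1], acq$ppm_range[2], length.out = acq$n_points)
  signal <- numeric(acq$n_points)
  for (comp in comps) {
    mult <- component_multiplet(comp, obs)
    if (any(mult$center < acq$ppm_range[1] | mult$center > acq$ppm_range[2]))
      stop("component '", comp$name, "' has lines outside the ppm range")
    conc <- if (!is.null(concentrations) && comp$name %in% names(concentrations))
      concentrations[[comp$name]] else component_concentration(comp, group)
    att <- attenuation_factor(comp, obs)
    if (conc * att == 0) next
    signal <- signal + conc * att * lorentzian_profile(ppm, mult, acq$spectrometer_freq)
  }
  if (acq$noise_sd > 0 || acq$heteroscedastic_frac > 0) {
    sd_pt <- acq$noise_sd + acq$heteroscedastic_frac * abs(signal)
    signal <- signal + stats::rnorm(acq$n_points, sd = sd_pt)
  }
  method_tag <- if (obs$kind == "led")
    sprintf("led_%02d", round(100 * obs$gradient_fraction)) else obs$kind
  new_spectrum(ppm, signal, meta = utils::modifyList(list(
    sample_id = "sample", group = group, batch = 1L, method = method_tag,
    gradient_fraction = obs$gradient_fraction,
    spectrometer_freq = acq$spectrometer_freq
  ), meta))
}

#' Design of a replicate cohort
#'
#' @param groups Named list mapping group label to a named numeric vector of
#'   concentration multipliers (may be empty for "no change").
#' @param n_replicates Named integer vector of replicate counts per group.
#' @param batches Optional integer vector assigning each sample (in group
#'   order) to a batch; defaults to a single batch.
#' @param batch_effect_sd Log-normal sd of the multiplicative batch effect.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(groups = list(PA = c(), PPGL = c()),
                          n_replicates = c(PA = 9, PPGL = 9),
                          batches = NULL, batch_effect_sd = 0) {
  stopifnot(length(groups) >= 1, all(n_replicates >= 1),
            setequal(names(groups), names(n_replicates)), batch_effect_sd >= 0)
  n <- sum(n_replicates)
  if (is.null(batches)) batches <- rep(1L, n)
  stopifnot(length(batches) == n)
  structure(list(groups = groups, n_replicates = n_replicates,
                 batches = as.integer(batches),
                 batch_effect_sd = batch_effect_sd),
            class = "cohort_design")
}

# Derive per-sample seeds from a master seed so that the stream consumed by
# one sample never shifts another sample's draws.
sample_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a replicate cohort of plasma spectra
#'
#' Draws per-sample metabolite concentrations log-normally around their group
#' means (spread set by each component's `replicate_cv`), then renders one
#' spectrum per sample under every observation model in `obs_list`. Ground
#' truth is recorded alongside. Fully reproducible from `seed`: per-sample
#' substreams are derived from the master seed, so the same seed gives
#' byte-identical output.
#'
#' @param design A [cohort_design()].
#' @param components A component set; see [default_components()].
#' @param standard Internal standard spec.
#' @param acq Acquisition settings.
#' @param obs_list Named list of [observation_model()]s.
#' @param seed Master integer seed.
#' @return A list of class `nmr_cohort` with elements `spectra` (named list,
#'   one entry per sample x observation model, names `"<sample>.<method>"`),
#'   `samples` (tibble: sample_id, group, batch) and `truth` (long tibble of
#'   ground-truth concentrations in mM).
#' @export
simulate_cohort <- function(design = cohort_design(),
                            components = default_components(),
                            standard = internal_standard(),
                            acq = acquisition_config(),
                            obs_list = default_observation_models(),
                            seed = 1) {
  stopifnot(inherits(design, "cohort_design"))
  if (any(design$n_replicates < 1)) stop("every group needs >= 1 replicate")
  samples <- tibble::tibble(
    sample_id = unlist(purrr::imap(as.list(design$n_replicates),
                                   function(n, g) sprintf("%s_%02d", g, seq_len(n)))),
    group = rep(names(design$n_replicates), design$n_replicates),
    batch = design$batches
  )
  n <- nrow(samples)
  seeds <- sample_seeds(seed, n + 1L)
  batch_factor <- rep(1, n)
  if (design$batch_effect_sd > 0) {
    set.seed(seeds[n + 1L])
    per_batch <- exp(stats::rnorm(max(design$batches), sd = design$batch_effect_sd))
    batch_factor <- per_batch[design$batches]
  }
  comp_names <- purrr::map_chr(components, "name")
  truth <- list(); spectra <- list()
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    g <- samples$group[i]
    mult <- design$groups[[g]]
    conc <- purrr::map_dbl(components, function(comp) {
      mu <- component_concentration(comp, g)
      if (comp$name %in% names(mult)) mu <- mu * mult[[comp$name]]
      cv <- comp$replicate_cv
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        mu <- mu * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      }
      mu * batch_factor[i]
    })
    names(conc) <- comp_names
    truth[[i]] <- tibble::tibble(sample_id = samples$sample_id[i], group = g,
                                 batch = samples$batch[i],
                                 component = comp_names, conc_mM = unname(conc))
    for (m in names(obs_list)) {
      sp <- render_spectrum(components, standard, acq, obs_list[[m]],
                            group = g, concentrations = conc,
                            meta = list(sample_id = samples$sample_id[i],
                                        batch = samples$batch[i]))
      spectra[[paste(samples$sample_id[i], m, sep = ".")]] <- sp
    }
  }
  structure(list(spectra = spectra, samples = samples,
                 truth = dplyr::bind_rows(truth), seed = seed),
            class = "nmr_cohort")
}

#' Default observation models for the three-method comparison
#'
#' Filtered NOESY (the ultrafiltration gold standard), CPMG, and the LED pair
#' at 2% and 70% gradient strength whose difference isolates small molecules.
#'
#' @return Named list of [observation_model()]s.
#' @export
default_observation_models <- function() {
  list(
    noesy_filtered = observation_model("noesy_filtered"),
    cpmg = observation_model("cpmg"),
    led_02 = observation_model("led", gradient_fraction = 0.02),
    led_70 = observation_model("led", gradient_fraction = 0.70)
  )
}

#' Components used in the standard-addition experiment
#'
#' Nine compounds of the spiking stock, each rendered as a single narrow
#' singlet at a position clear of the default exclusion regions, with master
#' stock concentrations in mM and an endogenous QC plasma level.
#'
#' @param replicate_cv Replicate coefficient of variation for the endogenous
#'   level.
#' @param bound_fraction Fraction of each metabolite invisible to NMR through
#'   protein binding (applied to total concentration when rendering).
#' @return A list with `components` (component_set), `stock` (named mM
#'   vector), `endogenous` (named mM vector) and `bound_fraction`.
#' @export
standard_addition_components <- function(replicate_cv = 0.02,
                                         bound_fraction = 0) {
  defs <- list(              #   stock mM, endogenous mM, singlet ppm
    glycine       = c(5.54, 0.25, 3.56),
    alanine       = c(2.38, 0.40, 1.47),
    phenylalanine = c(4.77, 0.08, 7.32),
    methionine    = c(0.56, 0.03, 2.13),
    lysine        = c(3.17, 0.18, 3.01),
    threonine     = c(1.14, 0.14, 4.25),
    creatine      = c(1.07, 0.04, 3.03),
    creatinine    = c(0.99, 0.07, 4.05),
    hypoxanthine  = c(0.29, 0.01, 8.20)
  )
  comps <- purrr::imap(defs, function(d, nm)
    metabolite(nm, multiplet_lines(d[3], fwhm = 1),
               concentration_by_group = d[2], replicate_cv = replicate_cv))
  list(components = structure(unname(comps), class = "component_set"),
       stock = purrr::map_dbl(defs, 1),
       endogenous = purrr::map_dbl(defs, 2),
       bound_fraction = bound_fraction)
}

#' Simulate the standard-addition spiking experiment
#'
#' Emulates spiking 100 uL of stock solution (at dilutions 1x, 3x, 5x, 10x,
#' plus a water blank) into 400 uL of QC plasma: the added plasma-phase
#' increment is `stock / dilution / 5` (the 1:5 volumetric ratio of 100 uL
#' into a 500 uL total). With the default levels and `n_reps = 3` this yields
#' the 15-sample design. A protein-bound fraction can be hidden from the NMR
#' observation while remaining in the true totals.
#'
#' @param qc An object from [standard_addition_components()].
#' @param levels Dilution factors of the stock; `Inf` encodes the water blank.
#' @param n_reps Replicates per level.
#' @param acq,obs Acquisition settings and observation model.
#' @param seed Master seed.
#' @return List of class `standard_addition_sim`: `spectra` (named list),
#'   `samples` (tibble with sample_id, level, dilution), and `truth` (long
#'   tibble with added_mM, endogenous_mM, total_mM, nmr_visible_mM per
#'   metabolite and sample).
#' @export
simulate_standard_addition <- function(qc = standard_addition_components(),
                                       levels = c(1, 3, 5, 10, Inf),
                                       n_reps = 3,
                                       acq = acquisition_config(),
                                       obs = observation_model("led", gradient_fraction = 0.02),
                                       seed = 1) {
  if (length(levels) == 0) stop("`levels` must be non-empty")
  if (any(levels <= 0)) stop("dilution factors must be positive")
  stopifnot(n_reps >= 1)
  design <- tidyr::expand_grid(dilution = levels, rep = seq_len(n_reps))
  design$level <- ifelse(is.finite(design$dilution),
                         sprintf("%gx", design$dilution), "blank")
  design$sample_id <- sprintf("SA_%s_%d", design$level, design$rep)
  seeds <- sample_seeds(seed, nrow(design))
  spectra <- list(); truth <- list()
  for (i in seq_len(nrow(design))) {
    set.seed(seeds[i])
    added <- ifelse(is.finite(design$dilution[i]),
                    qc$stock / design$dilution[i] / 5, 0)
    endo <- qc$endogenous
    cvs <- purrr::map_dbl(qc$components, "replicate_cv")
    if (any(cvs > 0)) {
      sdlog <- sqrt(log(1 + cvs^2))
      endo <- endo * stats::rlnorm(length(endo), -sdlog^2 / 2, sdlog)
    }
    total <- endo + added
    visible <- total * (1 - qc$bound_fraction)
    sp <- render_spectrum(qc$components, internal_standard(), acq, obs,
                          concentrations = visible,
                          meta = list(sample_id = design$sample_id[i],
                                      group = design$level[i]))
    spectra[[design$sample_id[i]]] <- sp
    truth[[i]] <- tibble::tibble(sample_id = design$sample_id[i],
                                 level = design$level[i],
                                 metabolite = names(qc$stock),
                                 added_mM = unname(added),
                                 endogenous_mM = unname(endo),
                                 total_mM = unname(total),
                                 nmr_visible_mM = unname(visible))
  }
  structure(list(spectra = spectra,
                 samples = tibble::as_tibble(design[c("sample_id", "level", "dilution", "rep")]),
                 truth = dplyr::bind_rows(truth)),
            class = "standard_addition_sim")
}

#' Simulate QC repeatability batches
#'
#' Defaults emulate the inter-batch design (45 batches of one QC each); set
#' `n_batches = 1, per_batch = 19` for the intra-batch design. Batch effects
#' are multiplicative log-normal factors of sd `batch_effect_sd`.
#'
#' @param n_batches,per_batch Batch layout (both >= 1).
#' @param components,standard,acq,obs Simulation settings; components default
#'   to the QC panel of [default_components()] with `replicate_cv` applied.
#' @param replicate_cv Aliquot-to-aliquot concentration CV.
#' @param batch_effect_sd Log-sd of the multiplicative batch factor.
#' @param seed Master seed.
#' @return An `nmr_cohort` with one group `"QC"` and batch labels.
#' @export
simulate_repeatability <- function(n_batches = 45, per_batch = 1,
                                   components = default_components(groups = "QC",
                                                                   n_differential = 0,
                                                                   replicate_cv = 0.05),
                                   standard = internal_standard(),
                                   acq = acquisition_config(),
                                   obs = observation_model("led", gradient_fraction = 0.02),
                                   replicate_cv = NULL,
                                   batch_effect_sd = 0.05, seed = 1) {
  stopifnot(n_batches >= 1, per_batch >= 1)
  if (!is.null(replicate_cv))
    components <- structure(purrr::map(components, function(c) {
      c$replicate_cv <- replicate_cv; c
    }), class = "component_set")
  n <- n_batches * per_batch
  design <- cohort_design(groups = list(QC = c()), n_replicates = c(QC = n),
                          batches = rep(seq_len(n_batches), each = per_batch),
                          batch_effect_sd = batch_effect_sd)
  simulate_cohort(design, components, standard, acq, list(qc = obs), seed = seed)
}
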
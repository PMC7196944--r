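#' Define a metabolite for the spectral simulator
#'
#' A metabolite is rendered as a sum of Lorentzian lines (its multiplet) whose
#' total intensity scales linearly with concentration. Small molecules diffuse
#' fast (`diffusion` near 1) and relax slowly (`t2` of order 1 s), so they
#' survive CPMG editing and are attenuated away at high gradient strength in
#' LED experiments.
#'
#' @param name Metabolite name.
#' @param multiplet Data frame or tibble with columns `center` (ppm),
#'   `relative_area` (unitless, >= 0) and `fwhm` (Hz, > 0); one row per line.
#' @param diffusion Relative diffusion coefficient in `[0, 1]`; 1 means a
#'   fast-diffusing small molecule.
#' @param t2 Transverse relaxation time in seconds (> 0).
#' @param concentration_by_group Named numeric vector of concentrations (mM)
#'   per sample group; a single unnamed value is used for every group.
#' @param replicate_cv Coefficient of variation (unitless, >= 0) applied
#'   log-normally across replicate samples.
#' @return An object of class `metabolite_spec`.
#' @examples
#' metabolite("alanine", multiplet_lines(1.47, fwhm = 1), concentration_by_group = 0.4)
#' @export
metabolite <- function(name, multiplet, diffusion = 1, t2 = 1,
                       concentration_by_group = 1, replicate_cv = 0) {
  multiplet <- tibble::as_tibble(multiplet)
  stopifnot(
    nrow(multiplet) > 0,
    all(c("center", "relative_area", "fwhm") %in% names(multiplet)),
    all(multiplet$fwhm > 0),
    all(multiplet$relative_area >= 0),
    sum(multiplet$relative_area) > 0,
    diffusion >= 0, diffusion <= 1, t2 > 0, replicate_cv >= 0
  )
  structure(
    list(name = name, multiplet = multiplet, diffusion = diffusion, t2 = t2,
         concentration_by_group = concentration_by_group,
         replicate_cv = replicate_cv, kind = "metabolite"),
    class = c("metabolite_spec", "component_spec")
  )
}

#' Build a multiplet line table
#'
#' @param centers Line positions in ppm.
#' @param relative_area Relative area per line (recycled).
#' @param fwhm Full width at half maximum per line, in Hz (recycled).
#' @return A tibble with columns `center`, `relative_area`, `fwhm`.
#' @export
multiplet_lines <- function(centers, relative_area = 1, fwhm = 1) {
  tibble::tibble(center = centers,
                 relative_area = rep_len(relative_area, length(centers)),
                 fwhm = rep_len(fwhm, length(centers)))
}

#' Define a macromolecule (broad protein/lipoprotein envelope)
#'
#' Macromolecules are rendered as broad Lorentzian humps (FWHM typically
#' >= 100 Hz). They diffuse slowly (`diffusion` near 0), so they survive
#' high-gradient LED acquisition, and they relax fast (short `t2`), so CPMG
#' editing suppresses them down to a configurable residual fraction.
#'
#' @param name Name of the envelope.
#' @param humps Data frame with columns `center` (ppm), `relative_area`,
#'   `fwhm` (Hz, every hump > 20 Hz).
#' @param diffusion Relative diffusion coefficient, near 0.
#' @param t2 Transverse relaxation time in seconds, short.
#' @param cpmg_residual_fraction Fraction in `[0, 1]` of the T2-attenuated
#'   signal that still leaks through CPMG editing.
#' @param concentration_by_group Concentration (mM equivalents) per group.
#' @param replicate_cv Replicate coefficient of variation.
#' @return An object of class `macromolecule_spec`.
#' @export
macromolecule <- function(name, humps, diffusion = 0.002, t2 = 0.05,
                          cpmg_residual_fraction = 0.5,
                          concentration_by_group = 1, replicate_cv = 0) {
  humps <- tibble::as_tibble(humps)
  stopifnot(
    nrow(humps) > 0,
    all(humps$fwhm > 20),
    diffusion >= 0, diffusion <= 1, t2 > 0,
    cpmg_residual_fraction >= 0, cpmg_residual_fraction <= 1
  )
  structure(
    list(name = name, multiplet = humps, diffusion = diffusion, t2 = t2,
         cpmg_residual_fraction = cpmg_residual_fraction,
         concentration_by_group = concentration_by_group,
         replicate_cv = replicate_cv, kind = "macromolecule"),
    class = c("macromolecule_spec", "component_spec")
  )
}

#' Define an internal standard
#'
#' Maleic acid (MA, singlet at 6.0 ppm) keeps a narrow line in both filtered
#' and unfiltered plasma because it does not bind protein; TSP (0.0 ppm)
#' broadens dramatically in unfiltered plasma through protein binding, which
#' the simulator expresses as a larger unfiltered line width.
#'
#' @param name `"MA"` or `"TSP"` (any label accepted).
#' @param center Singlet position in ppm.
#' @param concentration Concentration in mM.
#' @param fwhm_filtered,fwhm_unfiltered Line width (Hz) in filtered vs
#'   unfiltered samples.
#' @param diffusion,t2 Diffusion coefficient and T2 of the free standard.
#' @return An object of class `internal_standard_spec`.
#' @export
internal_standard <- function(name = "MA", center = 6.0, concentration = 0.43,
                              fwhm_filtered = 1, fwhm_unfiltered = 1,
                              diffusion = 1, t2 = 1) {
  stopifnot(concentration > 0, fwhm_filtered > 0, fwhm_unfiltered > 0)
  structure(
    list(name = name, center = center, concentration = concentration,
         fwhm_filtered = fwhm_filtered, fwhm_unfiltered = fwhm_unfiltered,
         diffusion = diffusion, t2 = t2, kind = "internal_standard"),
    class = c("internal_standard_spec", "component_spec")
  )
}

#' Acquisition settings for simulated spectra
#'
#' @param n_points Number of points in the digitized spectrum (>= 2).
#' @param ppm_range Length-2 numeric, min < max.
#' @param spectrometer_freq Proton frequency in MHz; line widths in Hz are
#'   converted to ppm through this value.
#' @param noise_sd Standard deviation of additive Gaussian noise, in intensity
#'   units (0 disables noise).
#' @param heteroscedastic_frac Optional intensity-proportional noise: the
#'   per-point noise sd becomes `noise_sd + heteroscedastic_frac * |signal|`.
#' @return An `acquisition_config` list.
#' @export
acquisition_config <- function(n_points = 16384, ppm_range = c(-0.5, 10.5),
                               spectrometer_freq = 500.13, noise_sd = 0.003,
                               heteroscedastic_frac = 0) {
  stopifnot(n_points >= 2, length(ppm_range) == 2, ppm_range[1] < ppm_range[2],
            noise_sd >= 0, spectrometer_freq > 0, heteroscedastic_frac >= 0)
  structure(list(n_points = as.integer(n_points), ppm_range = ppm_range,
                 spectrometer_freq = spectrometer_freq, noise_sd = noise_sd,
                 heteroscedastic_frac = heteroscedastic_frac),
            class = "acquisition_config")
}

#' Observation model: how an acquisition scheme weights each component
#'
#' Three schemes are supported. `noesy_filtered` emulates ultrafiltration
#' followed by a 1D NOESY: macromolecules are removed physically, metabolites
#' pass unattenuated. `cpmg` applies T2 editing: every component is scaled by
#' `exp(-cpmg_loops * echo_spacing / t2)` and macromolecules are additionally
#' scaled by their `cpmg_residual_fraction`. `led` applies diffusion editing:
#' every component is scaled by `exp(-gradient_constant * gradient_fraction^2 *
#' diffusion)`, so a high-gradient spectrum retains mainly slow-diffusing
#' macromolecules.
#'
#' The default `gradient_constant` is `log(100) / 0.70^2`, which attenuates a
#' `diffusion = 1` metabolite to exactly 1% at 70% gradient strength while
#' leaving it essentially untouched (99.6%) at 2%.
#'
#' @param kind One of `"noesy_filtered"`, `"cpmg"`, `"led"`.
#' @param gradient_fraction Gradient strength as a fraction in `[0, 1]`;
#'   required for (and only for) `kind = "led"`.
#' @param gradient_constant Attenuation scale of the reduced Stejskal-Tanner
#'   factor.
#' @param cpmg_loops Number of CPMG echo loops.
#' @param echo_spacing Echo spacing in seconds.
#' @return An `observation_model` list.
#' @export
observation_model <- function(kind = c("noesy_filtered", "cpmg", "led"),
                              gradient_fraction = NULL,
                              gradient_constant = log(100) / 0.70^2,
                              cpmg_loops = 300, echo_spacing = 4e-4) {
  kind <- match.arg(kind)
  if (kind == "led") {
    if (is.null(gradient_fraction))
      stop("`gradient_fraction` is required for an LED observation model")
    stopifnot(gradient_fraction >= 0, gradient_fraction <= 1)
  } else if (!is.null(gradient_fraction)) {
    stop("`gradient_fraction` only applies to LED observation models")
  }
  stopifnot(gradient_constant > 0, cpmg_loops >= 1, echo_spacing > 0)
  structure(list(kind = kind, gradient_fraction = gradient_fraction,
                 gradient_constant = gradient_constant,
                 cpmg_loops = as.integer(cpmg_loops),
                 echo_spacing = echo_spacing),
            class = "observation_model")
}

#' Default plasma component set
#'
#' A compact ground-truth model of pooled human plasma: an internal maleic
#' acid standard (0.43 mM singlet at 6.0 ppm), the anomeric glucose doublet
#' at 5.22 ppm used for axis referencing, a panel of small-molecule
#' metabolites at millimolar-range plasma concentrations, and a broad
#' protein/lipoprotein envelope. Multiplet positions avoid the default
#' excluded spectral regions so that the differential metabolites survive
#' region exclusion.
#'
#' @param groups Character vector of group labels used for differential
#'   concentrations.
#' @param fold_change Fold change applied to the differential metabolites in
#'   the second group.
#' @param n_differential Number of metabolites carrying the fold change
#'   (taken from the front of the panel, at most 5).
#' @param replicate_cv Replicate coefficient of variation applied to every
#'   metabolite.
#' @return A list of component specs (class `component_set`).
#' @export
default_components <- function(groups = c("PA", "PPGL"), fold_change = 2,
                               n_differential = 5, replicate_cv = 0.1) {
  base <- list(
    # differential panel: centers chosen outside the default exclusion regions
    list("alanine",       1.47, 0.40),
    list("lactate",       1.33, 1.20),
    list("glutamine",     2.44, 0.50),
    list("creatinine",    3.05, 0.07),
    list("histidine",     7.60, 0.09),
    # stable panel
    list("valine",        0.99, 0.22),
    list("isoleucine",    1.01, 0.06),
    list("acetone",       2.22, 0.05),
    list("citrate",       2.55, 0.11),
    list("glycine",       3.56, 0.25),
    list("threonine",     4.25, 0.14),
    list("tyrosine",      6.90, 0.06),
    list("phenylalanine", 7.32, 0.08),
    list("formate",       8.45, 0.03),
    list("hypoxanthine",  8.20, 0.01)
  )
  n_differential <- min(n_differential, 5)
  comps <- purrr::imap(base, function(b, i) {
    conc <- stats::setNames(rep(b[[3]], length(groups)), groups)
    if (i <= n_differential && length(groups) >= 2)
      conc[2] <- conc[2] * fold_change
    metabolite(b[[1]], multiplet_lines(b[[2]], fwhm = 1),
               concentration_by_group = conc, replicate_cv = replicate_cv)
  })
  glucose <- metabolite(
    "glucose-anomeric",
    multiplet_lines(c(5.216, 5.224), relative_area = 0.5, fwhm = 1),
    concentration_by_group = stats::setNames(rep(5, length(groups)), groups),
    replicate_cv = replicate_cv
  )
  macro <- macromolecule(
    "protein-lipoprotein",
    tibble::tibble(center = c(0.85, 1.25, 2.05, 3.20, 5.30),
                   relative_area = c(1.5, 2.0, 1.0, 0.8, 0.5),
                   fwhm = c(150, 200, 150, 120, 180)),
    concentration_by_group = stats::setNames(rep(2, length(groups)), groups),
    replicate_cv = replicate_cv
  )
  structure(c(comps, list(glucose, macro)), class = "component_set")
}
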
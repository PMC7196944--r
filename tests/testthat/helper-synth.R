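# Small, fast fixtures used across test files.

# Fine grid over a narrow window; noise-free unless asked otherwise.
fine_acq <- function(ppm_range = c(5, 7), n_points = 2^14, noise_sd = 0)
  acquisition_config(n_points = n_points, ppm_range = ppm_range,
                     noise_sd = noise_sd)

# One singlet metabolite.
singlet <- function(center, conc = 1, fwhm = 1, name = "met", diffusion = 1,
                    t2 = 1, cv = 0)
  metabolite(name, multiplet_lines(center, fwhm = fwhm),
             diffusion = diffusion, t2 = t2,
             concentration_by_group = conc, replicate_cv = cv)

comp_set <- function(...) structure(list(...), class = "component_set")

# A broad macromolecule hump.
hump <- function(center = 6, fwhm = 200, conc = 1, diffusion = 0.002)
  macromolecule("macro", tibble::tibble(center = center, relative_area = 1,
                                        fwhm = fwhm),
                diffusion = diffusion, concentration_by_group = conc)

# Render a bare spectrum (no internal standard).
render1 <- function(components, acq, obs = observation_model("noesy_filtered"),
                    ...)
  render_spectrum(components, standard = NULL, acq = acq, obs = obs, ...)

# Point-sum integral of a spectrum over an interval.
integral <- function(spec, lo = -Inf, hi = Inf) {
  sel <- spec$ppm >= lo & spec$ppm <= hi
  sum(spec$intensity[sel]) * (spec$ppm[2] - spec$ppm[1])
}

# Wide feature table straight from a matrix.
toy_table <- function(m, groups = rep("A", nrow(m)), positions = NULL) {
  if (is.null(positions)) positions <- seq_len(ncol(m))
  colnames(m) <- sprintf("%.4f", positions)
  feature_table(m, tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(nrow(m))),
    group = groups, batch = 1L))
}

# A linearly separable two-group matrix: one informative direction plus
# isotropic noise.
separable_xy <- function(n_per = 9, p = 10, delta = 4, noise = 1, seed = 42) {
  set.seed(seed)
  y <- rep(c("A", "B"), each = n_per)
  X <- matrix(rnorm(2 * n_per * p, sd = noise), 2 * n_per, p)
  X[y == "B", 1] <- X[y == "B", 1] + delta
  list(X = X, y = y)
}
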
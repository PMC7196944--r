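test_that("spectrum files round-trip at full precision and normalize descending axes", {
  acq <- fine_acq(c(5, 7), n_points = 512, noise_sd = 0.01)
  set.seed(1)
  sp <- render1(comp_set(singlet(6.0)), acq,
                meta = list(sample_id = "s1", group = "QC"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(sp, f)
  back <- read_spectrum(f)
  expect_equal(back$ppm, sp$ppm)
  expect_equal(back$intensity, sp$intensity)
  expect_equal(spectrum_meta(back)$sample_id, "s1")
  # one-column file errors
  writeLines(c("ppm", "1", "2"), f)
  expect_error(read_spectrum(f), "two")
  # descending axis is reversed and flagged
  rev_sp <- new_spectrum(rev(sp$ppm), rev(sp$intensity))
  expect_true(all(diff(rev_sp$ppm) > 0))
  expect_true(spectrum_meta(rev_sp)$axis_reversed)
  expect_error(new_spectrum(c(1, 1, 2), c(0, 0, 0)), "monotone")
})

test_that("diffusion-pair subtraction isolates the fast-diffusing component", {
  acq <- fine_acq(c(0.5, 7))
  met <- comp_set(singlet(1.0, conc = 1, diffusion = 1))
  mac <- comp_set(hump(4.0, conc = 1, diffusion = 0))
  both <- comp_set(singlet(1.0, conc = 1, diffusion = 1),
                   hump(4.0, conc = 1, diffusion = 0))
  obs2 <- observation_model("led", gradient_fraction = 0.02)
  obs70 <- observation_model("led", gradient_fraction = 0.70)
  lo <- render1(both, acq, obs2)
  hi <- render1(both, acq, obs70)
  d <- subtract_diffusion_pair(lo, hi)
  expect_equal(spectrum_meta(d)$method, "led_diff")
  # ground-truth integrals from single-component renders
  met_ref <- integral(render1(met, acq, observation_model("noesy_filtered")),
                      0.5, 1.5)
  mac_ref <- integral(render1(mac, acq, observation_model("led",
                                                          gradient_fraction = 0.02)),
                      2.5, 5.5)
  expect_gte(integral(d, 0.5, 1.5) / met_ref, 0.98)
  expect_lte(integral(d, 2.5, 5.5) / mac_ref, 0.02)
  # identical pair -> all zero
  z <- subtract_diffusion_pair(lo, lo, check = FALSE)
  expect_true(all(z$intensity == 0))
  # axis mismatch and tag violations
  expect_error(subtract_diffusion_pair(lo, hi[-1, ]), "axis")
  expect_error(subtract_diffusion_pair(hi, lo), "low < high")
  uf <- render1(both, acq)
  expect_error(subtract_diffusion_pair(uf, hi), "LED")
})

test_that("subtraction is linear in a common offset", {
  acq <- fine_acq(c(5, 7), n_points = 512)
  a <- render1(comp_set(singlet(6.0)), acq,
               observation_model("led", gradient_fraction = 0.02))
  b <- render1(comp_set(singlet(6.0)), acq,
               observation_model("led", gradient_fraction = 0.70))
  shift <- function(s, c) new_spectrum(s$ppm, s$intensity + c,
                                       meta = spectrum_meta(s))
  d0 <- subtract_diffusion_pair(a, b)
  d1 <- subtract_diffusion_pair(shift(a, 5), shift(b, 5))
  expect_equal(d1$intensity, d0$intensity, tolerance = 1e-12)
})

test_that("underground removal flattens broad humps and keeps narrow peaks", {
  acq <- fine_acq(c(0, 10), n_points = 2^15)
  # constant offset is pure underground
  flat <- new_spectrum(seq(0, 10, length.out = 4096), rep(3, 4096),
                       meta = list(spectrometer_freq = 500.13))
  out <- remove_underground(flat, 20)
  expect_lt(max(abs(out$intensity)), 1e-9)
  # 1-Hz line on a 200-Hz hump: narrow preserved within 10%, hump down >90%
  narrow <- render1(comp_set(singlet(5.0, fwhm = 1)), acq)
  broad <- render1(comp_set(hump(5.0, fwhm = 200)), acq,
                   observation_model("led", gradient_fraction = 0.02))
  both <- new_spectrum(narrow$ppm, narrow$intensity + broad$intensity,
                       meta = list(spectrometer_freq = 500.13))
  cleaned <- remove_underground(both, 20)
  peak_region <- abs(cleaned$ppm - 5) < 0.005
  expect_equal(max(cleaned$intensity[peak_region]), max(narrow$intensity),
               tolerance = 0.1)
  hump_only <- remove_underground(
    new_spectrum(broad$ppm, broad$intensity,
                 meta = list(spectrometer_freq = 500.13)), 20)
  expect_lt(max(hump_only$intensity), 0.1 * max(broad$intensity))
  expect_error(remove_underground(both, 0), "positive")
  expect_error(remove_underground(flat, 0.001), "3 grid points")
})

test_that("underground removal is idempotent within 1% of the peak scale", {
  acq <- fine_acq(c(0, 10), n_points = 2^15)
  sp <- render1(comp_set(singlet(5.0), hump(4.0, fwhm = 200)), acq)
  once <- remove_underground(sp, 20)
  twice <- remove_underground(once, 20)
  expect_lt(max(abs(twice$intensity - once$intensity)),
            0.01 * max(once$intensity))
})

test_that("noise estimation is robust and region-checked", {
  set.seed(7)
  ppm <- seq(0, 12, length.out = 6000)
  sp <- new_spectrum(ppm, rnorm(6000, sd = 0.5))
  expect_equal(estimate_noise(sp, c(10, 12)), 0.5, tolerance = 0.15)
  zero <- new_spectrum(ppm, rep(0, 6000))
  expect_equal(estimate_noise(zero, c(10, 12)), 0)
  expect_error(estimate_noise(sp, c(20, 30)), "overlap")
})

test_that("signal-to-noise is scale invariant and matches construction", {
  set.seed(21)
  acq <- acquisition_config(n_points = 2^14, ppm_range = c(0, 10.5),
                            noise_sd = 2)
  sp <- render1(comp_set(singlet(6.0, conc = 100, fwhm = 2)), acq)
  snr <- signal_to_noise(sp, 6.0)
  expect_equal(snr, 100 / 2, tolerance = 0.2)
  scaled <- new_spectrum(sp$ppm, 7 * sp$intensity, meta = spectrum_meta(sp))
  expect_equal(signal_to_noise(scaled, 6.0), snr, tolerance = 1e-9)
  # exactly zero noise region -> infinite ratio sentinel
  ppm <- seq(0, 10.5, length.out = 2^14)
  y <- ifelse(abs(ppm - 6) < 0.5, 100 / (1 + ((ppm - 6) / 0.01)^2), 0)
  clean <- new_spectrum(ppm, y)
  expect_identical(signal_to_noise(clean, 6.0), Inf)
})

test_that("peak width at half height recovers rendered line widths", {
  acq <- fine_acq(c(5.5, 6.5), n_points = 2^15)
  sp <- render1(comp_set(singlet(6.0, fwhm = 1)), acq)
  expect_equal(peak_width_half_height(sp, 6.0), 1.0, tolerance = 0.05)
  flat <- new_spectrum(seq(5.5, 6.5, length.out = 1000), rep(1, 1000))
  expect_error(peak_width_half_height(flat, 6.0), "unresolved|truncated")
})

test_that("TSP line widths reproduce the 11:1 unfiltered:filtered broadening", {
  acq <- fine_acq(c(-1, 1), n_points = 2^15)
  tsp <- internal_standard("TSP", center = 0.0, concentration = 1,
                           fwhm_filtered = 1, fwhm_unfiltered = 11)
  filt <- render_spectrum(comp_set(), tsp, acq, observation_model("noesy_filtered"))
  unf <- render_spectrum(comp_set(), tsp, acq,
                         observation_model("led", gradient_fraction = 0.02))
  ratio <- peak_width_half_height(unf, 0) / peak_width_half_height(filt, 0)
  expect_equal(ratio, 11, tolerance = 0.1 * 11)
})

test_that("axis referencing shifts single peaks and doublet midpoints to target", {
  acq <- fine_acq(c(4.5, 6.5), n_points = 2^14)
  step <- diff(acq$ppm_range) / (acq$n_points - 1)
  sp <- render1(comp_set(singlet(5.23)), acq)     # pre-shifted by +0.01
  ref <- reference_axis(sp, observed_peak_ppm = 5.23, target_ppm = 5.22)
  expect_equal(ref$ppm[which.max(ref$intensity)], 5.22, tolerance = step * 1.5)
  again <- reference_axis(ref, observed_peak_ppm = 5.22, target_ppm = 5.22)
  expect_equal(again$ppm, ref$ppm, tolerance = step)
  # doublet at 5.21 / 5.23 is referenced by its midpoint
  dbl <- render1(comp_set(metabolite("glc", multiplet_lines(c(5.21, 5.23),
                                                            fwhm = 1))), acq)
  refd <- reference_axis(dbl, observed_peak_ppm = 5.22, target_ppm = 5.22)
  apexes <- refd$ppm[order(refd$intensity, decreasing = TRUE)[1:2]]
  expect_equal(mean(range(apexes)), 5.22, tolerance = step * 1.5)
  expect_error(reference_axis(sp, observed_peak_ppm = 8), "search window|near")
})
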
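---
title: "Untargeted plasma 1H-NMR metabolomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted plasma 1H-NMR metabolomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmanmr)
```

## The problem

Blood plasma contains small-molecule metabolites dissolved in a matrix of
proteins and lipoproteins. In 1D proton NMR the macromolecules contribute
broad, intense envelopes that swamp and distort the narrow metabolite
signals, so any untargeted plasma protocol must suppress them. Three routes
are in common use:

* **Ultrafiltration (UF)** — physically remove macromolecules through a
  10 kDa filter and acquire a plain 1D NOESY spectrum. Clean, but laborious
  and it perturbs metabolite recovery.
* **CPMG** — a spin-echo train attenuates signals in proportion to
  `exp(-t_echo / T2)`; macromolecules relax fast (short T2) and fade, but a
  residual fraction always leaks through.
* **Diffusion editing (LED)** — signal attenuation grows with gradient
  strength and the molecular diffusion coefficient. A spectrum at high
  gradient strength (70%) retains mainly slow-diffusing macromolecules;
  subtracting it from a low-gradient (2%) twin leaves the small molecules.

This package implements the complete LED-based workflow together with the
CPMG and UF comparators: a ground-truth simulator of all three observation
models, the diffusion-edit subtraction and baseline ("underground")
workflow, spectral reduction to feature tables, the conditioning chain,
PLS-DA classification under double cross-validation with VIP signatures,
and a quantification-validation suite (standard addition, LOD/LOQ,
recovery, Bland–Altman, repeatability).

## The simulator

Spectra are rendered as sums of Lorentzian lines. Each metabolite is a
multiplet with centers in ppm and widths in Hz (converted to ppm through
the 500.13 MHz spectrometer frequency); each macromolecule is a set of
broad humps (FWHM ≥ 100 Hz). A spectrum under observation model *o* is

    I(d) = sum_c conc_c * A_o(c) * L_c(d) + e,   e ~ N(0, noise_sd^2)

with attenuation factors

* filtered NOESY: `A = 1` for metabolites, `A = 0` for macromolecules
  (the filter removes them physically);
* CPMG: `A = exp(-n_loops * echo_spacing / T2)`, macromolecules further
  multiplied by a configurable `cpmg_residual_fraction`;
* LED: `A = exp(-c * f^2 * D)`, a reduced Stejskal–Tanner form with a
  single instrument constant `c`, gradient fraction `f` and relative
  diffusion coefficient `D` in [0, 1].

The default instrument constant is `c = ln(100) / 0.70^2`, chosen so a
`D = 1` metabolite survives at exactly 1% at 70% gradient strength while
keeping 99.6% of its signal at 2%. Under the exponential form it is not
possible to push the 2% loss below 0.1% while still attenuating 99% at
70%; we prioritized the high-gradient end because the subtraction quality
depends on it. Macromolecules default to `D = 0.002`, which keeps more
than 99% of their signal at 70% and lets the subtraction cancel them to
below 1%.

No diffusion coefficients or T2 values are reported for the study this
emulates; the defaults (metabolite T2 ≈ 1 s, macromolecule T2 = 0.05 s
with 300 CPMG loops at 0.4 ms echo spacing) are physically plausible
placeholders chosen once, and every one is a config parameter, not a
claim. The CPMG residual fraction (default 0.5, i.e. ≈ 4.5% net
macromolecule leakage) deliberately makes CPMG suppression worse than the
LED subtraction, reproducing the qualitative ordering observed on real
plasma.

Replicate variability is log-normal (it keeps concentrations positive):
a CV of 0.1 means `sd(log conc) = sqrt(log(1 + 0.01))`. Noise is iid
Gaussian per point; an optional intensity-proportional term
(`heteroscedastic_frac`) produces the mixed additive/multiplicative error
structure that the glog transform is designed for. One master seed spawns
per-sample substreams, so cohorts are byte-reproducible and changing one
sample's parameters cannot shift another's draws.

The default cohort emulates a two-group technical-replicate design: plasma
pooled per disease group (primary aldosteronism, PA, and
pheochromocytoma/paraganglioma, PPGL), aliquoted 9 times each, with 2-fold
concentration changes on 5 metabolites at 10% replicate CV. The default
standard-addition design spikes 100 uL of a 9-compound stock (and its 3x,
5x, 10x dilutions, plus a water blank) into 400 uL QC plasma — three
replicates per level, 15 samples, added increment `stock / dilution / 5`.
Repeatability designs default to 45 batches of one QC (inter-batch) and
one batch of 19 QCs (intra-batch).

What the simulator does *not* emulate: J-coupling evolution, pH-dependent
chemical-shift wander, water/solvent suppression artifacts, phasing errors,
and sample-to-sample shift misalignment (the emulated protocol relies on
buffering and omits alignment, and so do we). Passing tests therefore
demonstrate the correctness of the processing chain on spectra whose
line positions are stable; they do not certify performance on poorly
buffered real data.

## Processing design choices

**Underground removal.** The reference workflow delegates broad-baseline
removal to a proprietary tool with a 20 Hz filter width; the algorithm is
unpublished. We implement it as a rolling minimum over a window of
20 Hz (converted to grid points), smoothed by a rolling mean of the same
width, then subtracted. Features much broader than the window are removed,
features much narrower survive; the operation is idempotent to within 1%
of the peak scale. This surrogate is validated only by its contract, not
by algorithm identity.

**Noise and S/N.** Noise is estimated as 1.4826 × the median absolute
deviation of a signal-free region (above 10 ppm by default) — robust to
stray peaks. Signal-to-noise uses the maleic acid singlet at 6.0 ppm and
the 8.50–9.99 ppm noise window; peak height is measured above a local
baseline (the 10% quantile in a ±0.2 ppm window).

**Peak picking.** Instead of the cited wavelet detector we use local
maxima with three safeguards: (1) the detection threshold
`height > snr_min * noise` is applied to the height *above a running-median
local baseline* (window 0.05 ppm), so ripple riding on macromolecule humps
is not promoted to peaks; (2) maxima closer than `min_separation` merge;
(3) adjacent maxima whose inter-apex valley stays above half the smaller
apex are treated as one peak — this removes noise satellites on the flanks
of tall peaks while preserving genuine doublets (whose valley is deep).
Positions are refined by 3-point parabolic interpolation, widths come from
linearly interpolated half-height crossings, and areas from trapezoidal
integration of the baseline-corrected intensity over ±2 FWHM. Correctness
is defined by contract tests (position/width/area recovery on rendered
lines), not by algorithm identity with the wavelet detector.

**Grouping and filling.** Peak positions are clustered by single linkage
cut at 0.0075 ppm — about half a bucket width, keeping the two reduction
modes comparable. For 1-D positions that cut is exactly "split the sorted
positions at gaps larger than the tolerance", which is how it is computed
(the O(n²) dendrogram would not scale to the ~50k raw peaks of a cohort).
When a sample contributes two peaks to one group, the one nearest the
group median stays and the rest re-enter the pool for another round.
Filling integrates the sample's baseline-corrected spectrum over the group
consensus position ± consensus width; integrals below `3 * noise * width`
are recorded as non-detects, feeding the presence filter. Region exclusion
(11 closed intervals covering macromolecule envelopes, water, glucose and
urea, 1-methylhistidine and acetate) is applied to picked peaks by center
position before grouping.

**Conditioning chain.** The order is fixed and enforced: presence filter →
internal-standard scaling → PQN → KNN imputation → glog. The 80% presence
rule is read class-wise ("present in ≥ 80% of at least one group"); the
stricter both-groups reading is exposed as `rule = "all_groups"`. Maleic
acid (0.43 mM, singlet at 6.0 ppm) is the scaling reference: it does not
bind protein, so its line stays narrow in unfiltered plasma (unlike TSP,
which broadens ~11-fold). PQN divides each sample by the median quotient
to the feature-wise median reference, ignoring non-detects; it is exactly
idempotent when inter-sample variation is multiplicative (its model), and
only approximately otherwise. KNN imputation treats *features* as
neighbours (the convention of the reference implementation, k = 10), with
root-mean-square distance over co-observed samples, inverse-distance
weights, uniform weights among zero-distance neighbours, and a
feature-mean fallback when fewer than k neighbours are observed.

**glog calibration.** The transform `g(x) = ln(x + sqrt(x^2 + lambda))`
interpolates between `ln(2x)` (lambda → 0) and a linear map (large
lambda). Lambda is calibrated on a technical-replicate group by minimizing
the heterogeneity of per-feature variances after transformation (sd of
variances over their mean), searched on `log(lambda)` over
`[1e-12, 1e12] * median(value)^2`. This is a variance-stabilization
surrogate for the reference implementation's maximum-likelihood fit; an
exhaustive grid search over 200 log-spaced values serves as its test
oracle, and the two agree to within an order of magnitude on
mixed-error data (the objective is flat near its minimum, so the precise
lambda matters little).

## Classification

PLS-DA uses NIPALS-style sequential extraction on the mean-centered matrix
against a centered ±1-coded class column (for two classes this is
equivalent to two-column dummy coding). No variance scaling is applied by
default — only mean-centering — matching the emulated protocol;
unit-variance scaling is available but off. Prediction is by the sign of
the continuous regression estimate, with an exact 0 (e.g. a degenerate
constant-feature fold) assigned to the class coded −1 — a documented,
tested tie rule. The component count is selected by leave-one-out
cross-validation (smallest count attaining the minimal error, capped at
`min(10, n − 2)`; the emulated protocol states no cap), and the headline
error comes from double cross-validation: an outer leave-one-out loop that
re-selects the component count by inner leave-one-out on each fold before
classifying the held-out sample. Feature importance uses VIP scores
(`sum(VIP^2) = p` by construction) with the conventional importance
threshold of 1 (the emulated study does not state its threshold; ours is
configurable). Signatures from different acquisition methods are compared
by greedy nearest-position matching of important features within a ppm
tolerance. Filtering and exclusion are performed once before
cross-validation, matching the described sequence (the alternative —
re-filtering inside each fold — would leak no labels either way since the
filters are unsupervised, but it would make the feature universes
fold-dependent).

## Quantification validation

Standard-addition regressions put the NMR-measured concentration on the
left and the known added amount on the right — the standard-addition
convention, and the one that makes "prediction error = RSE / mean NMR
concentration" dimensionally natural. `LOD = 3.3 * SE(intercept) / slope`,
`LOQ = 3.3 * LOD` exactly. Recovery is the ratio of replicate means × 100
per spike level (the percent-difference form is exposed as an option);
Bland–Altman differences are NMR − reference, so a positive bias means
NMR reads high; limits of agreement use the 1.96 normal multiplier.
Repeatability reports per-peak RSD (100·sd/mean), the median RSD and the
count and fraction of peaks under the 30% acceptability cutoff. The
repeatability chain applies the presence filter before scaling and PQN:
"peaks found in the QC samples" are those detected in at least 80% of
runs — sporadic fill-in groups are picking artifacts whose RSD is
undefined.

In-package spectral quantification integrates each target over its center
± 0.01 ppm and converts through the maleic acid integral; identical line
shapes make the truncated Lorentzian tails cancel in the ratio. The
default standard-addition panel deliberately keeps the
lysine/creatine/creatinine cluster at 3.01/3.03/3.05 ppm: their residual
tail overlap reads a few percent high, reproducing the well-known
convolution bias of real plasma (recovery above 100% for convoluted
signals) while well-separated singlets recover exactly.

The reference assay used for recovery and agreement is synthetic: it
reads the *total* (free + protein-bound) concentration with configurable
relative bias and replicate CV. A protein-bound fraction hidden from the
NMR observation therefore depresses recovery by exactly that fraction —
the mechanism behind sub-100% recovery in real plasma.

## Problem sizes and numerical notes

Default spectra use 16384 points over −0.5 to 10.5 ppm (0.34 Hz per
point), enough to resolve 1 Hz lines for picking while keeping cohort
simulations light; width-measurement examples use finer local grids.
Bucket intervals are half-open and exclusion intervals closed, preventing
double counting while honouring the inclusive phrasing of the exclusion
list. Degenerate inputs are handled explicitly: constant replicate blocks
return the lambda search's lower bound with a warning; constant feature
matrices yield prediction 0 and the tie-rule class; zero-slope fits refuse
to compute an LOD. Acceptance-level checks run the full pipeline on the
default 9 + 9 cohort and the 15-sample spiking design; statistical
calibration checks (CI coverage, permutation null) use 100 seeded
repeats.

## Known limitations

* The underground-removal and peak-detection algorithms are contract-level
  surrogates for proprietary or wavelet-based tools; they match behavior,
  not implementation.
* The simulator's spectra are far sparser than real plasma (tens of
  singlets, not hundreds of overlapping multiplets), which flatters the
  bucket-mode tables less than the peak-mode ones: on sparse spectra many
  buckets contain pure noise and PQN factors degrade, which is visible as
  misclassifications in bucket-mode models — qualitatively the same
  weakness that motivated peak tables on real data.
* PQN idempotence and exact recovery hold in the regimes of their models
  (multiplicative dilution; separated singlets); real data will sit near,
  not on, those regimes.
* Chemical-shift misalignment is out of scope; on unbuffered data a shift
  alignment step would be required before grouping.
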
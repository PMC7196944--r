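# plasmanmr

Untargeted plasma ¹H-NMR metabolomics with diffusion-edited macromolecule
suppression: simulation, preprocessing, classification and quantification
validation in one tested pipeline.

## The problem

Plasma NMR spectra are dominated by broad protein and lipoprotein signals
that obscure the narrow metabolite resonances. The workflow implemented
here suppresses them by **diffusion editing**: in an LED experiment the
signal of a component with relative diffusion coefficient *D* acquired at
gradient fraction *f* is attenuated by

    A(f, D) = exp(−c · f² · D)

so a 70%-gradient spectrum retains mainly slow-diffusing macromolecules
(*D* ≈ 0) and subtracting it from its 2%-gradient twin leaves the small
molecules. The package provides this workflow end to end, alongside its
two standard comparators — CPMG relaxation editing
(`A = exp(−n·τ/T2)`) and ultrafiltration + NOESY — so the three methods
can be compared on simulated cohorts with known ground truth:

* a **spectral simulator** (Lorentzian line shapes, per-group
  concentrations, log-normal replicate variability, batch effects, all
  three observation models, deterministic seeding);
* **spectral tools**: LED pair subtraction, broad-baseline
  ("underground") removal at 20 Hz, noise estimation (1.4826·MAD),
  signal-to-noise, peak width at half height, axis referencing to the
  glucose doublet at 5.22 ppm;
* **reduction** to feature tables by 0.02 ppm bucketing or peak
  picking/grouping/filling, with the standard 11 excluded regions;
* **conditioning**: group-wise 80% presence filter, scaling to the maleic
  acid internal standard (6.0 ppm), probabilistic quotient normalization,
  KNN imputation, generalized log transform with λ calibrated on
  technical replicates;
* **classification**: PCA, two-class PLS-DA (NIPALS), leave-one-out
  component selection, double (nested LOO) cross-validation, VIP
  signatures (`ΣVIP² = p`) and cross-method signature overlap;
* **quantification validation**: standard-addition linearity,
  `LOD = 3.3·SE(intercept)/slope`, `LOQ = 3.3·LOD`, recovery against a
  reference assay, Bland–Altman agreement, inter-/intra-batch
  repeatability RSD.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

Simulate the default two-group cohort (9 + 9 technical replicates, 2-fold
changes on 5 metabolites at 10% replicate CV), acquire it under all three
observation models, and run the full peak-mode comparison:

```r
library(plasmanmr)

cfg <- run_config(seed = 1)
mc  <- run_method_comparison(cfg, modes = "peaks")
mc$summary
#> # A tibble: 3 × 7
#>   method mode  n_features misclassifications components n_important shared_with_uf
#>   <chr>  <chr>      <int>              <int>      <int>       <int>          <int>
#> 1 uf     peaks         20                  0          1           5              5
#> 2 cpmg   peaks         18                  0          1           6              5
#> 3 led    peaks         20                  0          1           6              5
```

All three methods separate the groups without a single double-CV
misclassification using one latent variable, and the VIP-flagged features
are led by the five metabolites that truly differ — the LED and CPMG
signatures each share all five with the ultrafiltration gold standard.

The quantification suite simulates the 15-sample standard-addition series
(four spike levels × 3 replicates + 3 blanks), quantifies each metabolite
against the maleic acid standard, and validates against a synthetic
reference assay and QC repeatability batches:

```r
qr <- run_quant_suite(cfg)
qr
#> Quantification validation
#>   linearity: adj. R^2 0.9989-0.9999 over 9 metabolites
#>   recovery: mean 100.9% over 36 metabolite x level cells
#>   repeatability: inter median RSD 7.2%, intra 6.6%

subset(qr$linearity, metabolite == "glycine")
#> glycine: slope 1.007, adj R2 0.9993, LOD 0.0127 mM, LOQ 0.0420 mM
```

Slopes near 1 mean the added amounts are recovered quantitatively;
recoveries just above 100% for creatine and lysine reproduce the familiar
convolution bias of the 3.01/3.03/3.05 ppm cluster. A command-line front
end is installed as `exec/plasmanmr` (`simulate-cohort`,
`run-comparison`, `run-quant`, ...).

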
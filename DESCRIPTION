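Package: plasmanmr
Title: Untargeted Plasma 1H-NMR Metabolomics Pipeline with Diffusion-Edited
    Macromolecule Suppression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, preprocessing, multivariate classification and
    quantification assessment for one-dimensional plasma proton NMR
    metabolomics. Provides an observation-model simulator for filtered
    NOESY, CPMG relaxation-edited and LED diffusion-edited acquisition of
    plasma spectra with known ground truth; diffusion-edit subtraction and
    broad-baseline ("underground") removal; spectral reduction by
    equidistant bucketing or peak picking, grouping and filling; feature
    conditioning by group-wise presence filtering, internal-standard
    scaling, probabilistic quotient normalization, k-nearest-neighbour
    imputation and the generalized log transform with replicate-calibrated
    lambda; two-class PLS-DA under double (nested leave-one-out)
    cross-validation with VIP signatures; and quantification validation via
    standard addition (linearity, LOD/LOQ), recovery against a reference
    assay, Bland-Altman agreement and repeatability RSD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    zoo,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
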
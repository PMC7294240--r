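Package: depwmh
Title: Disease Evolution Prediction for White Matter Hyperintensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise prediction of white-matter-hyperintensity (WMH)
    evolution between a baseline and a follow-up brain scan. Builds signed
    Disease Evolution Maps (DEM) from serial irregularity maps, probability
    maps or binary lesion labels; trains a supervised three-class
    U-Residual-Network segmenter (DEP-UResNet) and an adversarial predictor
    with two Wasserstein gradient-penalty critics (DEP-GAN), both with
    FiLM-modulated auxiliary input (clinical lesion loads or Gaussian
    noise); generates longitudinal synthetic cohorts with known
    grow/shrink/stable ground truth; and evaluates predictions by direction
    accuracy, Bland-Altman volumetric agreement, volumetric correlation,
    per-class Dice overlap and ANCOVA clinical-plausibility models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
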
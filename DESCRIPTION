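Package: ssmfit
Title: Scaled Subprofile Model Analysis of Tract-Level White Matter Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Scaled Subprofile Model (SSM) regional covariance patterns to
    participant-by-tract tables of diffusion MRI metrics (axial, radial and mean
    diffusivity, fractional anisotropy) and relates pattern expression to a
    cardiorespiratory fitness covariate (VO2max). Provides log transformation with
    double mean-centering, principal component decomposition, BIC selection of the
    leading components whose linear combination best predicts fitness, bootstrap
    percentile confidence intervals for tract loadings with sign alignment,
    interquartile-range quality control of tract values, FDR-corrected univariate
    tract regressions, block-wise covariate regressions, a synthetic cohort
    generator with planted covariance patterns for validation, and a reproducible
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
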
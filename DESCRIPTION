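Package: normdae
Title: Normative Modelling of Brain Morphometry with Denoising Autoencoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Normative modelling of regional brain morphometry using a
    semi-supervised denoising deep autoencoder. The model is trained on
    healthy-population vectors of 104 regional measures (68 Desikan-Killiany
    cortical thicknesses and 36 segmentation volumes), with supervised age and
    sex heads and a cross-covariance (XCov) penalty that disentangles these
    covariates from the latent code. Each test subject receives a total
    deviation metric (mean squared reconstruction error) and a per-region
    deviation map, compared between groups with Mann-Whitney U tests and
    Cliff's delta effect sizes. Includes a latent-factor synthetic cohort
    generator, a bootstrap AUC comparison against a linear support vector
    machine baseline, readers for tidy and FreeSurfer-style morphometry
    tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
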
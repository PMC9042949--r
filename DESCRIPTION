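Package: facepath
Title: Geometric Morphometrics and Bayesian Path Models for Facial
    Perception Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studies linking facial shape, skin colour, age and
    body mass to perceived dominance and sex-typicality. Reads tpsDig2-style
    landmark files, runs generalized Procrustes superimposition with sliding
    semi-landmarks, computes sexual shape dimorphism (SShD), morphological
    distinctiveness (DIST) and per-face shape-trait regression scores, and
    fits a layered Bayesian path model (normal priors on intercepts and
    slopes, exponential priors on scales, LKJ priors on residual correlation
    matrices) by a blocked Gibbs/slice sampler. Includes interrater
    reliability (ICC(3,k)), Horn's parallel analysis with single-factor
    colour extraction, collinearity diagnostics (VIF), and a synthetic-study
    generator with known ground truth so that every pipeline stage can be
    validated without the original photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
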
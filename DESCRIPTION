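Package: metquant
Title: Quantitative Analysis of Hair-Cell Mechanotransduction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of cochlear hair-cell
    mechanoelectrical transduction (MET) experiments: extraction of
    peak-to-peak MET currents, current-voltage curves, reversal potentials
    and resting open probability from stimulus-annotated patch-clamp traces;
    sub-pixel hair-bundle tracking from high-speed movies and steady-state
    bundle stiffness estimation from fluid-jet force steps; ratiometric
    quantification of immunofluorescence in anisotropic Gaussian volumes at
    anatomical landmarks along the hair cell; and gene-set overlap arithmetic
    for differential-expression tables. A synthetic-data generator produces
    all input modalities with known ground truth, so every analysis stage is
    testable end to end without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
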
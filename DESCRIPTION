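Package: dcquant
Title: Quantitative Analysis of Dorsal Closure Dynamics in Drosophila Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify epithelial dorsal closure in Drosophila
    embryos from live-imaging derived measurements: two-phase closure-rate
    kinetics of the dorsal hole with outcome classification (closed,
    arrested, torn), laser-ablation recoil velocity and Kelvin-Voigt
    viscoelastic fitting, 14-descriptor cell-shape morphometrics with
    standardized principal component analysis, per-cell normalized
    fluorescence intensity with a bootstrap group test, and two-by-two
    penetrance statistics. Includes a synthetic-data generator that
    emulates the imaging outputs (closure trajectories, post-ablation
    recoil series, epithelial cell meshes, junctional fluorescence
    z-stacks and cuticle counts) with known ground truth, so the whole
    pipeline can be exercised and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
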
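Package: radialign
Title: Orientation, Alignment and Mechanical-Stimulation Analytics for
    Radially Organized Engineered Muscle
Version: 0.1.0
Authors@R:
    person("radialign", "developers", email = "radialign@example.org",
           role = c("aut", "cre"))
Description: Quantitative image and signal analytics for tissue-engineered
    muscle cultured under radial mechanical stimulation. Implements weighted
    structure-tensor estimation of local fiber orientation and coherency,
    orientation-distribution histograms with Gaussian peak fitting and a
    [0,1] alignment score, comparison of orientation fields against radial
    and isotropic controls, a spherical-cap membrane-inflation model mapping
    reservoir volume change to radial strain with a two-phase stimulation
    protocol compiler, and dF/F0 calcium-transient quantification. Ships
    seeded synthetic-data generators (gratings, fiber fields, radial spoke
    patterns, elongated nuclei, calcium transients) with ground truth so the
    whole pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
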
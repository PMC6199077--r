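Package: nanopillar
Title: Quantitative Analysis of Nanopillar Surfaces and Their Bactericidal Activity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for quantifying mechano-bactericidal nanopillar surfaces
    such as black silicon from calibrated electron micrographs, AFM-style
    height maps and plate-count viability assays. Provides a sliding-window
    multilayer-perceptron pillar-tip detector trained by back-propagation,
    point-pattern statistics (pair-correlation function with isotropic edge
    correction, first-peak localization, neighbor-count distributions),
    tiled averaged-FFT radial spectra with halo-peak analysis, surface
    metrology (Ra, Rq, Abbott-Firestone bearing curve, aspect ratio), and
    bactericidal-efficiency estimation with replicate statistics. A
    synthetic-data generator produces hard-core short-range-ordered tip
    patterns, SEM-like renders, pillar-forest height maps and viability
    tables with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, png
Suggests: testthat (>= 3.0.0), withr, tiff, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'detector.R'
    'io.R'
    'nanopillar-package.R'
    'pipeline.R'
    'spatial.R'
    'spectral.R'
    'synthgen.R'
    'topography.R'
    'viability.R'
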
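Package: lfsmia
Title: Label-Free Single-Molecule Immunoassay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, classification and quantification of single-molecule
    antibody binding events in plasmonic scattering microscopy (PSM) image
    stacks. Implements the differential-imaging detection pipeline (block
    averaging, mean normalization, frame differencing, Haar-like blob
    filtering, 3-sigma candidate selection and sub-pixel 2D Gaussian fitting),
    intensity-to-molecular-weight calibration, position/mass/duration/frequency
    filtering of binding events, a Bayesian Gaussian-process smoother of
    replicate cumulative count trajectories, and assay-level statistics
    (standard curves, limit of detection, coefficient of variation, dynamic
    range). A seeded synthetic-video generator grounded in first-order
    association kinetics makes every stage testable without an instrument.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
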
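Package: mtdyn
Title: Quantification of Microtubule Plus-End Dynamics, Single-Molecule
    Stoichiometry, FRAP Recovery and Protofilament Flare Geometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying microtubule (MT) plus-end dynamics from
    in vitro reconstitution experiments: stochastic simulation of tip
    trajectories switching among fast growth, slow growth, pause and
    shrinkage states; kymograph rendering and sub-pixel tip tracing;
    penalized changepoint segmentation of tip traces into constant-velocity
    phases with four-way rate classification; dynamics summaries (state-time
    fractions, catastrophe/rescue/pause transition frequencies, weighted
    growth-rate histograms); single-molecule spot detection, 2D Gaussian
    photometry and oligomer stoichiometry inference; FRAP trace
    normalization and exponential recovery fitting; and cryo-ET style
    protofilament flare metrics (flared length, per-MT length s.d., local
    curvature, end raggedness) with rank-based group comparisons.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
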
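Package: maci
Title: Multivariate Analysis of Congruent Images with O2PLS for
    Ultrasound Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares two time-resolved grayscale image sequences, such as
    musculoskeletal B-mode ultrasound loops, by compressing each frame with
    a 2-D discrete wavelet transform (Symlet 8 by default), selecting the
    highest-variance coefficients into a congruent two-way feature table,
    and decomposing the paired tables with a two-block O2PLS model into
    joint, block-unique (orthogonal) and residual variation.  Includes
    cross-validated component selection, movement-phase segmentation from
    score vectors, block-matching speckle tracking with vector flow field
    summaries, sequence synchronisation by linear frame removal, and a
    synthetic speckle-sequence generator with known latent kinematics for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
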
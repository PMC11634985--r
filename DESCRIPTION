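Package: hwnav
Title: Simulation and Analysis of Digital Hebb-Williams Maze Navigation Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator and analysis toolkit for digital spatial
    navigation training on Hebb-Williams style grid mazes. Provides maze
    representation, validation and shortest-path geometry; an egocentric
    step/turn navigation environment with graded visual masking
    (full vision, 50 percent mask, blindfold); auditory distance sonification
    (wall-proximity tones and footstep events); trial scoring and daily
    training scores; a multi-day training protocol scheduler; a synthetic
    learning agent; nonlinear least-squares logarithmic learning-curve
    fitting with confidence intervals, paired comparisons and effect sizes;
    and a simplified ROI-to-ROI resting-state connectivity contrast engine
    (bandpass, Fisher z, paired edge tests with Benjamini-Hochberg FDR)
    exercised on synthetic multivariate time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    MASS,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    minpack.lm,
    yaml,
    optparse
Config/testthat/edition: 3
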
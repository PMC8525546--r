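Package: cpast
Title: Active-Inference Simulation of Culturally Patterned Visual Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a discrete-state active-inference agent foraging over
    synthetic vase decorations of graded complexity. The agent carries a
    two-level hierarchical generative model whose local observation likelihood
    is remapped from the 3x3 neighbourhood of its gaze after every saccade, so
    it never holds a global scene model. Motif-to-motif transition
    probabilities are learned through Dirichlet count updates; the learned
    transition matrix constitutes a culturally patterned attention style
    (C-PAST), phenotyped by its Shannon entropy. The package provides the
    stimulus generator, the variational inference and expected-free-energy
    action-selection engine, a visual-foraging experiment with scanpath
    vertical-index statistics, and a cut-out categorisation experiment that
    measures how transferred attention styles affect decision performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
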
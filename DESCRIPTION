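Package: cholinepipe
Title: Analysis of Septo-Hippocampal Cholinergic Dynamics from Fiber Photometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for analysing dual-channel fiber photometry of
    septo-hippocampal cholinergic activity recorded during an object location
    memory task: isosbestic delta-F/F motion and bleaching correction with an
    adjusted-control fit, movement-speed coding across smoothing timescales,
    session-start recency (exponential decay) analysis, behavioral bout
    extraction and event-triggered averaging with linear time warping,
    nonparametric cluster-based permutation tests on paired aligned series,
    and frame-level linear mixed-effects inference with novelty-interaction
    contrasts.  A seeded synthetic-session generator emulates the statistical
    structure of the recordings (log2-speed coding, behavioral-state effects,
    phasic novelty transients, an exponentially decaying session-start
    component, shared photobleaching and motion artifacts) so that every
    stage of the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    lme4,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich
Config/testthat/edition: 3
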
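Package: biofilmq
Title: Quantification of In Situ Oral Biofilm Imaging and Trial Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for in situ oral biofilm intervention
    studies. Estimates mean biofilm thickness from optical coherence
    tomography (OCT) volumes by disk median filtering, global intensity
    thresholding and per-column voxel counting; estimates biovolume from
    sparse confocal z-stacks with the Cavalieri principle; measures
    extracellular biofilm pH from two-channel ratiometric confocal images
    via a fitted five-parameter logistic calibration curve with analytic
    inverse; and implements the trial's statistical layer, including
    thickness-ranked pair randomization, multi-method consensus outlier
    screening, gamma regression with a log link, linear models for pH, and
    participant-level cluster bootstrap inference. Ships synthetic-data
    generators with known ground truth for every input so the whole
    pipeline can be validated end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
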
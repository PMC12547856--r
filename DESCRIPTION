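Package: simscorr
Title: Correlative Electron Microscopy and NanoSIMS Image Analysis
Version: 0.1.0
Authors@R:
    person("Simscorr", "Developers", email = "simscorr@example.org",
           role = c("aut", "cre"))
Description: Tools for computer-vision-assisted correlation of transmission
    electron microscopy (EM) images with nanoscale secondary ion mass
    spectrometry (NanoSIMS) ion-count images. Provides offset multi-pass
    tiling of large EM images for fixed-frame instance segmentation
    backends, compilation of per-tile detections into filtered organelle
    instance masks, segmentation evaluation metrics (IoU, precision,
    recall, F1, mAP@0.5-0.95, confusion matrix), dead-time and plane-drift
    correction of ion-count stacks, landmark similarity registration of
    EM masks onto SIMS frames, per-organelle 15N-enrichment extraction,
    and pulse-chase exponential-decay half-life estimation with group
    statistics. A synthetic phantom generator with known ground truth
    makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
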
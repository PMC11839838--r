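Package: promptseg
Title: Simulated Interactive Point-Prompt Segmentation Evaluation for
    Volumetric Tumor MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automated evaluation of promptable 2D segmentation models on
    volumetric tumor MRI. Simulates an expert-interactive point-to-mask
    workflow: iterative foreground/background prompt placement driven by
    distance transforms of the residual error, selection among the three
    candidate masks a promptable model returns (oracle, model-suggested, or
    most similar to the previous slice), per-iteration intersection-over-union
    accounting, stacking of per-slice masks into 3D with tri-orientation
    majority-vote fusion, region-of-interest cropping, and tumor-area
    threshold analysis via maximally selected rank statistics. Ships a
    synthetic phantom generator and a mock promptable predictor so the whole
    pipeline runs end-to-end without external data or model weights; real
    NIfTI image/label pairs and any predictor satisfying the prompt contract
    can be substituted.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
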
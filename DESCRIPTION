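Package: polypscope
Title: Whole-Slide Colorectal Polyp Classification with Hierarchical
    Slide-Level Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for classifying colorectal polyps on
    whole-slide histopathology images: sliding-window patch extraction
    from rectangular region-of-interest annotations, a small trainable
    convolutional patch classifier with softmax-averaging ensembles, a
    hierarchical slide-level diagnosis rule (adenomatous versus serrated
    patch voting followed by villous and sessile-serrated fraction
    thresholds) with grid-search threshold calibration, multi-annotator
    evaluation statistics (one-vs-rest accuracy/sensitivity/specificity
    with Wald intervals, mean pairwise multiclass Cohen kappa,
    two-proportion tests, confusion matrices), and confidence heatmap
    visualization.  A seeded procedural generator of class-textured
    synthetic slides, annotations and annotator panels makes the whole
    pipeline runnable and testable without real slide data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    e1071,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
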
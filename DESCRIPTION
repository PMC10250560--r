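Package: dtuemp
Title: Video-Based Dual-Task Upper-Extremity Motor Performance Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify dual-task upper-extremity motor performance
    (DTUEMP) from video-derived joint keypoints. Decodes pose-network
    heatmaps, estimates Lucas-Kanade optical flow at the elbow and wrist,
    fuses network and flow tracks into a corrected wrist-elbow angle
    sequence, segments the sequence into flexion and extension phases by
    local peaks, and summarises each trial by six duration metrics (mean
    and SD of flexion, extension and flexion-extension phase). Includes
    the agreement and clinical-association statistics used with such
    metrics (Spearman, ICC(2,1), rank-based inverse-normal transform,
    partial correlation) and an l1-regularised multi-task least-squares
    model, with a single-task Lasso benchmark and cross-validated MAPE,
    for joint prediction of cognitive (MMSE) and mobility (TUG) scores.
    A synthetic-trial generator provides ground-truth flexion-extension
    trials, noisy keypoint tracks, rendered test frames and cohorts so
    the full pipeline is testable without video recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics, tools, e1071, yaml, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
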
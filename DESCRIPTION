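Package: ethobench
Title: Benchmarking Frame-Wise Animal-Behavior Classifiers Against Graded
    Multi-Observer Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for evaluating supervised frame-by-frame behavior
    classifiers (such as JAABA score tracks for Drosophila social behaviors)
    against graded annotations from multiple human observers. Implements
    union-merging of two observers' bout annotations into combined 1-6
    confidence scores, smoothing of per-frame classifier scores into bouts
    (threshold, maximum-gap filling, minimum bout length), one-to-many
    bout matching with virtual bouts, confidence-stratified precision and
    recall, permutation null models for the annotation-score correlation,
    and a synthetic-data generator emulating graded observers and
    correlated score tracks so the full pipeline is testable without video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse,
    yaml
Config/testthat/edition: 3
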
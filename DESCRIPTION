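Package: scanpathr
Title: Dynamic Scan-Path Analysis of Driver Eye Movements over Areas of Interest
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sequence analysis of gaze behaviour in dynamic tasks
    such as driving. Fixation event streams coded over seven dynamic areas of
    interest (AOIs) are filtered by a minimum fixation duration, run-length
    collapsed into AOI visit sequences, and decomposed into fixed-length scan
    paths with a sliding window. Scan paths are classified into six functional
    classes (forward polling, guidance, backwards polling, right scenery,
    speed monitoring and automation supervision) by length-4 positional rules
    and a 28-triplet catalogue, and class frequencies are compared between
    manual and highly automated driving with chi-squared homogeneity tests,
    Fisher's exact test and Benjamini-Hochberg correction. A seeded
    motif-mixture generator produces synthetic fixation tables with planted,
    recoverable gaze strategies for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
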
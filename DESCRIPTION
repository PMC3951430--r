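Package: stnhfs
Title: Multimodal Analysis Pipeline for Subthalamic High-Frequency
    Stimulation Studies in the 6-OHDA Rat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the quantitative analysis stages of a bilateral
    6-OHDA rat deep-brain-stimulation study as a tested pipeline:
    probe-level microarray preprocessing with per-comparison change calls
    and signal-log ratios, an intra-animal consensus differential
    expression screen with counter-regulation detection and EASE
    enrichment scoring, open-field locomotion segmentation into rest and
    motion episodes with bimodal motion-mode identification, local field
    potential and ECoG band-power statistics with exact Wilcoxon rank-sum
    tests, optical fractionator stereology with Cavalieri volume and
    coefficient-of-error estimation, and delta-delta-CT / densitometric
    validation. A synthetic-data module generates every input with
    recorded ground truth so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    limma,
    signal,
    data.table
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
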
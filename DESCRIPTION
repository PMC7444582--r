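Package: calciflow
Title: Quantification of Spermathecal Calcium Dynamics from Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying GCaMP calcium dynamics during oocyte
    transits through the C. elegans spermatheca. Reads and registers
    time-lapse TIFF stacks, extracts region-of-interest fluorescence traces,
    normalizes them to a pre-entry baseline (F/F0), builds kymograms, detects
    calcium pulses by prominence and width, and derives pulse metrics
    (peak counts and rates, time to half-maximal and maximal signal, variance
    of the first derivative). Also computes entry/dwell/exit/total transit
    times from event annotations, classifies transit phenotypes, tabulates
    population occupancy assays, and compares conditions with an exact 2x2
    test and one-way ANOVA. Ships a synthetic spatiotemporal calcium movie
    generator with genotype-style presets and ground-truth pulse logs so the
    entire pipeline can be exercised and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
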
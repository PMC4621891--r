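Package: pvnscreen
Title: Analysis of Perivascular-Niche Co-Culture Drug Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytics for high-throughput drug screens run in
    glioblastoma-endothelial co-culture, where the readout of interest is a
    compound's ability to block the trophic (growth-stimulating) effect of
    endothelial cells on tumor cells rather than to kill tumor cells
    directly. Implements the percent-inhibition-of-trophic-effect statistic
    with per-plate vehicle normalization, a four-way compound
    classification (inert, pan-cytotoxic, monoculture-cytotoxic-protected,
    anti-trophic), and the mean + 3 SD dual-criterion hit call; secondary
    conditioned-media dose-response analysis with background subtraction
    and CM/TSM normalization; preclinical endpoint analytics
    (baseline-balanced randomization, per-animal bioluminescence
    normalization, Kaplan-Meier curves and log-rank tests); and a
    synthetic-data generator with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
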
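Package: modmapr
Title: Mapping Post-Transcriptional Modifications in Mitochondrial tRNAs by
    Mass Spectrometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping post-transcriptional modifications in
    (mitochondrial) tRNAs from mass-spectrometric data: elemental-formula
    mass arithmetic for modified ribonucleosides, in-silico RNase T1/RNase A
    digestion with correct terminal chemistry, MS1 peak-list matching with a
    bounded modification-placement search, CID c/y/w/a-B product-ion ladders
    for site localization, differential cyanoethylation analysis for
    pseudouridine detection, ESI charge-series deconvolution for intact-mass
    validation, and landscape statistics over a modification catalog.
    Ships the bovine mitochondrial tRNA modification catalog and a
    ground-truthed synthetic-data generator so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
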
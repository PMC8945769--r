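Package: telomut
Title: Two-Factor Gene Mutability by Telomere Proximity and A+T Content
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Ranks druggable genes (ion channels, G-protein-coupled
    receptors) by their predicted relative mutability using two genomic
    factors: proximity of the gene locus to its nearest telomere (factor i,
    below 50 Mb) and high adenine plus thymine content of the gene sequence
    (factor ii, above the 59% genome-wide average). Provides readers for
    gene tables, chromosome sizes and telomere intervals, nucleotide
    composition from sequence, nearest-telomere distance with the
    centimorgan linkage heuristic, Both/one/None factor classification with
    cohort matching rates and candidate prioritization, the supporting
    correlation, normality and ANOVA/Tukey statistics, a synthetic cohort
    generator for pipeline validation, and an end-to-end analysis report
    with summary plots. Ships the 11 ion-channel and 20 GPCR drug-target
    reference tables as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2,
    rlang
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
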
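Package: dosageseries
Title: Dosage-Series Analysis of Homoeolog Expression in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing homoeologous gene expression across a serial
    allopolyploid genome-dosage design (diploid parents AA and CC plus the
    derived hybrids AC, AAC, CCA and CCAA). The package classifies genes as
    dosage-dependent, dosage-independent (compensated) or inverse-dosage by
    correlating replicate-averaged FPKM against the relative subgenome dosage
    series, quantifies expression divergence from mid-parent values with
    fold-change summaries, partitions homoeolog-pair regulatory divergence
    into cis and trans components from parental and hybrid allele ratios, and
    cross-tabulates regulatory categories against dosage classes. A synthetic
    allopolyploid transcriptome generator with known per-gene ground truth
    makes every stage testable end-to-end without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
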
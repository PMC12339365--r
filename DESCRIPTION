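Package: escapeseq
Title: Sort-Seq Analysis of Pooled Peptide-HLA Surface-Presentation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design, simulation and analysis of pooled single-chain-trimer
    peptide-HLA surface-presentation screens read out by DNA sequencing.
    Covers tiling/variant/fusion peptide library design with synonymous-codon
    allele barcodes, exact-anchor FASTQ demultiplexing into a peptide x allele
    x sort-bin count table, bin-weighted enrichment scores (E-scores) with
    per-allele mode alignment and binder calling, benchmarking against
    affinity and elution references (ROC/PR with bootstrap confidence
    intervals), allele similarity by pseudo-sequence and by score profile,
    Hardy-Weinberg population-coverage extrapolation, and a generative
    sorter model producing synthetic FASTQ with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
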
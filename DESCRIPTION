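Package: semeth
Title: Differentially Methylated Super-Enhancers and Their In-Cis Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers differentially methylated super-enhancers (SEs) from
    per-sample methylation peak calls (MBD-Seq/MACS-style BED intervals) and
    links them to in-cis target gene expression. Quantifies SE and promoter
    methylation as the net base-pair intersection of each region with a
    sample's methylation peaks, tests tumour-versus-control differences with
    Wilcoxon rank-sum tests (genome-wide 100 bp tiles use exact Fisher tests
    on binary methylation status), applies Benjamini-Hochberg false discovery
    rate control, assigns candidate target genes by a 1 Mbp transcription
    start site window, screens SE-gene pairs by negative Kendall tau-b
    correlation between methylation and expression, and validates pairs in an
    independent cohort measured on a 450k-style probe array using the
    most-negatively-correlated probe inside each SE. Includes a ground-truthed
    synthetic cohort generator for end-to-end evaluation and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
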
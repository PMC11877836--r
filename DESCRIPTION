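Package: germmeth
Title: Male-Germline DNA Methylation and Transposon Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for whole-genome bisulfite sequencing
    analysis of plant male sex cells (meiocyte, microspore, pollen) against
    somatic tissue. Reads and merges per-cytosine CX-report methylation calls,
    quantifies CG/CHG/CHH methylation in fixed windows and end-anchored
    metaprofiles, calls sexual-lineage hypermethylated loci from windowed
    differentials with Fisher's exact testing and replicate consistency
    filters, classifies them by somatic RdDM activity, calls CHH
    differentially methylated regions between conditions with
    Benjamini-Hochberg correction, relates loci to gene and transposon
    annotation, computes TPM, classifies LTR transposon activity with k-means
    expression clustering, and intersects locus-targeted genes with
    differential expression calls. Ships a synthetic-data generator with
    planted ground truth so the whole pipeline is testable without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
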
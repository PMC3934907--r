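Package: sotargets
Title: Direct-Target Inference for the Sine Oculis Transcription Factor
    from ChIP-Seq and Expression Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for inferring direct
    transcriptional targets of the Drosophila retinal determination
    factor Sine oculis (So) from ChIP-seq binding data and loss/gain
    expression contrasts. Provides scored-peak handling under the MACS
    -10*log10(P) convention (filtering, ranking, top-quantile
    selection), peak-to-gene and nearest-TSS assignment with
    intragenic/intergenic status, degenerate IUPAC motif scanning with
    a shuffled-sequence background, classification of peak-bearing
    responsive genes as positively, negatively or ambiguously regulated,
    hypergeometric term enrichment, three-criterion screen-candidate
    selection, and a fully seeded synthetic-data generator that emulates
    the study conditions so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    BiocGenerics,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
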
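Package: cernet
Title: CLIP-Supported miRNA Target and ceRNA Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies competing endogenous RNA (ceRNA) pairs from
    CLIP-Seq-supported miRNA target sites. Provides strand-aware overlap of
    predicted miRNA seed sites with Argonaute CLIP binding-site clusters,
    miRNA-family collapsing, an upper-tail hypergeometric test on shared
    miRNA families with Benjamini-Hochberg false discovery rate control,
    miRNA super-sponge detection, hypergeometric functional-term enrichment
    with Bonferroni and FDR correction, a deterministic synthetic-fixture
    generator with planted ground truth, and an end-to-end pipeline with
    reproducible tabular outputs.
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
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringi,
    tibble,
    tools
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
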
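Package: mirmeta
Title: Multi-Evidence microRNA Target Identification from Expression
    Panels and Ago2 HITS-CLIP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies high-confidence microRNA targets by integrating
    loss-of-function and gain-of-function expression panels with Ago2
    HITS-CLIP binding data. Provides seed-site motif scanning and
    classification (6/7/8mer), dinucleotide-shuffle motif-enrichment
    backgrounds, small-RNA and 3'-end (3Seq) quantification with
    internal-priming filtering, translation-efficiency analysis from
    ribosome profiling, CLIP read clustering with hierarchical genomic
    annotation and per-miRNA target-site prediction, a sign-consistent
    expression meta-analysis with hypergeometric seed enrichment and
    one-sided Kolmogorov-Smirnov CDF-shift tests, and a seeded synthetic
    study generator with planted targets for end-to-end validation.
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
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
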
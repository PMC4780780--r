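Package: promoterCpG
Title: TSS-Anchored CpG Dinucleotide Density Profiling of Promoter Domains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing CpG dinucleotide density in upstream
    promoter domains of annotated genes. Extracts strand-aware, TSS-anchored
    sequence windows (-3000..+500 by default) from a genome and its gene
    annotation, computes 51-bp moving-average CpG/GpC density profiles
    normalized to G+C content or to the observed/expected CpG ratio, builds
    randomized control gene models from genome base composition and codon
    usage, and compares region-wise CpG frequencies between functional gene
    groups with Kruskal-Wallis, Dunn post hoc, and Wilcoxon rank-sum
    statistics. A synthetic-genome generator with a controllable positional
    CpG observed/expected profile makes the whole pipeline testable without
    any genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
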
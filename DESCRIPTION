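Package: sweepscan
Title: Selective Sweep Scans from Pooled Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective sweep regions from two-pool
    whole-genome resequencing (pool-seq) allele counts. Implements windowed
    pooled heterozygosity (Hp) and its genome-wide Z-transformation (ZHp),
    a sliding-window pool-Fst with Z-transformation (ZFst), the differential
    heterozygosity statistic D-ZHp, and quantile-intersection candidate
    selection (bottom-tail ZHp crossed with top-tail ZFst), together with
    gene overlap annotation, SNP effect classification against transcript
    models, SNP summary statistics (ts/tv, heterozygosity rate), readers and
    writers for sync/VCF/BED/FASTQ inputs, and a forward simulator of pooled
    allele counts with planted sweeps for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    methods,
    jsonlite,
    yaml,
    ggplot2,
    vcfR,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
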
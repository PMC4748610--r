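Package: cprselect
Title: Selection Scans on Core Promoter Sequence Variation in Inbred Line Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects natural selection on core promoter region (CPR) sequence
    variants that explain gene-expression differences across a panel of
    homozygous inbred lines. Provides per-CPR diversity statistics (segregating
    sites, nucleotide diversity, Watterson's theta, Tajima's D) with the
    panel's data-cleaning rules; a coalescent simulator for demographic null
    models (bottleneck, exponential growth, admixture) and empirical two-tailed
    outlier P values for Tajima's D; expression ~ haplotype x sex linear
    modelling with Benjamini-Hochberg control; log-odds PSSM scanning with
    balanced score thresholds, transcription-factor binding-site gain/loss
    calling between alleles, and minimal mutation-set enumeration; haplotype
    block and linkage-disequilibrium screens of flanking SNPs; read-depth
    duplication screening; neighbor-joining allele phylogenies with bootstrap
    support; a synthetic cohort generator with planted ground truth; and a
    pipeline that assembles all stages into a per-CPR selection report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    car,
    data.table,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
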
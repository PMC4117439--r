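Package: altisweep
Title: Two-Population Selective Sweep Scans from Diploid Genotype Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps by contrasting two populations of diploid
    genomes: genotype quality control (CpG exclusion, missingness, heterozygosity,
    Ti/Tv, genotype concordance, diagnostic-allele admixture screening), windowed
    Weir-Cockerham F_ST and nucleotide-diversity (theta-pi) ratios joined through
    empirical-percentile products, outlier-region extraction with gene overlap,
    fixed-difference genotype-pattern filtering of candidate SNPs, allelic
    association tests, linkage-disequilibrium r-squared (phased, EM and composite),
    LD pruning and complete-LD grouping, variant effect classification, ortholog
    alignment QC and local hypergeometric gene-set enrichment. Includes a seedable
    two-population sweep simulator that emits VCF/FASTA/GFF3 fixtures with a
    machine-readable truth record.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
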
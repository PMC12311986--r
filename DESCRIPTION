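Package: popgenpipe
Title: Population-Genomic Analysis of Diversity, Inbreeding, Mutational
    Load and Selection from Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for conservation population genomics on
    small numbers of resequenced diploid genomes: VCF reading and
    hard/soft genotype filtering, outgroup polarization of alleles into
    ancestral and derived states, per-individual additive mutational
    load and the between-population R_xy frequency-ratio statistic with
    block-jackknife confidence intervals, missing-data-aware windowed
    nucleotide diversity with invariant sites, per-individual and
    region-stratified heterozygosity, sliding-window detection of runs
    of homozygosity with F_ROH summaries, linkage-disequilibrium decay
    curves, windowed Tajima's D, Weir-Cockerham FST and XP-EHH selection
    scans with top-quantile candidate-region intersection,
    neighbor-joining trees from genotype p-distances with bootstrap
    support, genotype PCA, and a forward Wright-Fisher simulator that
    generates inputs of known truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
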
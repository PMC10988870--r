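Package: SweepScan
Title: Selective Sweep Detection from Phased Population Genomic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Window-based detection of selective sweeps between two
    populations from phased biallelic SNP genotypes. Implements per-site
    Hudson and Weir-Cockerham fixation-index estimators, nucleotide
    diversity, Watterson's theta and Tajima's D, extended haplotype
    homozygosity (EHH), integrated haplotype homozygosity and the
    cross-population XP-EHH statistic with genome-wide standardization;
    aggregates them over consecutive 50-kb windows, calls candidate sweep
    regions by empirical-quantile outlier intersection with Fisher
    window-enrichment tests, merges adjacent sweeps and annotates them
    with overlapping genes. Also provides population-structure summaries
    (pairwise-FST distance matrix with neighbor-joining tree, Patterson
    normalized genotype PCA, linkage-disequilibrium decay curves) and two
    synthetic-data generators (Balding-Nichols genotypes and a forward
    Wright-Fisher simulator with recombination and an optional hard
    sweep) for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    vcfR,
    rtracklayer,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'filtering.R'
    'genotype-io.R'
    'haplotype-statistics.R'
    'pipeline.R'
    'population-structure.R'
    'site-statistics.R'
    'studies.R'
    'synthetic-data.R'
    'window-scan.R'
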
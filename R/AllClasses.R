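#' @include AllGenerics.R
#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importClassesFrom S4Vectors Annotated
#' @importFrom GenomicRanges GRanges granges findOverlaps reduce start end width seqnames
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<-
#' @importFrom stats quantile rbeta rbinom rpois runif sd var setNames complete.cases
#' @importFrom utils read.table write.table head tail
#' @useDynLib SweepScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Site tables ride along as a GRanges (1-based, width-1 positions) with
## id/ref/alt metadata columns; genotype payloads are plain integer and
## character matrices with samples in rows.

#' GenotypeMatrix: diploid genotypes at SNP sites
#'
#' Container for diploid genotype calls at an ordered set of variant sites.
#' Sites are held as a width-1 [GenomicRanges::GRanges] with metadata columns
#' `id`, `ref` and `alt` (a `CharacterList`, so multi-allelic records keep
#' their full alternate list until filtering). The `dosage` slot counts
#' non-reference alleles per genotype (0, 1, 2, or `NA` for missing calls —
#' missing is never conflated with homozygous reference); the `gt` slot keeps
#' the raw VCF `GT` strings so phase survives the round trip into
#' [asHaplotypes()] and [writeVcfGenotypes()].
#'
#' @slot sites width-1 `GRanges`, strictly increasing position per chromosome.
#' @slot dosage integer matrix, samples x sites; `NA` encodes a missing call.
#' @slot gt character matrix, samples x sites, raw `GT` field values.
#'
#' @seealso [readVcfGenotypes()], [filterSites()], [asHaplotypes()]
#' @export
setClass("GenotypeMatrix",
  contains = "Annotated",
  representation(sites = "GRanges", dosage = "matrix", gt = "matrix")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- NULL
  d <- object@dosage
  if (ncol(d) != length(object@sites))
    msg <- c(msg, "ncol(dosage) must equal length(sites)")
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msg <- c(msg, "dosage must have unique sample rownames")
  if (!all(dim(object@gt) == dim(d)) && !all(dim(object@gt) == 0L))
    msg <- c(msg, "gt matrix must match dosage dimensions (or be empty when GT strings are not materialized)")
  if (length(d) && !all(is.na(d))) {
    rng <- range(d, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2)
      msg <- c(msg, "dosage values must be in {0, 1, 2} or NA")
  }
  if (!all(c("id", "ref", "alt") %in% names(mcols(object@sites))))
    msg <- c(msg, "sites must carry id, ref and alt metadata columns")
  if (length(object@sites) > 1) {
    chr <- as.integer(seqnames(object@sites))
    pos <- start(object@sites)
    sameChr <- diff(chr) == 0L
    if (any(sameChr & diff(pos) <= 0L))
      msg <- c(msg, "site positions must be strictly increasing within chromosome")
  }
  if (is.null(msg)) TRUE else msg
})

#' HaplotypeMatrix: phased haplotype alleles at biallelic sites
#'
#' Phased 0/1 allele codes for `2 * n` haplotypes at biallelic SNP sites; the
#' substrate for EHH, XP-EHH, nucleotide diversity, Tajima's D and LD. Rows
#' `2i - 1` and `2i` are sample `i`'s left and right haplotypes in VCF order.
#' The phased-input contract forbids missing entries.
#'
#' @slot sites width-1 `GRanges` of biallelic sites.
#' @slot alleles integer matrix in \{0, 1\}, haplotypes x sites, no `NA`.
#' @slot sampleIds character vector, one id per diploid sample.
#'
#' @seealso [asHaplotypes()], [ehh()], [xpehhScan()]
#' @export
setClass("HaplotypeMatrix",
  contains = "Annotated",
  representation(sites = "GRanges", alleles = "matrix", sampleIds = "character")
)

setValidity("HaplotypeMatrix", function(object) {
  msg <- NULL
  a <- object@alleles
  if (ncol(a) != length(object@sites))
    msg <- c(msg, "ncol(alleles) must equal length(sites)")
  if (nrow(a) %% 2L != 0L)
    msg <- c(msg, "number of haplotypes must be even")
  if (nrow(a) != 2L * length(object@sampleIds))
    msg <- c(msg, "need exactly two haplotypes per sample id")
  if (anyNA(a)) {
    msg <- c(msg, "phased haplotypes cannot contain missing entries")
  } else if (length(a)) {
    rng <- range(a)
    if (rng[1] < 0L || rng[2] > 1L)
      msg <- c(msg, "allele codes must be 0 or 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeMatrix
#'
#' @param sites width-1 `GRanges` with `id`, `ref`, `alt` metadata columns
#'   (`alt` may be a character vector or `CharacterList`).
#' @param dosage integer matrix samples x sites with sample rownames;
#'   `NA` marks missing genotypes.
#' @param gt optional character matrix of raw GT strings; when omitted,
#'   unphased strings are synthesized from `dosage` (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `"./."`).
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(sites, dosage, gt = NULL) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (!("alt" %in% names(mcols(sites))))
    stop("sites must carry an 'alt' metadata column")
  if (!is(mcols(sites)$alt, "CharacterList"))
    mcols(sites)$alt <- CharacterList(as.list(mcols(sites)$alt))
  if (!("id" %in% names(mcols(sites)))) mcols(sites)$id <- NA_character_
  if (is.null(gt)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[dosage + 1L],
                 nrow = nrow(dosage), dimnames = dimnames(dosage))
    gt[is.na(dosage)] <- "./."
  }
  if (length(gt)) dimnames(gt) <- dimnames(dosage)
  new("GenotypeMatrix", sites = sites, dosage = dosage, gt = gt)
}

#' Construct a HaplotypeMatrix
#'
#' @param sites width-1 `GRanges` of biallelic sites.
#' @param alleles integer matrix in \{0,1\}, `2 * length(sampleIds)` rows.
#' @param sampleIds character vector of diploid sample ids.
#' @return A [HaplotypeMatrix-class] object.
#' @export
HaplotypeMatrix <- function(sites, alleles, sampleIds) {
  if (!is.matrix(alleles)) alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (is.null(rownames(alleles)))
    rownames(alleles) <- paste0(rep(sampleIds, each = 2L), "_", c(1L, 2L))
  new("HaplotypeMatrix", sites = sites, alleles = alleles,
      sampleIds = as.character(sampleIds))
}

#' @describeIn GenotypeMatrix-class number of variant sites
#' @param x a `GenotypeMatrix` or `HaplotypeMatrix`
#' @export
setMethod("nSites", "GenotypeMatrix", function(x) length(x@sites))

#' @export
setMethod("nSites", "HaplotypeMatrix", function(x) length(x@sites))

#' @export
setMethod("nSamples", "GenotypeMatrix", function(x) nrow(x@dosage))

#' @export
setMethod("nSamples", "HaplotypeMatrix", function(x) length(x@sampleIds))

#' @export
setMethod("sites", "GenotypeMatrix", function(x) x@sites)

#' @export
setMethod("sites", "HaplotypeMatrix", function(x) x@sites)

#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @export
setMethod("sampleIds", "HaplotypeMatrix", function(x) x@sampleIds)

#' @export
setMethod("dosage", "GenotypeMatrix", function(x) x@dosage)

#' @export
setMethod("gtStrings", "GenotypeMatrix", function(x) {
  if (!length(x@gt) && length(x@dosage))
    stop("GT strings were not materialized for this GenotypeMatrix ",
         "(asGenotypes(withGT = FALSE)); rebuild with withGT = TRUE")
  x@gt
})

#' @export
setMethod("haplotypes", "HaplotypeMatrix", function(x) x@alleles)

#' Subset a GenotypeMatrix by samples (i) and sites (j)
#' @param x a `GenotypeMatrix`
#' @param i sample index (integer, logical or sample-id character)
#' @param j site index (integer or logical)
#' @param ... ignored
#' @param drop ignored; subsetting never drops dimensions
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_along(x@sites)
  initialize(x, sites = x@sites[j],
             dosage = x@dosage[i, j, drop = FALSE],
             gt = if (length(x@gt)) x@gt[i, j, drop = FALSE] else x@gt)
})

#' Subset a HaplotypeMatrix by samples (i, diploid ids/indices) and sites (j)
#' @param x a `HaplotypeMatrix`
#' @param i diploid sample index (integer, logical or sample-id character)
#' @param j site index (integer or logical)
#' @param ... ignored
#' @param drop ignored
#' @export
setMethod("[", "HaplotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_along(x@sampleIds)
  if (missing(j)) j <- seq_along(x@sites)
  if (is.character(i)) i <- match(i, x@sampleIds)
  if (is.logical(i)) i <- which(i)
  if (anyNA(i)) stop("unknown sample id in haplotype subset")
  hapRows <- as.vector(rbind(2L * i - 1L, 2L * i))
  initialize(x, sites = x@sites[j],
             alleles = x@alleles[hapRows, j, drop = FALSE],
             sampleIds = x@sampleIds[i])
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nSamples(object), "samples x", nSites(object),
      "sites\n")
  nmis <- sum(is.na(object@dosage))
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(object@sites))), collapse = ", "),
      "\n  missing genotypes:", nmis,
      sprintf("(%.2f%%)\n", 100 * nmis / max(1L, length(object@dosage))))
  if (!is.null(metadata(object)$filterReport))
    cat("  filtered:", metadata(object)$filterReport$removedTotal,
        "sites removed upstream\n")
})

setMethod("show", "HaplotypeMatrix", function(object) {
  cat("HaplotypeMatrix:", nrow(object@alleles), "haplotypes (",
      nSamples(object), "samples ) x", nSites(object), "sites\n")
  cat("  chromosomes:",
      paste(unique(as.character(seqnames(object@sites))), collapse = ", "),
      "\n")
})

#' Scan thresholds and window parameters
#'
#' Bundle of the empirical-outlier and windowing parameters used by the sweep
#' scan: the SNP/window outlier tail fractions (top 5% by default), the
#' alternative 1% right-tail window rule, the Fisher enrichment alpha
#' (`P < 0.05`), the minimum SNPs per window below which a window is masked,
#' the 50-kb window size and the 50-kb sweep merge gap.
#'
#' @param fstTail,xpehhTail upper-tail fractions defining FST and XP-EHH
#'   outliers (default 0.05 = "top 5%").
#' @param windowTail1pct upper-tail fraction for the alternative
#'   single-statistic window rule (default 0.01 = "1% right tail").
#' @param fisherAlpha significance level for the window enrichment test
#'   (default 0.05).
#' @param minSnps windows with fewer SNPs are masked (default 10).
#' @param windowSize window span in bp (default 50000).
#' @param mergeGap maximum gap for merging adjacent sweeps in bp
#'   (default 50000; a gap of exactly `mergeGap` merges).
#' @return A `ScanThresholds` object.
#' @export
scanThresholds <- function(fstTail = 0.05, xpehhTail = 0.05,
                           windowTail1pct = 0.01, fisherAlpha = 0.05,
                           minSnps = 10L, windowSize = 50000L,
                           mergeGap = 50000L) {
  new("ScanThresholds", fstTail = fstTail, xpehhTail = xpehhTail,
      windowTail1pct = windowTail1pct, fisherAlpha = fisherAlpha,
      minSnps = as.integer(minSnps), windowSize = as.integer(windowSize),
      mergeGap = as.integer(mergeGap))
}

#' @rdname scanThresholds
#' @export
setClass("ScanThresholds", representation(
  fstTail = "numeric", xpehhTail = "numeric", windowTail1pct = "numeric",
  fisherAlpha = "numeric", minSnps = "integer", windowSize = "integer",
  mergeGap = "integer"))

setValidity("ScanThresholds", function(object) {
  fr <- c(object@fstTail, object@xpehhTail, object@windowTail1pct,
          object@fisherAlpha)
  if (any(fr <= 0 | fr >= 1)) return("tail fractions must lie in (0, 1)")
  if (object@windowSize < 1L || object@mergeGap < 0L || object@minSnps < 1L)
    return("windowSize >= 1, mergeGap >= 0 and minSnps >= 1 required")
  TRUE
})

#' SNP inclusion filter parameters
#'
#' Site-level inclusion rules applied before structure and sweep analyses:
#' biallelic SNPs only, missing rate not higher than 10% (a site at exactly
#' the threshold is retained: removal requires a rate strictly *higher* than
#' `maxMissingRate`), and minor allele frequency strictly *higher* than
#' `mafMin` (a MAF of exactly 5% is removed).
#'
#' @param maxMissingRate sites with missing-genotype fraction strictly above
#'   this are removed (default 0.10).
#' @param mafMin sites with MAF not strictly above this are removed
#'   (default 0.05).
#' @param biallelicOnly drop sites with more than one alternate allele
#'   (default TRUE).
#' @return A `FilterParams` object.
#' @export
filterParams <- function(maxMissingRate = 0.10, mafMin = 0.05,
                         biallelicOnly = TRUE) {
  new("FilterParams", maxMissingRate = maxMissingRate, mafMin = mafMin,
      biallelicOnly = biallelicOnly)
}

#' @rdname filterParams
#' @export
setClass("FilterParams", representation(
  maxMissingRate = "numeric", mafMin = "numeric", biallelicOnly = "logical"))

setValidity("FilterParams", function(object) {
  if (object@maxMissingRate < 0 || object@maxMissingRate > 1)
    return("maxMissingRate must lie in [0, 1]")
  if (object@mafMin < 0 || object@mafMin >= 0.5)
    return("mafMin must lie in [0, 0.5)")
  TRUE
})
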
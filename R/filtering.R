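#' @include AllClasses.R
NULL

#' Per-site alternate allele frequency
#'
#' Frequency of the (first) alternate allele computed from dosages, excluding
#' missing genotypes from both numerator and denominator. The called allele
#' count is twice the number of non-missing genotypes. A site where every
#' genotype is missing has an undefined (`NA`) frequency and is treated as
#' missing by downstream statistics.
#'
#' @param g a [GenotypeMatrix-class].
#' @param siteIdx site indices (default: all sites).
#' @param samples optional character vector restricting to a sample subset
#'   (must be non-empty).
#' @return `data.frame` with columns `freq` (alt allele frequency) and
#'   `nCalled` (called allele count, `2 *` non-missing genotypes).
#' @examples
#' # dosages 0,1,2 -> freq 0.5 over 6 called alleles
#' @export
alleleFrequency <- function(g, siteIdx = seq_len(nSites(g)), samples = NULL) {
  d <- dosage(g)
  if (!is.null(samples)) {
    if (length(samples) == 0L) stop("sample subset must be non-empty")
    miss <- setdiff(samples, rownames(d))
    if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
    d <- d[samples, , drop = FALSE]
  }
  d <- d[, siteIdx, drop = FALSE]
  nCalled <- 2L * colSums(!is.na(d))
  altSum <- colSums(d, na.rm = TRUE)
  freq <- ifelse(nCalled > 0L, altSum / nCalled, NA_real_)
  data.frame(freq = freq, nCalled = as.integer(nCalled))
}

#' Apply SNP inclusion filters
#'
#' Applies the site-inclusion rules in order: biallelic (at most one
#' alternate allele), missingness (remove when the missing-genotype fraction
#' is strictly higher than `maxMissingRate`; a site at exactly the threshold
#' is kept), then minor allele frequency (keep only MAF strictly higher than
#' `mafMin`; a MAF of exactly `mafMin` is removed). MAF is computed on the
#' pooled samples of `g` — subset the matrix to the scan samples first to
#' re-filter per scan — or per population when `assignment` and `perPopMaf`
#' are supplied, in which case a site is kept when the MAF rule passes in at
#' least one population. The rules are per-site and independent, so their
#' order cannot change the surviving set; the order only attributes removals
#' in the report.
#'
#' A `filterReport` (removal counts per rule, in application order) is stored
#' in `metadata()` of the result and returned by [filterReport()].
#'
#' @param g a [GenotypeMatrix-class].
#' @param params a [filterParams()] object.
#' @param assignment optional named population vector (for `perPopMaf`).
#' @param perPopMaf compute the MAF rule within each population instead of on
#'   the pooled samples (default `FALSE`).
#' @return The filtered `GenotypeMatrix`.
#' @export
filterSites <- function(g, params = filterParams(), assignment = NULL,
                        perPopMaf = FALSE) {
  nIn <- nSites(g)
  nAlt <- lengths(mcols(sites(g))$alt)
  passBi <- if (params@biallelicOnly) nAlt <= 1L else rep(TRUE, nIn)

  d <- dosage(g)
  missRate <- colMeans(is.na(d))
  passMiss <- missRate <= params@maxMissingRate  # removal needs rate > thr

  mafPass <- function(dd) {
    nCalled <- 2 * colSums(!is.na(dd))
    freq <- ifelse(nCalled > 0, colSums(dd, na.rm = TRUE) / nCalled,
                   NA_real_)
    maf <- pmin(freq, 1 - freq)
    !is.na(maf) & maf > params@mafMin  # strictly higher than mafMin
  }
  passMaf <- if (perPopMaf && !is.null(assignment)) {
    pops <- unique(unname(assignment[rownames(d)]))
    Reduce(`|`, lapply(pops, function(p) {
      mafPass(d[names(assignment)[assignment == p &
                                    names(assignment) %in% rownames(d)], ,
                drop = FALSE])
    }))
  } else mafPass(d)

  removedBi <- !passBi
  removedMiss <- passBi & !passMiss
  removedMaf <- passBi & passMiss & !passMaf
  keep <- passBi & passMiss & passMaf

  out <- if (all(keep)) g else g[, keep]
  report <- list(
    keptIndex = which(keep),
    sitesIn = nIn,
    sitesOut = sum(keep),
    removedBiallelic = sum(removedBi),
    removedMissing = sum(removedMiss),
    removedMaf = sum(removedMaf),
    removedTotal = nIn - sum(keep),
    params = params)
  metadata(out)$filterReport <- report
  out
}

#' @rdname filterSites
#' @param x a filtered `GenotypeMatrix`.
#' @return `filterReport(x)`: the removal-count list, or `NULL` when `x` has
#'   not been filtered.
#' @export
filterReport <- function(x) metadata(x)$filterReport

#' Serialize a filter report to TSV
#' @param report list from [filterReport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFilterReport <- function(report, path) {
  df <- data.frame(
    rule = c("input", "biallelic", "missingness", "maf", "output"),
    sites = c(report$sitesIn, report$removedBiallelic, report$removedMissing,
              report$removedMaf, report$sitesOut),
    action = c("in", "removed", "removed", "removed", "out"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
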
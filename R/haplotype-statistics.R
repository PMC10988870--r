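#' @include AllClasses.R
NULL

## Status codes from the C++ walker: 0 = reached the EHH cutoff,
## 1 = edge-truncated (chromosome end first), 2 = inter-site gap > maxGap,
## 3 = capped at maxExtend (score stays defined).

checkSingleChrom <- function(h) {
  if (length(unique(as.character(seqnames(sites(h))))) > 1L)
    stop("EHH statistics operate on one chromosome at a time; subset first")
}

#' Extended haplotype homozygosity curve
#'
#' EHH around a core site, computed over all haplotypes (the pooled scope
#' used by XP-EHH). The curve starts at 1 for the zero-length extension; at
#' extension to site `j`, EHH is `sum C(m_k, 2) / C(N, 2)` over the counts of
#' distinct haplotype strings spanning the sites beyond the core through `j`.
#' The walk stops at the first value below `cutoff`, at the chromosome end
#' (`status = "edge"`), at an inter-site gap larger than `maxGap`
#' (`status = "gap"`, mirroring selscan's max-gap guard), or `maxExtend` bp
#' from the core (`status = "max_extend"`, mirroring selscan's max-extend
#' cap; the curve stays usable).
#'
#' @param h a [HaplotypeMatrix-class] on a single chromosome (`N >= 2`
#'   haplotypes).
#' @param core core site index (1-based).
#' @param direction `"downstream"` (increasing position) or `"upstream"`.
#' @param cutoff EHH truncation threshold (default 0.05, the selscan
#'   default).
#' @param maxGap maximum tolerated inter-site gap in bp (default 200000).
#' @param maxExtend maximum extension from the core in bp (default 1e6).
#' @return List with `core`, `direction`, `offsets` (bp, starting at 0),
#'   `values` (EHH, starting at 1) and `status` (`"cutoff"`, `"edge"` or
#'   `"gap"`).
#' @export
ehh <- function(h, core, direction = c("downstream", "upstream"),
                cutoff = 0.05, maxGap = 200000, maxExtend = 1e6) {
  direction <- match.arg(direction)
  checkSingleChrom(h)
  a <- haplotypes(h)
  if (nrow(a) < 2) stop("EHH requires at least 2 haplotypes")
  if (core < 1 || core > ncol(a)) stop("core site index out of bounds")
  res <- .ehh_curve_cpp(a, as.numeric(start(sites(h))), core - 1L,
                        if (direction == "downstream") 1L else -1L,
                        cutoff, maxGap, maxExtend)
  list(core = core, direction = direction,
       offsets = c(0, res$offsets), values = c(1, res$values),
       status = c("cutoff", "edge", "gap", "max_extend")[res$status + 1L])
}

#' Integrated haplotype homozygosity
#'
#' Trapezoidal integral of the EHH curve over physical distance (bp), summed
#' over the upstream and downstream directions. Integration is truncated at
#' the first offset where EHH drops below `cutoff` (the sub-cutoff point
#' itself contributes nothing) and capped `maxExtend` bp from the core (a
#' capped integral stays defined). A curve that reaches the chromosome edge
#' while still above the cutoff is flagged edge-truncated; a gap above
#' `maxGap` flags the score gap-undefined. Both flags make the score
#' excluded by default in [xpehhScan()].
#'
#' @inheritParams ehh
#' @return List with `ihh` (bp), `edgeTruncated`, `gapUndefined`.
#' @export
ihh <- function(h, core, cutoff = 0.05, maxGap = 200000, maxExtend = 1e6) {
  checkSingleChrom(h)
  a <- haplotypes(h)
  if (nrow(a) < 2) stop("iHH requires at least 2 haplotypes")
  res <- .ihh_cpp(a, as.numeric(start(sites(h))), core - 1L, cutoff, maxGap,
                  maxExtend)
  list(ihh = res$ihh,
       edgeTruncated = res$status == 1L,
       gapUndefined = res$status == 2L)
}

#' Raw XP-EHH at one core site
#'
#' `ln(iHH_sel / iHH_ref)`, both integrals taken over *all* haplotypes of
#' each population (not partitioned by core allele). Undefined when either
#' iHH is zero, edge-truncated or gap-undefined (unless
#' `includeEdgeTruncated`). Swapping the populations negates the score
#' exactly.
#'
#' @param hSel,hRef [HaplotypeMatrix-class] objects for the selected and
#'   reference populations over the same sites.
#' @param core core site index (1-based).
#' @param cutoff,maxGap,maxExtend see [ehh()].
#' @param includeEdgeTruncated keep scores whose curves hit the chromosome
#'   edge (default FALSE).
#' @return List with `ihhSel`, `ihhRef`, `raw` (`NA` when undefined).
#' @export
xpehhSite <- function(hSel, hRef, core, cutoff = 0.05, maxGap = 200000,
                      maxExtend = 1e6, includeEdgeTruncated = FALSE) {
  stopifnot(nSites(hSel) == nSites(hRef))
  iS <- ihh(hSel, core, cutoff, maxGap, maxExtend)
  iR <- ihh(hRef, core, cutoff, maxGap, maxExtend)
  bad <- iS$gapUndefined || iR$gapUndefined ||
    (!includeEdgeTruncated && (iS$edgeTruncated || iR$edgeTruncated)) ||
    iS$ihh <= 0 || iR$ihh <= 0
  list(ihhSel = iS$ihh, ihhRef = iR$ihh,
       raw = if (bad) NA_real_ else log(iS$ihh / iR$ihh))
}

#' Standardize raw XP-EHH scores genome-wide
#'
#' Single-bin normalization: `z = (raw - mean) / sd` over all defined raw
#' scores, with the population (divisor `n`) standard deviation, so the
#' standardized set has mean 0 and sd 1 by construction.
#'
#' @param raw numeric vector of raw scores (`NA` allowed, >= 2 defined).
#' @return z-scores, `NA` preserved.
#' @export
standardizeXpehh <- function(raw) {
  ok <- !is.na(raw)
  if (sum(ok) < 2L) stop("need at least 2 defined raw scores to standardize")
  mu <- mean(raw[ok])
  sdp <- sqrt(mean((raw[ok] - mu)^2))
  if (sdp == 0) stop("raw XP-EHH scores have zero variance")
  (raw - mu) / sdp
}

#' Genome-wide XP-EHH scan
#'
#' Computes the raw XP-EHH score at every site whose pooled minor allele
#' frequency is strictly above `minMaf` (default 0.05) and standardizes the
#' defined scores genome-wide. Chromosomes are scanned independently.
#'
#' @inheritParams xpehhSite
#' @param minMaf pooled-MAF inclusion threshold for core sites
#'   (default 0.05).
#' @return `data.frame` with one row per site: `chrom`, `pos` (1-based),
#'   `p_sel`, `p_ref`, `ihh_sel`, `ihh_ref`, `raw`, `z`. Sites failing the
#'   MAF rule or with undefined scores carry `NA`.
#' @export
xpehhScan <- function(hSel, hRef, minMaf = 0.05, cutoff = 0.05,
                      maxGap = 200000, maxExtend = 1e6,
                      includeEdgeTruncated = FALSE) {
  stopifnot(nSites(hSel) == nSites(hRef))
  if (!all(start(sites(hSel)) == start(sites(hRef))))
    stop("selected and reference haplotypes must share the same sites")
  aS <- haplotypes(hSel)
  aR <- haplotypes(hRef)
  s <- sites(hSel)
  chrom <- as.character(seqnames(s))
  posAll <- start(s)
  pPool <- (colSums(aS) + colSums(aR)) / (nrow(aS) + nrow(aR))
  maf <- pmin(pPool, 1 - pPool)
  out <- data.frame(
    chrom = chrom, pos = posAll,
    p_sel = colMeans(aS), p_ref = colMeans(aR),
    ihh_sel = NA_real_, ihh_ref = NA_real_,
    raw = NA_real_, z = NA_real_, stringsAsFactors = FALSE)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cores <- idx[maf[idx] > minMaf]
    if (!length(cores)) next
    res <- .xpehh_scan_cpp(aS[, idx, drop = FALSE], aR[, idx, drop = FALSE],
                           as.numeric(posAll[idx]),
                           match(cores, idx) - 1L, cutoff, maxGap, maxExtend)
    okS <- res$statusSel == 0L |
      (includeEdgeTruncated & res$statusSel == 1L)
    okR <- res$statusRef == 0L |
      (includeEdgeTruncated & res$statusRef == 1L)
    defined <- okS & okR & res$ihhSel > 0 & res$ihhRef > 0
    out$ihh_sel[cores] <- res$ihhSel
    out$ihh_ref[cores] <- res$ihhRef
    out$raw[cores[defined]] <- log(res$ihhSel[defined] / res$ihhRef[defined])
  }
  if (sum(!is.na(out$raw)) >= 2L && sd(out$raw, na.rm = TRUE) > 0)
    out$z <- standardizeXpehh(out$raw)
  out
}

#' Write a per-site XP-EHH table
#'
#' TSV column-compatible with selscan's `.xpehh.out` naming where feasible
#' (`id`, `pos`, `p1`, `ihh1`, `p2`, `ihh2`, `xpehh`, plus the standardized
#' `z`).
#'
#' @param scan `data.frame` from [xpehhScan()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXpehhTable <- function(scan, path) {
  df <- data.frame(id = paste0(scan$chrom, ":", scan$pos), pos = scan$pos,
                   p1 = numFormat(scan$p_sel), ihh1 = numFormat(scan$ihh_sel),
                   p2 = numFormat(scan$p_ref), ihh2 = numFormat(scan$ihh_ref),
                   xpehh = numFormat(scan$raw), z = numFormat(scan$z))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
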
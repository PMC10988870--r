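#' @include AllClasses.R
NULL

#' Partition chromosomes into consecutive, non-overlapping windows
#'
#' A site at 1-based position `p` belongs to window index
#' `floor((p - 1) / W)`; reported window bounds are `[i W + 1, (i + 1) W]`
#' 1-based inclusive, so the grid is anchored at multiples of `W` plus one
#' (with `W = 50000`, position 90,623,456 falls in the window
#' 90,600,001-90,650,000; position 50,000 is in window 0 and 50,001 in
#' window 1). The last window of a chromosome may be short; it is retained.
#'
#' @param sitesGR width-1 `GRanges` of (sorted) SNP positions.
#' @param chromLengths optional named vector of chromosome lengths; defaults
#'   to the largest site position per chromosome. A site beyond the declared
#'   length is an error.
#' @param windowSize window span in bp (default 50000).
#' @return List with `windows` (a `GRanges` with `windowIndex` and `nSnps`
#'   metadata columns, covering each chromosome from position 1) and
#'   `siteWindow` (the window row of every site). Every site is assigned to
#'   exactly one window.
#' @export
assignWindows <- function(sitesGR, chromLengths = NULL, windowSize = 50000L) {
  windowSize <- as.integer(windowSize)
  chrom <- as.character(seqnames(sitesGR))
  pos <- start(sitesGR)
  chromsObserved <- unique(chrom)
  if (is.null(chromLengths)) {
    chromLengths <- vapply(split(pos, chrom)[chromsObserved], max, numeric(1))
  } else {
    missing <- setdiff(chromsObserved, names(chromLengths))
    if (length(missing))
      stop("no declared length for chromosome(s): ",
           paste(missing, collapse = ", "))
    tooFar <- pos > chromLengths[chrom]
    if (any(tooFar))
      stop(sprintf("site %s:%d lies beyond the declared chromosome length %d",
                   chrom[which(tooFar)[1]], pos[which(tooFar)[1]],
                   as.integer(chromLengths[chrom[which(tooFar)[1]]])))
  }
  chroms <- if (is.null(names(chromLengths))) chromsObserved
            else intersect(names(chromLengths), chromsObserved)
  winChrom <- character(0); winIdx <- integer(0)
  winStart <- integer(0); winEnd <- integer(0)
  for (ch in chroms) {
    len <- as.integer(chromLengths[[ch]])
    n <- (len - 1L) %/% windowSize + 1L
    i <- seq_len(n) - 1L
    winChrom <- c(winChrom, rep(ch, n))
    winIdx <- c(winIdx, i)
    winStart <- c(winStart, i * windowSize + 1L)
    winEnd <- c(winEnd, pmin((i + 1L) * windowSize, len))
  }
  windows <- GRanges(winChrom, IRanges(winStart, winEnd))
  mcols(windows)$windowIndex <- winIdx
  key <- paste(winChrom, winIdx)
  siteWindow <- match(paste(chrom, (pos - 1L) %/% windowSize), key)
  mcols(windows)$nSnps <- tabulate(siteWindow, nbins = length(windows))
  list(windows = windows, siteWindow = siteWindow)
}

#' Empirical outlier threshold
#'
#' The `(1 - tail)` empirical quantile with "higher" interpolation (the
#' cutoff is always an observed value): for sorted values `v[1..n]` the
#' cutoff is `v[ceil((n - 1) (1 - tail)) + 1]`. An item is an outlier iff
#' `value >= cutoff`, so ties at the cutoff are all included. With values
#' 1..100 and a 5% tail the cutoff is 96 and the outliers are 96..100.
#'
#' @param values numeric vector (`NA` ignored).
#' @param tail upper-tail fraction (e.g. 0.05 for "top 5%").
#' @return The cutoff value.
#' @export
empiricalThreshold <- function(values, tail = 0.05) {
  v <- sort(values[!is.na(values)])
  n <- length(v)
  if (n == 0L) return(NA_real_)
  if (n < 1 / tail)
    warning(sprintf("only %d defined values for a %.3g tail; threshold noisy",
                    n, tail))
  cutoff <- v[min(n, ceiling((n - 1) * (1 - tail)) + 1L)]
  if (cutoff <= v[1L] && n > 1L)
    warning("degenerate empirical distribution: every value is an outlier")
  cutoff
}

#' One-sided Fisher window enrichment p-value
#'
#' Exact upper hypergeometric tail for a window holding `k` significant SNPs
#' out of `m`, against `K` significant among `M` genome-wide:
#' `p = sum_{i >= k} C(K, i) C(M - K, m - i) / C(M, m)` (computed in log
#' space). `k = 0` gives `p = 1`. A window is enrichment-significant when
#' `p < fisherAlpha` (the raw 0.05 rule; apply [stats::p.adjust()] to the
#' returned column for a Benjamini-Hochberg variant).
#'
#' @param k significant SNPs in the window.
#' @param m SNPs in the window.
#' @param K significant SNPs genome-wide.
#' @param M SNPs genome-wide.
#' @return The one-sided (greater) p-value; vectorized over windows.
#' @export
fisherWindowEnrichment <- function(k, m, K, M) {
  if (length(m) == 1L) m <- rep(m, length(k))
  if (any(k > m | k > K | m > M | K > M | k < 0 | m < 0))
    stop("inconsistent enrichment counts (need k <= m, k <= K, m <= M, K <= M)")
  vapply(seq_along(k), function(w) {
    i <- seq(k[w], min(m[w], K))
    if (!length(i)) return(0)
    min(1, sum(exp(lchoose(K, i) + lchoose(M - K, m[w] - i) -
                     lchoose(M, m[w]))))
  }, numeric(1))
}

## shared aggregation core for the genome scan and fine-mapping
windowAggregate <- function(windows, siteWindow, siteStats = NULL,
                            xpehh = NULL, hSel = NULL, hRef = NULL,
                            minSnps = 1L, fstTail = 0.05) {
  nw <- length(windows)
  tbl <- data.frame(
    chrom = as.character(seqnames(windows)),
    start1 = start(windows), end1 = end(windows),
    n_snps = tabulate(siteWindow, nbins = nw),
    weighted_fst = NA_real_, hudson_fst = NA_real_,
    n_significant_snps = NA_integer_, fisher_p = NA_real_,
    max_abs_xpehh = NA_real_,
    pi_sel = NA_real_, pi_ref = NA_real_, pi_ratio = NA_real_,
    log2_pi_ratio = NA_real_, tajd_sel = NA_real_, tajd_ref = NA_real_,
    stringsAsFactors = FALSE)

  sumByWin <- function(x) {
    ok <- !is.na(x) & !is.na(siteWindow)
    out <- rep(0, nw)
    if (any(ok)) {
      agg <- rowsum(x[ok], siteWindow[ok])
      out[as.integer(rownames(agg))] <- agg[, 1]
    }
    out
  }

  if (!is.null(siteStats)) {
    sumA <- sumByWin(siteStats$wc_a)
    sumAbc <- sumByWin(siteStats$wc_a + siteStats$wc_b + siteStats$wc_c)
    tbl$weighted_fst <- ifelse(sumAbc != 0, sumA / sumAbc, NA_real_)
    sumNum <- sumByWin(siteStats$hudson_num)
    sumDen <- sumByWin(siteStats$hudson_den)
    tbl$hudson_fst <- ifelse(sumDen != 0, sumNum / sumDen, NA_real_)

    fstDefined <- !is.na(siteStats$fst_site)
    M <- sum(fstDefined)
    if (M >= 1L) {
      snpCut <- suppressWarnings(
        empiricalThreshold(siteStats$fst_site, fstTail))
      sig <- fstDefined & siteStats$fst_site >= snpCut
      K <- sum(sig)
      kWin <- as.integer(sumByWin(as.numeric(sig)))
      mWin <- as.integer(sumByWin(as.numeric(fstDefined)))
      tbl$n_significant_snps <- kWin
      has <- mWin > 0L
      tbl$fisher_p[has] <- fisherWindowEnrichment(kWin[has], mWin[has], K, M)
      attr(tbl, "snpFstCutoff") <- snpCut
    }
  }

  if (!is.null(xpehh)) {
    zAbs <- abs(xpehh$z)
    ok <- !is.na(zAbs) & !is.na(siteWindow)
    if (any(ok)) {
      mx <- vapply(split(zAbs[ok], siteWindow[ok]), max, numeric(1))
      tbl$max_abs_xpehh[as.integer(names(mx))] <- mx
    }
  }

  if (!is.null(hSel) && !is.null(hRef)) {
    piSelSite <- piSite(hSel)
    piRefSite <- piSite(hRef)
    tbl$pi_sel <- sumByWin(piSelSite)
    tbl$pi_ref <- sumByWin(piRefSite)
    tbl$pi_ratio <- ifelse(tbl$pi_sel > 0, tbl$pi_ref / tbl$pi_sel, NA_real_)
    tbl$log2_pi_ratio <- log2(tbl$pi_ratio)
    byWin <- split(which(!is.na(siteWindow)),
                   siteWindow[!is.na(siteWindow)])
    for (wn in names(byWin)) {
      w <- as.integer(wn)
      idx <- byWin[[wn]]
      tbl$tajd_sel[w] <- tajimasD(hSel, idx)$D
      tbl$tajd_ref[w] <- tajimasD(hRef, idx)$D
    }
  }

  if (minSnps > 1L) {
    masked <- tbl$n_snps < minSnps
    statCols <- setdiff(names(tbl), c("chrom", "start1", "end1", "n_snps"))
    tbl[masked, statCols] <- NA
  }
  tbl
}

#' Per-window scan statistics
#'
#' Aggregates per-site and per-haplotype statistics over the 50-kb windows:
#' weighted FST (`sum a / sum (a + b + c)` of Weir-Cockerham components),
#' Hudson ratio-of-averages FST, the maximum absolute standardized XP-EHH
#' score per window, the number of significant SNPs (per-site Hudson FST in
#' the genome-wide top `fstTail`) with the one-sided Fisher enrichment
#' p-value, per-population nucleotide diversity and its reference/selected
#' ratio (values above 1 indicate diversity loss in the selected
#' population; `log2` also emitted), and per-population Tajima's D. Windows
#' with fewer than `minSnps` SNPs are masked (`NA`) for all statistics and
#' excluded from downstream quantiles.
#'
#' @param siteStats `data.frame` from [siteStatistics()].
#' @param xpehh `data.frame` from [xpehhScan()] over the same sites.
#' @param hSel,hRef per-population [HaplotypeMatrix-class] objects over the
#'   same sites.
#' @param windows result of [assignWindows()] on those sites.
#' @param thresholds a [scanThresholds()] object.
#' @return Window `data.frame` (see [writeWindowTable()] for the column
#'   layout) with the SNP-level FST cutoff in `attr(, "snpFstCutoff")`.
#' @export
computeWindowStats <- function(siteStats, xpehh, hSel, hRef, windows,
                               thresholds = scanThresholds()) {
  stopifnot(nrow(siteStats) == length(windows$siteWindow))
  windowAggregate(windows$windows, windows$siteWindow, siteStats, xpehh,
                  hSel, hRef, minSnps = thresholds@minSnps,
                  fstTail = thresholds@fstTail)
}

#' Call candidate sweep windows and merge them into sweep regions
#'
#' Default `rule = "intersect"`: a window is flagged when its weighted FST
#' and its max |XP-EHH| both lie in their top-`fstTail`/`xpehhTail`
#' empirical tails (cutoffs computed over unmasked windows; an item equal to
#' the cutoff is an outlier) *and* its Fisher enrichment p-value is below
#' `fisherAlpha`. `rule = "xpehh_1pct"`: windows in the top
#' `windowTail1pct` right tail of max |XP-EHH|. Flagged windows become
#' sweeps and adjacent sweeps within `mergeGap` bp are merged (a gap of
#' exactly `mergeGap` merges; merging is transitive, idempotent and
#' order-independent). No flagged window yields an empty result, not an
#' error.
#'
#' @param tbl window table from [computeWindowStats()].
#' @param thresholds a [scanThresholds()] object.
#' @param rule `"intersect"` or `"xpehh_1pct"`.
#' @return List with `sweeps` (merged `GRanges` with `nWindows`, `peakFst`,
#'   `peakXpehh`), `table` (the input plus `outlier_fst`, `outlier_xpehh`,
#'   `fisher_sig`, `sweep_window` flag columns) and `cutoffs`.
#' @export
callSweeps <- function(tbl, thresholds = scanThresholds(),
                       rule = c("intersect", "xpehh_1pct")) {
  rule <- match.arg(rule)
  fstCut <- suppressWarnings(
    empiricalThreshold(tbl$weighted_fst, thresholds@fstTail))
  xpCut <- suppressWarnings(
    empiricalThreshold(tbl$max_abs_xpehh, thresholds@xpehhTail))
  xp1Cut <- suppressWarnings(
    empiricalThreshold(tbl$max_abs_xpehh, thresholds@windowTail1pct))
  tbl$outlier_fst <- !is.na(tbl$weighted_fst) & !is.na(fstCut) &
    tbl$weighted_fst >= fstCut
  tbl$outlier_xpehh <- !is.na(tbl$max_abs_xpehh) & !is.na(xpCut) &
    tbl$max_abs_xpehh >= xpCut
  tbl$fisher_sig <- !is.na(tbl$fisher_p) &
    tbl$fisher_p < thresholds@fisherAlpha
  tbl$sweep_window <- if (rule == "intersect") {
    tbl$outlier_fst & tbl$outlier_xpehh & tbl$fisher_sig
  } else {
    !is.na(tbl$max_abs_xpehh) & !is.na(xp1Cut) & tbl$max_abs_xpehh >= xp1Cut
  }
  flagged <- which(tbl$sweep_window)
  if (length(flagged)) {
    regions <- GRanges(tbl$chrom[flagged],
                       IRanges(tbl$start1[flagged], tbl$end1[flagged]))
    mcols(regions)$weighted_fst <- tbl$weighted_fst[flagged]
    mcols(regions)$max_abs_xpehh <- tbl$max_abs_xpehh[flagged]
    sweeps <- mergeSweeps(regions, thresholds@mergeGap)
  } else {
    sweeps <- GRanges()
    mcols(sweeps)$nWindows <- integer(0)
    mcols(sweeps)$peakFst <- numeric(0)
    mcols(sweeps)$peakXpehh <- numeric(0)
  }
  list(sweeps = sweeps, table = tbl,
       cutoffs = list(fst = fstCut, xpehh = xpCut, xpehh1pct = xp1Cut,
                      rule = rule))
}

#' Merge adjacent sweep regions
#'
#' Two regions on the same chromosome merge when the gap between them is at
#' most `mergeGap` bp (a gap of exactly `mergeGap` merges); merging is
#' transitive. Peak statistics of a merged region are the member maxima.
#'
#' @param regions sweep `GRanges` (any order), optionally with
#'   `weighted_fst` / `max_abs_xpehh` metadata columns.
#' @param mergeGap maximum gap in bp (default 50000).
#' @return Merged `GRanges`, sorted, with `nWindows`, `peakFst`,
#'   `peakXpehh`.
#' @export
mergeSweeps <- function(regions, mergeGap = 50000L) {
  merged <- reduce(sort(regions), min.gapwidth = as.integer(mergeGap) + 1L)
  hits <- findOverlaps(regions, merged)
  grp <- S4Vectors::subjectHits(hits)
  nWin <- tabulate(grp, nbins = length(merged))
  mcols(merged)$nWindows <- nWin
  peak <- function(col) {
    out <- rep(NA_real_, length(merged))
    if (col %in% names(mcols(regions))) {
      v <- mcols(regions)[[col]][S4Vectors::queryHits(hits)]
      ok <- !is.na(v)
      if (any(ok)) {
        mx <- vapply(split(v[ok], grp[ok]), max, numeric(1))
        out[as.integer(names(mx))] <- mx
      }
    }
    out
  }
  mcols(merged)$peakFst <- peak("weighted_fst")
  mcols(merged)$peakXpehh <- peak("max_abs_xpehh")
  merged
}

#' Attach overlapping genes to sweep regions
#'
#' A gene is attached when its interval overlaps the sweep by at least one
#' base. Intervals follow the half-open input conventions at the
#' boundaries: a BED gene ending exactly where a sweep starts does not
#' overlap it.
#'
#' @param sweeps sweep `GRanges`.
#' @param genes gene `GRanges` from [readGeneAnnotation()] (a `gene`
#'   metadata column; chromosome naming must match the sweeps).
#' @return `sweeps` with a `genes` `CharacterList` metadata column (sorted,
#'   unique).
#' @export
annotateSweeps <- function(sweeps, genes) {
  hits <- findOverlaps(sweeps, genes, minoverlap = 1L)
  lst <- rep(list(character(0)), length(sweeps))
  if (length(hits)) {
    sp <- split(mcols(genes)$gene[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (nm in names(sp)) lst[[as.integer(nm)]] <- sort(unique(sp[[nm]]))
  }
  mcols(sweeps)$genes <- CharacterList(lst)
  sweeps
}

#' Fine-map a candidate region with sliding sub-windows
#'
#' Re-evaluates the window statistics on sliding sub-windows inside a
#' region (default sub-window 50,000 bp with step = size; a 1,000-bp sliding
#' grid is equally supported). With sub-window equal to the region and the
#' genome-scan inputs, the single row reproduces the genome-scan row. When
#' `step < subWindow` the rows overlap and their spans jointly cover the
#' region. Empty sub-windows are masked.
#'
#' @param hSel,hRef population [HaplotypeMatrix-class] objects.
#' @param region `"chrom:start-end"` (1-based inclusive) or a length-1
#'   `GRanges`.
#' @param xpehh optional genome-standardized [xpehhScan()] table (z-scores
#'   are *not* re-standardized locally).
#' @param siteStats optional [siteStatistics()] table for FST columns.
#' @param subWindow sub-window size in bp (default 50000).
#' @param step slide step in bp (default `subWindow`).
#' @param minSnps mask sub-windows with fewer SNPs (default 1).
#' @return Sub-window `data.frame` in the [writeWindowTable()] layout.
#' @export
fineMapRegion <- function(hSel, hRef, region, xpehh = NULL, siteStats = NULL,
                          subWindow = 50000L, step = subWindow,
                          minSnps = 1L) {
  if (is.character(region)) {
    rg <- parseRegion(region)
  } else {
    rg <- list(chrom = as.character(seqnames(region))[1],
               start = start(region)[1], end = end(region)[1])
  }
  s <- sites(hSel)
  chrom <- as.character(seqnames(s))
  pos <- start(s)
  starts <- seq(rg$start, rg$end, by = step)
  ends <- pmin(starts + subWindow - 1L, rg$end)
  keepWin <- starts <= rg$end
  windows <- GRanges(rg$chrom, IRanges(starts[keepWin], ends[keepWin]))
  ## assign each site to the first covering sub-window; with step >= size
  ## this is the unique one. Overlapping grids re-count sites per window.
  if (step < subWindow) {
    tblList <- lapply(seq_along(windows), function(w) {
      inWin <- chrom == rg$chrom & pos >= start(windows)[w] &
        pos <= end(windows)[w]
      siteWindow <- ifelse(inWin, 1L, NA_integer_)
      windowAggregate(windows[w], siteWindow, siteStats, xpehh, hSel, hRef,
                      minSnps = minSnps)
    })
    tbl <- do.call(rbind, tblList)
  } else {
    inReg <- chrom == rg$chrom & pos >= rg$start & pos <= rg$end
    siteWindow <- rep(NA_integer_, length(pos))
    siteWindow[inReg] <- (pos[inReg] - rg$start) %/% step + 1L
    siteWindow[!is.na(siteWindow) & siteWindow > length(windows)] <- NA
    tbl <- windowAggregate(windows, siteWindow, siteStats, xpehh, hSel, hRef,
                           minSnps = minSnps)
  }
  tbl
}

#' Genes shared across scans
#'
#' Intersection of candidate-gene sets across two or more scans, plus all
#' pairwise intersections, in deterministic lexicographic order.
#'
#' @param geneSets named list (>= 2) of character vectors.
#' @return List with `shared` (genes in every scan) and `pairwise`
#'   (`data.frame` with `scanA`, `scanB`, `nShared`, `genes`).
#' @export
sharedGenes <- function(geneSets) {
  if (length(geneSets) < 2L) stop("need at least two scans")
  sets <- lapply(geneSets, function(x) sort(unique(as.character(x))))
  shared <- sort(Reduce(intersect, sets))
  prs <- utils::combn(names(sets), 2)
  pairwise <- data.frame(
    scanA = prs[1, ], scanB = prs[2, ],
    nShared = apply(prs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    genes = apply(prs, 2, function(p)
      paste(sort(intersect(sets[[p[1]]], sets[[p[2]]])), collapse = ",")),
    stringsAsFactors = FALSE)
  list(shared = shared, pairwise = pairwise)
}
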
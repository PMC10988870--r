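#' @include AllClasses.R
NULL

#' Per-site Hudson FST components
#'
#' Hudson estimator of per-site FST in the Bhatia et al. ratio form. With
#' `p_i = x_i / n_i`,
#' numerator `= (p1 - p2)^2 - p1 (1 - p1) / (n1 - 1) - p2 (1 - p2) / (n2 - 1)`
#' and denominator `= p1 (1 - p2) + p2 (1 - p1)`. Components are returned
#' separately so windows and genome-wide summaries can aggregate as a ratio
#' of averages (sum of numerators over sum of denominators), the standard
#' practice that avoids the upward bias of averaging per-site ratios.
#' Per-site values are never clamped to `[0, 1]`; a site with `p1 = p2` has a
#' non-positive numerator, and a fixed difference gives FST = 1 in the
#' large-sample limit.
#'
#' @param n1,n2 called allele counts (`>= 2`) in the two populations
#'   (vectorized).
#' @param x1,x2 alternate allele counts.
#' @return `data.frame` with columns `num`, `den` and `fst`
#'   (`num / den`, `NA` where `den == 0`).
#' @export
hudsonFstSite <- function(n1, x1, n2, x2) {
  if (any(n1 < 2 | n2 < 2, na.rm = TRUE))
    stop("Hudson sample-size correction requires n >= 2 alleles per population")
  p1 <- x1 / n1
  p2 <- x2 / n2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(num = num, den = den,
             fst = ifelse(den > 0, num / den, NA_real_))
}

#' Hudson FST as a ratio of averages
#'
#' `sum(num) / sum(den)` over sites with defined components; the window- and
#' genome-level aggregate of [hudsonFstSite()].
#'
#' @param num,den per-site Hudson components.
#' @return A single FST estimate (`NA` when no site has positive total
#'   denominator).
#' @export
hudsonFstRatio <- function(num, den) {
  ok <- !is.na(num) & !is.na(den)
  s <- sum(den[ok])
  if (!any(ok) || s == 0) return(NA_real_)
  sum(num[ok]) / s
}

#' Per-site Weir-Cockerham variance components (two populations)
#'
#' The a (among-population), b (among-individual within population) and c
#' (within-individual) variance components of Weir & Cockerham's 1984
#' estimator for two populations, using observed heterozygote fractions
#' from diploid genotypes. The weighted window FST used by the scan is
#' `sum(a) / sum(a + b + c)` over the window's sites (the "weighted"
#' estimate VCFtools reports).
#'
#' @param n1,n2 numbers of diploid individuals with called genotypes
#'   (vectorized; `(n1 + n2) / 2 > 1` required).
#' @param p1,p2 alternate allele frequencies.
#' @param h1,h2 observed heterozygote fractions.
#' @return `data.frame` with columns `a`, `b`, `c`.
#' @export
wcComponentsSite <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  if (any(nbar <= 1, na.rm = TRUE))
    stop("Weir-Cockerham components require mean sample size > 1 diploid")
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  data.frame(a = a, b = b, c = cc)
}

#' Per-site statistics table for a two-population scan
#'
#' Computes, for every site, the allele frequencies and called allele counts
#' in the selected and reference populations, the Hudson numerator and
#' denominator, the Weir-Cockerham a/b/c components (from diploid observed
#' heterozygosity) and the per-site Hudson FST ratio. Sites where either
#' population has fewer than two called alleles (or no diploid data) have
#' undefined (`NA`) statistics: undefined values are masked, never
#' zero-filled, so empirical quantiles are not distorted.
#'
#' @param g a filtered [GenotypeMatrix-class] containing both populations.
#' @param assignment named population vector covering `sampleIds(g)`.
#' @param selected,reference population labels of the scan pair.
#' @return `data.frame` keyed by `chrom`, `pos` (1-based) with columns
#'   `p_sel`, `p_ref`, `n_sel`, `n_ref`, `hudson_num`, `hudson_den`,
#'   `wc_a`, `wc_b`, `wc_c`, `fst_site`.
#' @export
siteStatistics <- function(g, assignment, selected, reference) {
  ids <- sampleIds(g)
  selIds <- ids[!is.na(assignment[ids]) & assignment[ids] == selected]
  refIds <- ids[!is.na(assignment[ids]) & assignment[ids] == reference]
  if (length(selIds) == 0L || length(refIds) == 0L)
    stop("both scan populations must be non-empty")
  d <- dosage(g)
  dSel <- d[selIds, , drop = FALSE]
  dRef <- d[refIds, , drop = FALSE]

  nSel <- 2L * colSums(!is.na(dSel))
  nRef <- 2L * colSums(!is.na(dRef))
  xSel <- colSums(dSel, na.rm = TRUE)
  xRef <- colSums(dRef, na.rm = TRUE)
  pSel <- ifelse(nSel > 0, xSel / nSel, NA_real_)
  pRef <- ifelse(nRef > 0, xRef / nRef, NA_real_)

  ok <- nSel >= 2L & nRef >= 2L
  num <- den <- rep(NA_real_, nSites(g))
  if (any(ok)) {
    hh <- hudsonFstSite(nSel[ok], xSel[ok], nRef[ok], xRef[ok])
    num[ok] <- hh$num
    den[ok] <- hh$den
  }

  h1 <- colMeans(dSel == 1L, na.rm = TRUE)
  h2 <- colMeans(dRef == 1L, na.rm = TRUE)
  wa <- wb <- wc <- rep(NA_real_, nSites(g))
  okw <- ok & (nSel / 2 + nRef / 2) / 2 > 1  # nbar > 1 diploid required
  if (any(okw)) {
    comp <- wcComponentsSite(nSel[okw] / 2, pSel[okw], h1[okw],
                             nRef[okw] / 2, pRef[okw], h2[okw])
    wa[okw] <- comp$a
    wb[okw] <- comp$b
    wc[okw] <- comp$c
  }

  s <- sites(g)
  data.frame(
    chrom = as.character(seqnames(s)), pos = start(s),
    p_sel = pSel, p_ref = pRef,
    n_sel = as.integer(nSel), n_ref = as.integer(nRef),
    hudson_num = num, hudson_den = den,
    wc_a = wa, wc_b = wb, wc_c = wc,
    fst_site = ifelse(!is.na(den) & den > 0, num / den, NA_real_),
    stringsAsFactors = FALSE)
}

#' Per-site unbiased heterozygosity (pi contribution)
#'
#' `2 p (1 - p) n / (n - 1)` per site from haplotype allele frequencies; the
#' per-site term whose sum over a window is the window's nucleotide
#' diversity. Equals the mean pairwise Hamming distance over all haplotype
#' pairs.
#'
#' @param h a [HaplotypeMatrix-class] (or 0/1 matrix), `n >= 2` haplotypes.
#' @param siteIdx site indices (default all).
#' @return Numeric vector of per-site diversity terms.
#' @export
piSite <- function(h, siteIdx = NULL) {
  a <- if (is(h, "HaplotypeMatrix")) haplotypes(h) else h
  if (is.null(siteIdx)) siteIdx <- seq_len(ncol(a))
  n <- nrow(a)
  if (n < 2) stop("pi requires at least 2 haplotypes")
  p <- colMeans(a[, siteIdx, drop = FALSE])
  2 * p * (1 - p) * n / (n - 1)
}

#' Window nucleotide diversity
#'
#' Sum of [piSite()] over the window's sites; also returned per bp when the
#' window span is given.
#'
#' @param h a [HaplotypeMatrix-class] or 0/1 haplotype matrix.
#' @param siteIdx indices of the window's sites.
#' @param span optional window span in bp for the per-bp value.
#' @return List with `pi` (per-window sum) and `piPerBp` (`NA` without
#'   `span`).
#' @export
piWindow <- function(h, siteIdx = NULL, span = NULL) {
  tot <- sum(piSite(h, siteIdx))
  list(pi = tot, piPerBp = if (is.null(span)) NA_real_ else tot / span)
}

#' Tajima's D and companions for a haplotype slice
#'
#' Computes the segregating-site count S, nucleotide diversity pi, Watterson
#' estimator `theta_w = S / a1` and Tajima's D
#' `(pi - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the standard constants
#' (`a1 = sum_{i<n} 1/i`, `a2 = sum_{i<n} 1/i^2`, `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2 (n^2 + n + 3) / (9 n (n - 1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`). D is undefined (`NA`) when `S = 0`.
#'
#' @param h a [HaplotypeMatrix-class] or 0/1 matrix slice (`n >= 4`
#'   haplotypes).
#' @param siteIdx optional site indices restricting the slice.
#' @return List with `S`, `pi`, `thetaW`, `D`, `n`.
#' @export
tajimasD <- function(h, siteIdx = NULL) {
  a <- if (is(h, "HaplotypeMatrix")) haplotypes(h) else h
  if (!is.null(siteIdx)) a <- a[, siteIdx, drop = FALSE]
  n <- nrow(a)
  if (n < 4) stop("Tajima's D requires at least 4 haplotypes")
  cnt <- colSums(a)
  seg <- cnt > 0L & cnt < n
  S <- sum(seg)
  p <- cnt[seg] / n
  pi <- sum(2 * p * (1 - p) * n / (n - 1))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  thetaW <- S / a1
  if (S == 0L)
    return(list(S = 0L, pi = 0, thetaW = 0, D = NA_real_, n = n))
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - thetaW) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = as.integer(S), pi = pi, thetaW = thetaW, D = D, n = n)
}

#' Pairwise linkage disequilibrium r^2
#'
#' Squared allelic correlation between two phased sites: with marginal
#' frequencies `pA`, `pB` and joint haplotype frequency `pAB`,
#' `D = pAB - pA pB` and `r^2 = D^2 / (pA (1 - pA) pB (1 - pB))`. Undefined
#' when either site is monomorphic in the chosen haplotypes (the pair is
#' skipped).
#'
#' @param h a [HaplotypeMatrix-class] or 0/1 matrix.
#' @param i,j site indices.
#' @param samples optional sample-id subset (population restriction).
#' @return `r^2` in `[0, 1]`, or `NA` for a monomorphic site.
#' @export
ldR2Pair <- function(h, i, j, samples = NULL) {
  if (is(h, "HaplotypeMatrix")) {
    if (!is.null(samples)) h <- h[samples, ]
    a <- haplotypes(h)
  } else a <- h
  x <- a[, i]
  y <- a[, j]
  pA <- mean(x)
  pB <- mean(y)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  pAB <- mean(x == 1L & y == 1L)
  Dld <- pAB - pA * pB
  Dld^2 / (pA * (1 - pA) * pB * (1 - pB))
}
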
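#' @include AllClasses.R
NULL

#' Pairwise Hudson FST distance matrix between populations
#'
#' Entry (i, j) is the Hudson ratio-of-averages FST over all sites where
#' both populations have at least two called alleles. Negative pairwise
#' estimates (expected between weakly diverged populations) are clamped to
#' zero; the number of clamped entries is recorded in
#' `attr(, "nClamped")` and messaged.
#'
#' @param g a [GenotypeMatrix-class].
#' @param assignment named population vector covering `sampleIds(g)`; every
#'   population needs at least two samples.
#' @return Symmetric matrix with zero diagonal, labelled by population, in
#'   order of first appearance.
#' @export
pairwiseFstMatrix <- function(g, assignment) {
  ids <- sampleIds(g)
  pops <- unique(unname(assignment[ids]))
  pops <- pops[!is.na(pops)]
  small <- vapply(pops, function(p) sum(assignment[ids] == p, na.rm = TRUE),
                  numeric(1)) < 2
  if (any(small))
    stop("population(s) with fewer than 2 samples: ",
         paste(pops[small], collapse = ", "))
  d <- dosage(g)
  stat <- lapply(pops, function(p) {
    dd <- d[ids[!is.na(assignment[ids]) & assignment[ids] == p], ,
            drop = FALSE]
    n <- 2L * colSums(!is.na(dd))
    list(n = n, x = colSums(dd, na.rm = TRUE))
  })
  names(stat) <- pops
  k <- length(pops)
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  nClamped <- 0L
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    a <- stat[[i]]; b <- stat[[j]]
    ok <- a$n >= 2L & b$n >= 2L
    hh <- hudsonFstSite(a$n[ok], a$x[ok], b$n[ok], b$x[ok])
    est <- hudsonFstRatio(hh$num, hh$den)
    if (is.na(est)) est <- 0
    if (est < 0) { nClamped <- nClamped + 1L; est <- 0 }
    m[i, j] <- m[j, i] <- est
  }
  if (nClamped > 0L)
    message(nClamped, " negative pairwise FST value(s) clamped to 0")
  attr(m, "nClamped") <- nClamped
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion
#' `Q(i, j) = (r - 2) d(i, j) - R_i - R_j`. Ties are broken
#' deterministically by the lexicographically smallest pair of subtree
#' labels (each subtree labelled by its smallest leaf). Negative branch
#' lengths are clamped to zero with the deficit moved to the sibling edge,
#' so an additive input reproduces its path-length matrix exactly. The final
#' three nodes are joined by the three-point formulas, giving the standard
#' unrooted trifurcating root.
#'
#' @param d symmetric distance matrix with labelled rows/columns
#'   (`n >= 3`; asymmetry beyond 1e-8 is an error).
#' @return An [ape] `phylo` tree; serialize with [ape::write.tree()].
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor-joining requires at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  nwk <- labels          # newick string per active node
  key <- labels          # smallest leaf label per subtree (tie-breaking)
  D <- d
  fmt <- function(x) sprintf("%.12g", x)
  while (nrow(D) > 3) {
    r <- nrow(D)
    Rsum <- rowSums(D)
    best <- NULL
    for (i in seq_len(r - 1)) for (j in seq(i + 1, r)) {
      q <- (r - 2) * D[i, j] - Rsum[i] - Rsum[j]
      pairKey <- paste(sort(c(key[i], key[j])), collapse = "\r")
      if (is.null(best) || q < best$q - 1e-12 ||
          (abs(q - best$q) <= 1e-12 && pairKey < best$key))
        best <- list(q = q, i = i, j = j, key = pairKey)
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newNwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    newKey <- min(key[i], key[j])
    others <- setdiff(seq_len(r), c(i, j))
    newD <- (D[i, others] + D[j, others] - D[i, j]) / 2
    D <- rbind(cbind(D[others, others, drop = FALSE], newD),
               c(newD, 0))
    nwk <- c(nwk[others], newNwk)
    key <- c(key[others], newKey)
  }
  ## three-point join
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  cc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- c(a, b, cc)
  for (kk in 1:3) if (v[kk] < 0) {
    deficit <- v[kk]; v[kk] <- 0
    sib <- which.max(v)
    v[sib] <- v[sib] + deficit
  }
  txt <- paste0("(", nwk[1], ":", fmt(v[1]), ",", nwk[2], ":", fmt(v[2]),
                ",", nwk[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = txt)
}

#' Principal component analysis of a genotype matrix
#'
#' Patterson-style PCA: each site is centered at `2 p` and scaled by
#' `sqrt(2 p (1 - p))` with `p` the sample alternate-allele frequency;
#' missing dosages are mean-imputed (zero after centering); the
#' sample-by-sample covariance matrix (normalized by the number of sites) is
#' eigendecomposed. Coordinates are the eigenvectors scaled by the square
#' root of their eigenvalue, so the coordinate cross-product is diagonal
#' with the eigenvalues on the diagonal. Eigenvector signs are fixed so
#' each component's largest-magnitude entry is positive (reproducible
#' output). Monomorphic sites must be filtered beforehand.
#'
#' @param g a [GenotypeMatrix-class] without monomorphic sites.
#' @param k number of components (`<= nSamples(g)`).
#' @return List with `coords` (samples x k), `eigenvalues` (all,
#'   non-increasing), `varFrac`, `rotation` (orthonormal eigenvectors).
#' @export
genotypePca <- function(g, k = 10L) {
  n <- nSamples(g)
  if (k > n) stop("k cannot exceed the number of samples")
  d <- dosage(g)
  af <- alleleFrequency(g)
  p <- af$freq
  if (any(is.na(p) | p <= 0 | p >= 1))
    stop("monomorphic or all-missing sites present; filter before PCA")
  X <- sweep(d, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  C <- tcrossprod(X) / ncol(X)
  eg <- eigen(C, symmetric = TRUE)
  vals <- eg$values
  vecs <- eg$vectors
  for (cmp in seq_len(ncol(vecs))) {
    mi <- which.max(abs(vecs[, cmp]))
    if (vecs[mi, cmp] < 0) vecs[, cmp] <- -vecs[, cmp]
  }
  rownames(vecs) <- rownames(d)
  coords <- vecs[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals[seq_len(k)], 0)), k, k)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coords = coords, eigenvalues = vals,
       varFrac = pmax(vals, 0) / sum(pmax(vals, 0)),
       rotation = vecs[, seq_len(k), drop = FALSE])
}

#' Linkage-disequilibrium decay curves
#'
#' For each population, all intra-chromosomal site pairs separated by at
#' most `maxDist` bp are scored with the squared allelic correlation r^2 and
#' binned by distance. The half-decay distance is the smallest bin midpoint
#' where the mean r^2 is at most half the maximum binned mean. Sites
#' monomorphic within a population yield no defined pairs; a population
#' where every site is monomorphic gives an empty curve.
#'
#' @param h a [HaplotypeMatrix-class].
#' @param assignment optional named population vector; `NULL` treats all
#'   samples as one population named `"all"`. Populations need at least 4
#'   haplotypes (2 diploid samples).
#' @param maxDist maximum pair separation in bp (default 500000).
#' @param binWidth distance bin width in bp (default 1000).
#' @return List with `curves` (`data.frame`: `population`, `bin_mid`,
#'   `mean_r2`, `n_pairs`) and `halfDecay` (named numeric, bp).
#' @export
ldDecay <- function(h, assignment = NULL, maxDist = 500000L,
                    binWidth = 1000L) {
  if (is.null(assignment))
    assignment <- setNames(rep("all", nSamples(h)), sampleIds(h))
  pops <- unique(unname(assignment[sampleIds(h)]))
  curves <- list()
  halfDecay <- setNames(rep(NA_real_, length(pops)), pops)
  for (p in pops) {
    hp <- h[sampleIds(h)[assignment[sampleIds(h)] == p], ]
    a <- haplotypes(hp)
    if (nrow(a) < 4) stop("population '", p, "' has fewer than 4 haplotypes")
    s <- sites(hp)
    chroms <- as.character(seqnames(s))
    binSum <- numeric(0); binN <- numeric(0)
    nBins <- ceiling(maxDist / binWidth)
    binSum <- numeric(nBins); binN <- numeric(nBins)
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      pfreq <- colMeans(a[, idx, drop = FALSE])
      poly <- pfreq > 0 & pfreq < 1
      idx <- idx[poly]
      if (length(idx) < 2) next
      pos <- start(s)[idx]
      A <- a[, idx, drop = FALSE]
      block <- 512L
      nI <- length(idx)
      for (b0 in seq(1L, nI - 1L, by = block)) {
        b1 <- min(b0 + block - 1L, nI - 1L)
        jMax <- max(which(pos <= pos[b1] + maxDist))
        if (jMax <= b0) next
        cc <- suppressWarnings(
          stats::cor(A[, b0:b1, drop = FALSE],
                     A[, b0:jMax, drop = FALSE]))^2
        for (ii in b0:b1) {
          if (ii + 1L > jMax) next
          jj <- seq(ii + 1L, jMax)
          dist <- pos[jj] - pos[ii]
          keep <- dist >= 1 & dist <= maxDist
          if (!any(keep)) next
          bins <- pmin(nBins, (dist[keep] - 1) %/% binWidth + 1)
          r2 <- cc[ii - b0 + 1L, jj[keep] - b0 + 1L]
          agg <- rowsum(r2, bins)
          bIdx <- as.integer(rownames(agg))
          binSum[bIdx] <- binSum[bIdx] + agg[, 1]
          cnt <- rowsum(rep(1, length(bins)), bins)
          binN[bIdx] <- binN[bIdx] + cnt[, 1]
        }
      }
    }
    has <- binN > 0
    mid <- (seq_len(nBins) - 0.5) * binWidth
    cur <- data.frame(population = rep(p, sum(has)), bin_mid = mid[has],
                      mean_r2 = binSum[has] / binN[has],
                      n_pairs = as.integer(binN[has]),
                      stringsAsFactors = FALSE)
    curves[[p]] <- cur
    if (nrow(cur)) {
      half <- max(cur$mean_r2) / 2
      hit <- which(cur$mean_r2 <= half)
      if (length(hit)) halfDecay[p] <- cur$bin_mid[min(hit)]
    }
  }
  list(curves = do.call(rbind, curves), halfDecay = halfDecay)
}

#' Write LD decay curves to TSV
#' @param ld result of [ldDecay()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLdCurves <- function(ld, path) {
  out <- ld$curves
  out$mean_r2 <- numFormat(out$mean_r2)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
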
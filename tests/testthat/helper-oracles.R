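# Independent oracle implementations used to cross-check the package's
# estimators. These are deliberately written as direct transcriptions of the
# published formulas or as brute-force enumerations, sharing no code with
# the implementation under test.

# Hudson/Bhatia per-site FST, written as the unbiased variance form
oracleHudson <- function(n1, x1, n2, x2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  num <- (p1 - p2)^2 -
    (x1 * (n1 - x1)) / (n1^2 * (n1 - 1)) -
    (x2 * (n2 - x2)) / (n2^2 * (n2 - 1))
  den <- p1 + p2 - 2 * p1 * p2
  list(num = num, den = den)
}

# Weir & Cockerham 1984 variance components, independent transcription
oracleWC <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nb <- mean(c(n1, n2))
  nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pb <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pb)^2 + n2 * (p2 - pb)^2) / ((r - 1) * nb)
  hb <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nb / nc * (s2 - 1 / (nb - 1) * (pb * (1 - pb) - (r - 1) / r * s2 - hb / 4))
  b <- nb / (nb - 1) * (pb * (1 - pb) - (r - 1) / r * s2 -
                          (2 * nb - 1) / (4 * nb) * hb)
  cc <- hb / 2
  list(a = a, b = b, c = cc)
}

# nucleotide diversity as the mean pairwise Hamming distance over all
# haplotype pairs (enumeration)
oraclePiPairwise <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(mat[i, ] != mat[j, ])
  tot / choose(n, 2)
}

# Tajima's D with constants recomputed from scratch
oracleTajimaD <- function(mat) {
  n <- nrow(mat)
  cnt <- colSums(mat)
  seg <- which(cnt > 0 & cnt < n)
  S <- length(seg)
  if (S == 0) return(NA_real_)
  piHat <- oraclePiPairwise(mat[, seg, drop = FALSE])
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (piHat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# r^2 from a direct 2x2 haplotype tally
oracleR2 <- function(x, y) {
  pA <- mean(x); pB <- mean(y)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# one-sided (greater) hypergeometric tail via direct summation of choose()
oracleHyperTail <- function(k, m, K, M) {
  i <- seq(k, min(m, K))
  sum(choose(K, i) * choose(M - K, m - i)) / choose(M, m)
}

# EHH by explicit string enumeration
oracleEhh <- function(mat, core, j) {
  lo <- min(core, j); hi <- max(core, j)
  span <- setdiff(seq(lo, hi), core)
  strs <- apply(mat[, span, drop = FALSE], 1, paste, collapse = "")
  m <- table(strs)
  sum(choose(m, 2)) / choose(nrow(mat), 2)
}

# random small genotype fixtures
randomGenotypeMatrix <- function(nSamples, nSites, missingRate = 0) {
  d <- matrix(rbinom(nSamples * nSites, 2L, runif(nSites, 0.1, 0.9)[
    rep(seq_len(nSites), each = nSamples)]), nrow = nSamples)
  if (missingRate > 0)
    d[runif(length(d)) < missingRate] <- NA_integer_
  rownames(d) <- paste0("s", seq_len(nSamples))
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(
    sort(sample.int(nSites * 1000L, nSites)), width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(
    as.list(rep("T", nSites)))
  GenotypeMatrix(s, d)
}

randomHaplotypeMatrix <- function(nSamples, nSites, posMax = nSites * 500L) {
  a <- matrix(rbinom(2L * nSamples * nSites, 1L, runif(nSites, 0.1, 0.9)[
    rep(seq_len(nSites), each = 2L * nSamples)]), nrow = 2L * nSamples)
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(
    sort(sample.int(posMax, nSites)), width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(
    as.list(rep("T", nSites)))
  HaplotypeMatrix(s, a, paste0("s", seq_len(nSamples)))
}

writeToyVcf <- function(bodyLines, samples,
                        path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(samples, collapse = "\t")),
    bodyLines), path)
  path
}
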
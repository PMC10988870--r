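test_that("NJ solves the 3-taxon star by the three-point formulas", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  pl <- ape::cophenetic.phylo(tr)[c("A", "B", "C"), c("A", "B", "C")]
  expect_equal(pl, d, tolerance = 1e-9)
  el <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("A", "B", "C")]), c(0, 2, 4), tolerance = 1e-9)
})

test_that("NJ recovers the additive 4-taxon tree with its internal edge", {
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 3,
                6, 7, 3, 0), 4, dimnames = list(lab, lab))
  tr <- njTree(d)
  pl <- ape::cophenetic.phylo(tr)[lab, lab]
  expect_equal(pl, d, tolerance = 1e-9)
  # AB|CD topology: internal edge length 3
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(sort(internal), 3, tolerance = 1e-9)
  # unrooted binary tree edge count: 2n - 3
  expect_equal(nrow(tr$edge), 2 * 4 - 3)
})

test_that("NJ reconstructs path lengths of random additive matrices exactly", {
  set.seed(123)
  for (i in 1:10) {
    n <- sample(4:9, 1)
    rt <- ape::rtree(n, br = function(k) runif(k, 0.1, 2))
    rt$edge.length <- runif(nrow(rt$edge), 0.1, 2)
    d <- ape::cophenetic.phylo(ape::unroot(rt))
    lab <- rownames(d)
    tr <- njTree(d)
    pl <- ape::cophenetic.phylo(tr)[lab, lab]
    expect_equal(pl, d, tolerance = 1e-8)
    # cross-check against the reference NJ implementation
    plApe <- ape::cophenetic.phylo(ape::nj(as.dist(d)))[lab, lab]
    expect_equal(pl, plApe, tolerance = 1e-8)
  }
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- matrix(c(0, 1, 2, 2, 0, 3, 1, 3, 0), 3)
  expect_error(njTree(bad), "symmetric")
})

test_that("pairwise FST matrix recovers trivial and simulated divergence", {
  # identical populations (duplicated genotypes) -> 0 after clamping
  set.seed(31)
  d0 <- matrix(rbinom(10 * 30, 2, 0.4), 10)
  d <- rbind(d0, d0)
  rownames(d) <- paste0("s", 1:20)
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(1:30 * 100L, width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(as.list(rep("T", 30)))
  g <- GenotypeMatrix(s, d)
  assign <- setNames(rep(c("X", "Y"), each = 10), paste0("s", 1:20))
  suppressMessages(m <- pairwiseFstMatrix(g, assign))
  expect_equal(m["X", "Y"], 0)
  expect_equal(diag(m), c(X = 0, Y = 0))
  # populations fixed for opposite alleles -> FST 1
  dF <- rbind(matrix(2L, 5, 20), matrix(0L, 5, 20))
  rownames(dF) <- paste0("s", 1:10)
  gF <- GenotypeMatrix(s[1:20], dF)
  assignF <- setNames(rep(c("X", "Y"), each = 5), paste0("s", 1:10))
  mF <- pairwiseFstMatrix(gF, assignF)
  expect_equal(mF["X", "Y"], 1)
  expect_error(pairwiseFstMatrix(gF, setNames(c("X", rep("Y", 9)),
                                              paste0("s", 1:10))),
               "fewer than 2")
  # Balding-Nichols parameter recovery at F = 0.1
  sim <- simulateBaldingNichols(F = 0.1, seed = 17)
  m2 <- pairwiseFstMatrix(sim$genotypes, sim$assignment)
  expect_gt(m2["pop1", "pop2"], 0.08)
  expect_lt(m2["pop1", "pop2"], 0.12)
})

test_that("PCA separates duplicated-genotype groups and is site-order invariant", {
  set.seed(44)
  # two distinct genotype patterns, duplicated -> PC1 separates exactly
  base <- rbind(matrix(rbinom(40, 2, 0.2), 1)[rep(1, 8), ],
                matrix(rbinom(40, 2, 0.8), 1)[rep(1, 8), ])
  base <- base + 0L
  rownames(base) <- paste0("s", 1:16)
  keep <- apply(base, 2, function(x) length(unique(x)) > 1)
  base <- base[, keep, drop = FALSE]
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(
    seq_len(ncol(base)) * 10L, width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(
    as.list(rep("T", ncol(base))))
  g <- GenotypeMatrix(s, base)
  pc <- genotypePca(g, k = 3)
  grpA <- pc$coords[1:8, 1]
  grpB <- pc$coords[9:16, 1]
  expect_lt(max(abs(grpA - grpA[1])), 1e-8)   # zero within-group spread
  expect_lt(max(abs(grpB - grpB[1])), 1e-8)
  expect_gt(abs(grpA[1] - grpB[1]), 0.1)
  # site-order invariance
  perm <- sample(ncol(base))
  gp <- GenotypeMatrix(s, base[, perm])
  # positions must stay sorted: rebuild with permuted dosage columns only
  pcP <- genotypePca(GenotypeMatrix(s, base[, perm]), k = 3)
  expect_equal(abs(pcP$coords[, 1]), abs(pc$coords[, 1]), tolerance = 1e-8)
  expect_error(genotypePca(g, k = 20), "exceed")
})

test_that("PCA coordinates diagonalize to the eigenvalues", {
  set.seed(55)
  g <- randomGenotypeMatrix(25, 120)
  keep <- !is.na(alleleFrequency(g)$freq) &
    alleleFrequency(g)$freq > 0 & alleleFrequency(g)$freq < 1
  g <- g[, keep]
  pc <- genotypePca(g, k = 6)
  cp <- crossprod(pc$coords)
  expect_equal(unname(cp), diag(pc$eigenvalues[1:6], 6), tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # rotation is orthonormal
  expect_equal(unname(crossprod(pc$rotation)), diag(6), tolerance = 1e-8)
})

test_that("PC1 separates Balding-Nichols populations with zero overlap", {
  ok <- 0L
  for (i in 1:10) {
    sim <- simulateBaldingNichols(nDiploids = c(30, 30), nSites = 800,
                                  F = 0.1, seed = 1000 + i)
    gf <- filterSites(sim$genotypes,
                      filterParams(mafMin = 0.01))
    pc <- genotypePca(gf, k = 2)
    a <- pc$coords[sim$assignment[rownames(pc$coords)] == "pop1", 1]
    b <- pc$coords[sim$assignment[rownames(pc$coords)] == "pop2", 1]
    if (max(a) < min(b) || max(b) < min(a)) ok <- ok + 1L
  }
  expect_equal(ok, 10L)
})

test_that("LD decay bins conserve pairs and detect faster decay", {
  # single chromosome, 2 usable sites -> one pair in one bin
  h <- makeFixture("ld6")
  ld <- ldDecay(h, binWidth = 1000L)
  expect_equal(sum(ld$curves$n_pairs), 1L)
  expect_true(all(ld$curves$mean_r2 >= 0 & ld$curves$mean_r2 <= 1))
  # population of monomorphic sites -> empty curve
  sM <- sites(h)
  hM <- HaplotypeMatrix(sM, matrix(0L, 6, 2), sampleIds(h))
  ldM <- ldDecay(hM)
  expect_true(is.null(ldM$curves) || nrow(ldM$curves) == 0L)
  expect_error(ldDecay(h[c("s1"), ]), "fewer than 4")
  # pair conservation on a random fixture
  set.seed(66)
  hr <- randomHaplotypeMatrix(6, 40, posMax = 20000L)
  ldr <- ldDecay(hr, maxDist = 20000L, binWidth = 500L)
  p <- colMeans(haplotypes(hr))
  polyPos <- GenomicRanges::start(sites(hr))[p > 0 & p < 1]
  nElig <- sum(outer(polyPos, polyPos, function(a, b) b - a) >= 1 &
                 outer(polyPos, polyPos, function(a, b) b - a) <= 20000)
  expect_equal(sum(ldr$curves$n_pairs), nElig)
  # tenfold higher recombination gives a strictly shorter half-decay
  # distance (an undefined half-decay means the curve never halves within
  # range, i.e. slower decay than any defined distance)
  faster <- 0L
  for (i in 1:5) {
    lo <- simulateForwardTwoPop(nDiploids = 25, seqLength = 2e5,
                                mutPerHap = 0.7, recPerBp = 1e-7,
                                splitGen = 150, seed = 300 + i)
    hi <- simulateForwardTwoPop(nDiploids = 25, seqLength = 2e5,
                                mutPerHap = 0.7, recPerBp = 1e-6,
                                splitGen = 150, seed = 300 + i)
    popIds <- names(lo$assignment)[lo$assignment == "pop1"]
    ldLo <- ldDecay(lo$haplotypes[popIds, ], maxDist = 2e5,
                    binWidth = 10000L)
    ldHi <- ldDecay(hi$haplotypes[names(hi$assignment)[
      hi$assignment == "pop1"], ], maxDist = 2e5, binWidth = 10000L)
    hiHalf <- ldHi$halfDecay["all"]
    loHalf <- ldLo$halfDecay["all"]
    if (!is.na(hiHalf) && (is.na(loHalf) || hiHalf < loHalf))
      faster <- faster + 1L
  }
  expect_gte(faster, 4L)
})

test_that("the FST matrix is permutation-equivariant in population labels", {
  sim <- simulateBaldingNichols(nDiploids = c(10, 10), nSites = 300,
                                F = 0.2, seed = 81,
                                popNames = c("P", "Q"))
  g <- sim$genotypes
  m1 <- pairwiseFstMatrix(g, sim$assignment)
  swapped <- setNames(ifelse(sim$assignment == "P", "Q", "P"),
                      names(sim$assignment))
  m2 <- pairwiseFstMatrix(g, swapped)
  expect_equal(m1["P", "Q"], m2["Q", "P"], tolerance = 1e-12)
})
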
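mkSites <- function(pos, chrom = "1") {
  s <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(
    as.list(rep("T", length(pos))))
  s
}

test_that("window boundaries follow the 50-kb grid anchored at W + 1", {
  s <- mkSites(c(50000L, 50001L, 90623456L), chrom = "7")
  aw <- assignWindows(s, chromLengths = c("7" = 91000000))
  w <- aw$windows
  idx <- aw$siteWindow
  expect_equal(S4Vectors::mcols(w)$windowIndex[idx[1]], 0L)
  expect_equal(S4Vectors::mcols(w)$windowIndex[idx[2]], 1L)
  # the window that contains position 90,623,456 is 90,600,001-90,650,000
  expect_equal(GenomicRanges::start(w)[idx[3]], 90600001L)
  expect_equal(GenomicRanges::end(w)[idx[3]], 90650000L)
})

test_that("every site is assigned to exactly one window and counts add up", {
  set.seed(88)
  pos <- sort(sample.int(1e6, 400))
  aw <- assignWindows(mkSites(pos))
  expect_false(anyNA(aw$siteWindow))
  expect_equal(sum(S4Vectors::mcols(aw$windows)$nSnps), 400L)
  expect_error(assignWindows(mkSites(1000L), chromLengths = c("1" = 500)),
               "beyond")
})

test_that("empirical threshold uses higher interpolation with inclusive ties", {
  expect_equal(empiricalThreshold(1:100, 0.05), 96)
  expect_equal(sum(1:100 >= empiricalThreshold(1:100, 0.05)), 5L)
  expect_warning(ct <- empiricalThreshold(rep(3, 50), 0.05), "degenerate")
  expect_equal(ct, 3)       # all equal -> everything is an outlier
  expect_warning(empiricalThreshold(1:5, 0.05), "defined values")
  set.seed(9)
  v <- rnorm(10000)
  cut <- empiricalThreshold(v, 0.05)
  nOut <- sum(v >= cut)
  expect_true(nOut >= 0.05 * 10000 && nOut <= 0.05 * 10000 + sum(v == cut))
})

test_that("Fisher window enrichment equals the exact hypergeometric tail", {
  expect_equal(fisherWindowEnrichment(0, 10, 100, 1000), 1)
  # drawing all significant SNPs into one window is itself significant
  pAll <- fisherWindowEnrichment(6, 6, 6, 100)
  expect_equal(pAll, 1 / choose(100, 6), tolerance = 1e-12)
  expect_lt(pAll, 0.05)
  expect_equal(fisherWindowEnrichment(8, 10, 100, 1000),
               oracleHyperTail(8, 10, 100, 1000), tolerance = 1e-12)
  set.seed(77)
  for (i in 1:50) {
    M <- sample(50:2000, 1); K <- sample(1:(M - 1), 1)
    m <- sample(1:min(60, M), 1); k <- sample(0:min(m, K), 1)
    got <- fisherWindowEnrichment(k, m, K, M)
    expect_equal(got, oracleHyperTail(k, m, K, M), tolerance = 1e-9)
    # and against the field-standard implementations
    expect_equal(got, stats::phyper(k - 1, K, M - K, m, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
  tab <- matrix(c(8, 2, 92, 898), 2)
  expect_equal(fisherWindowEnrichment(8, 10, 100, 1000),
               stats::fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-9)
  expect_error(fisherWindowEnrichment(5, 3, 10, 100), "inconsistent")
})

test_that("window statistics equal a brute-force recomputation on a toy", {
  set.seed(30)
  nS <- 12
  pos <- sort(sample.int(150000L, 90))
  h <- matrix(rbinom(4 * nS * 90, 1L, rep(runif(90, .1, .9), each = 4 * nS)),
              ncol = 90)
  sel <- h[1:(2 * nS), ]; ref <- h[(2 * nS + 1):(4 * nS), ]
  sGR <- mkSites(pos)
  hSel <- HaplotypeMatrix(sGR, sel, paste0("a", 1:nS))
  hRef <- HaplotypeMatrix(sGR, ref, paste0("b", 1:nS))
  g <- asGenotypes(HaplotypeMatrix(sGR, rbind(sel, ref),
                                   c(paste0("a", 1:nS), paste0("b", 1:nS))))
  assign <- setNames(rep(c("A", "B"), each = nS),
                     c(paste0("a", 1:nS), paste0("b", 1:nS)))
  st <- siteStatistics(g, assign, "A", "B")
  xp <- data.frame(chrom = "1", pos = pos, z = rnorm(90))
  aw <- assignWindows(sGR, chromLengths = c("1" = 150000))
  tbl <- computeWindowStats(st, xp, hSel, hRef, aw,
                            scanThresholds(minSnps = 1))
  for (w in seq_len(nrow(tbl))) {
    inWin <- pos >= tbl$start1[w] & pos <= tbl$end1[w]
    expect_equal(tbl$n_snps[w], sum(inWin))
    expect_equal(tbl$weighted_fst[w],
                 sum(st$wc_a[inWin]) /
                   sum(st$wc_a[inWin] + st$wc_b[inWin] + st$wc_c[inWin]))
    expect_equal(tbl$max_abs_xpehh[w], max(abs(xp$z[inWin])))
    expect_equal(tbl$pi_sel[w], oraclePiPairwise(sel[, inWin, drop = FALSE]),
                 tolerance = 1e-9)
    expect_equal(tbl$tajd_ref[w], oracleTajimaD(ref[, inWin, drop = FALSE]),
                 tolerance = 1e-9)
  }
  # single-site window reduces to the per-site component ratio
  one <- which(tbl$n_snps == 1)
  if (length(one)) {
    j <- which(pos >= tbl$start1[one[1]] & pos <= tbl$end1[one[1]])
    expect_equal(tbl$weighted_fst[one[1]],
                 st$wc_a[j] / (st$wc_a[j] + st$wc_b[j] + st$wc_c[j]))
  }
  # masking: fewer than minSnps leaves all statistics missing
  tblM <- computeWindowStats(st, xp, hSel, hRef, aw,
                             scanThresholds(minSnps = 40))
  masked <- tblM$n_snps < 40
  expect_true(any(masked))
  expect_true(all(is.na(tblM$weighted_fst[masked])))
  expect_true(all(is.na(tblM$tajd_sel[masked])))
})

test_that("sweep calling flags the conjunction and respects the limits", {
  n <- 100
  tbl <- data.frame(chrom = "1", start1 = (0:(n - 1)) * 50000 + 1,
                    end1 = (1:n) * 50000, n_snps = 20L,
                    weighted_fst = seq(0.01, 0.99, length.out = n),
                    max_abs_xpehh = seq(0.99, 0.01, length.out = n),
                    fisher_p = rep(0.001, n), stringsAsFactors = FALSE)
  # opposing gradients: no window is in both top-5% tails
  res <- callSweeps(tbl)
  expect_equal(length(res$sweeps), 0L)
  # align the two statistics: exactly the top tail is flagged
  tbl2 <- tbl
  tbl2$max_abs_xpehh <- tbl2$weighted_fst
  res2 <- callSweeps(tbl2)
  expect_equal(sum(res2$table$sweep_window), 5L)
  # a window outlying in FST only is not a sweep window
  expect_false(any(res2$table$sweep_window & !res2$table$outlier_xpehh))
  # loosening every threshold toward 1 flags (all but the minimum of) the
  # unmasked windows: the cutoff is always an observed value, so the single
  # smallest value can stay below it
  loose <- scanThresholds(fstTail = 0.999, xpehhTail = 0.999,
                          fisherAlpha = 1 - 1e-12)
  res3 <- callSweeps(tbl2, loose)
  expect_gte(sum(res3$table$sweep_window), n - 1L)
  # monotonicity: tightening tails never adds windows
  tight <- callSweeps(tbl2, scanThresholds(fstTail = 0.01,
                                           xpehhTail = 0.01))
  expect_true(all(which(tight$table$sweep_window) %in%
                    which(res2$table$sweep_window)))
})

test_that("sweep merging follows the within-50kb rule transitively", {
  r <- GenomicRanges::GRanges("1", IRanges::IRanges(
    c(100001, 180001), c(150000, 230000)))  # gap 30k -> merge
  m <- mergeSweeps(r)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m), 100001L)
  expect_equal(GenomicRanges::end(m), 230000L)
  # gap of exactly 50,000 bp still merges
  r2 <- GenomicRanges::GRanges("1", IRanges::IRanges(
    c(100001, 200001), c(150000, 250000)))
  expect_equal(length(mergeSweeps(r2)), 1L)
  # one bp more does not
  r3 <- GenomicRanges::GRanges("1", IRanges::IRanges(
    c(100001, 200002), c(150000, 250000)))
  expect_equal(length(mergeSweeps(r3)), 2L)
  # idempotent and order-independent
  set.seed(12)
  starts <- sample.int(100, 12) * 50000 + 1
  r4 <- GenomicRanges::GRanges("1", IRanges::IRanges(starts, starts + 49999))
  m1 <- mergeSweeps(r4)
  m2 <- mergeSweeps(r4[sample(12)])
  expect_equal(GenomicRanges::start(m1), GenomicRanges::start(m2))
  m3 <- mergeSweeps(m1)
  expect_equal(GenomicRanges::start(m3), GenomicRanges::start(m1))
  # merged regions are pairwise separated by more than the gap
  if (length(m1) > 1) {
    gaps <- GenomicRanges::start(m1)[-1] -
      GenomicRanges::end(m1)[-length(m1)] - 1L
    expect_true(all(gaps > 50000))
  }
})

test_that("gene annotation uses >= 1 bp overlap with half-open abutment", {
  sw <- GenomicRanges::GRanges("1", IRanges::IRanges(100001, 230000))
  genes <- GenomicRanges::GRanges("1", IRanges::IRanges(
    c(120001, 50001, 230001), c(130000, 100000, 240000)))
  S4Vectors::mcols(genes)$gene <- c("IN", "ABUT_LEFT", "AFTER")
  ann <- annotateSweeps(sw, genes)
  expect_equal(as.character(S4Vectors::mcols(ann)$genes[[1]]), "IN")
  # randomized fixtures against a quadratic overlap oracle
  set.seed(21)
  for (rep in 1:5) {
    sws <- GenomicRanges::GRanges("1", IRanges::IRanges(
      sort(sample.int(1e6, 5)), width = sample.int(50000, 5)))
    gs <- GenomicRanges::GRanges("1", IRanges::IRanges(
      sort(sample.int(1e6, 40)), width = sample.int(20000, 40)))
    S4Vectors::mcols(gs)$gene <- paste0("g", 1:40)
    ann2 <- annotateSweeps(sws, gs)
    for (i in seq_along(sws)) {
      manual <- sort(paste0("g", which(
        GenomicRanges::start(gs) <= GenomicRanges::end(sws)[i] &
          GenomicRanges::end(gs) >= GenomicRanges::start(sws)[i]),
        recycle0 = TRUE))
      expect_equal(as.character(S4Vectors::mcols(ann2)$genes[[i]]), manual)
    }
  }
})

test_that("fine-mapping is consistent with the genome scan and tiles regions", {
  set.seed(60)
  h <- randomHaplotypeMatrix(8, 60, posMax = 50000L)
  hSel <- h[paste0("s", 1:4), ]
  hRef <- h[paste0("s", 5:8), ]
  xp <- data.frame(chrom = "1", pos = GenomicRanges::start(sites(h)),
                   z = rnorm(60))
  # sub-window equal to the region reproduces a single aggregate row
  fm <- fineMapRegion(hSel, hRef, "1:1-50000", xpehh = xp,
                      subWindow = 50000L)
  expect_equal(nrow(fm), 1L)
  expect_equal(fm$max_abs_xpehh, max(abs(xp$z)))
  expect_equal(fm$pi_sel, oraclePiPairwise(haplotypes(hSel)),
               tolerance = 1e-9)
  # overlapping 1-kb steps cover the region
  fm2 <- fineMapRegion(hSel, hRef, "1:1-50000", xpehh = xp,
                       subWindow = 10000L, step = 1000L)
  expect_true(all(diff(fm2$start1) == 1000L))
  covered <- IRanges::reduce(IRanges::IRanges(fm2$start1, fm2$end1))
  expect_equal(IRanges::start(covered), 1L)
  expect_equal(IRanges::end(covered), 50000L)
})

test_that("shared gene intersections are exact and ordered", {
  res <- sharedGenes(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
                          c = "C"))
  expect_equal(res$shared, "C")
  expect_equal(res$pairwise$nShared[res$pairwise$scanA == "a" &
                                      res$pairwise$scanB == "b"], 2L)
  expect_equal(sharedGenes(list(x = "A", y = "B"))$shared, character(0))
  set.seed(15)
  sets <- lapply(1:3, function(i) sample(paste0("G", 1:300), 100))
  names(sets) <- c("s1", "s2", "s3")
  res2 <- sharedGenes(sets)
  manual <- character(0)
  for (g in unique(unlist(sets)))
    if (all(vapply(sets, function(s) g %in% s, logical(1))))
      manual <- c(manual, g)
  expect_equal(res2$shared, sort(manual))
})
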
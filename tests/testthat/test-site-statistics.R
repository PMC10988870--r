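test_that("Hudson per-site FST reproduces its closed form", {
  # fixed difference at large n approaches 1
  h <- hudsonFstSite(1000, 1000, 1000, 0)
  expect_equal(h$fst, 1, tolerance = 2e-3)
  # equal frequencies give a non-positive numerator (never clamped)
  h2 <- hudsonFstSite(200, 60, 200, 60)
  expect_true(h2$num <= 0)
  # worked example
  h3 <- hudsonFstSite(20, 15, 20, 5)
  expect_equal(h3$num, 0.25 - 2 * (0.1875 / 19), tolerance = 1e-12)
  expect_equal(h3$den, 0.625)
  expect_equal(h3$fst, h3$num / 0.625)
})

test_that("Hudson components match the independent oracle on random draws", {
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(4:80, 1); n2 <- sample(4:80, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    got <- hudsonFstSite(n1, x1, n2, x2)
    exp <- oracleHudson(n1, x1, n2, x2)
    expect_equal(got$num, exp$num, tolerance = 1e-9)
    expect_equal(got$den, exp$den, tolerance = 1e-9)
  }
})

test_that("ratio-of-averages aggregation behaves at the limits", {
  # identical frequencies everywhere -> estimate <= 0
  set.seed(5)
  x <- rbinom(50, 40, 0.4)
  h <- hudsonFstSite(rep(40, 50), x, rep(40, 50), x)
  expect_true(hudsonFstRatio(h$num, h$den) <= 0)
  # fixed differences everywhere -> estimate exactly 1
  h2 <- hudsonFstSite(rep(40, 20), rep(40, 20), rep(40, 20), rep(0, 20))
  expect_equal(hudsonFstRatio(h2$num, h2$den), 1)
})

test_that("Weir-Cockerham components match an independent transcription", {
  sym <- wcComponentsSite(10, 0.4, 0.2, 10, 0.4, 0.2)
  expect_true(sym$a <= 0)  # no among-population variance
  mono <- wcComponentsSite(12, 0, 0, 8, 0, 0)
  expect_equal(unlist(mono), c(a = 0, b = 0, c = 0))
  ex <- wcComponentsSite(10, 0.8, 0.2, 10, 0.2, 0.2)
  or <- oracleWC(10, 0.8, 0.2, 10, 0.2, 0.2)
  expect_equal(ex$a, or$a, tolerance = 1e-12)
  expect_equal(ex$b, or$b, tolerance = 1e-12)
  expect_equal(ex$c, or$c, tolerance = 1e-12)
  set.seed(202)
  for (i in 1:100) {
    n1 <- sample(2:60, 1); n2 <- sample(2:60, 1)
    p1 <- runif(1); p2 <- runif(1)
    h1 <- runif(1, 0, 2 * min(p1, 1 - p1))
    h2 <- runif(1, 0, 2 * min(p2, 1 - p2))
    got <- wcComponentsSite(n1, p1, h1, n2, p2, h2)
    exp <- oracleWC(n1, p1, h1, n2, p2, h2)
    expect_equal(unlist(got), unlist(exp), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("pi equals the all-pairs Hamming enumeration", {
  # monomorphic window
  mono <- matrix(0L, 4, 3)
  expect_equal(sum(piSite(mono)), 0)
  # one site, p = 0.5, n = 4
  m <- matrix(c(0L, 0L, 1L, 1L), ncol = 1)
  expect_equal(piSite(m), 2 * 0.25 * 4 / 3)
  expect_equal(piSite(m), oraclePiPairwise(m))
  set.seed(303)
  for (i in 1:20) {
    h <- randomHaplotypeMatrix(sample(3:10, 1), sample(5:30, 1))
    expect_equal(piWindow(h)$pi, oraclePiPairwise(haplotypes(h)),
                 tolerance = 1e-12)
  }
})

test_that("Tajima's D matches the frozen example and the oracle", {
  td <- tajimasD(makeFixture("tajd4"))
  expect_equal(td$pi, 5 / 3, tolerance = 1e-9)
  expect_equal(td$thetaW, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-9)
  expect_equal(td$D, 0.1676558, tolerance = 1e-6)
  # S = 0 leaves D undefined
  expect_true(is.na(tajimasD(matrix(0L, 4, 5))$D))
  set.seed(404)
  for (i in 1:100) {
    h <- randomHaplotypeMatrix(sample(4:12, 1), sample(3:40, 1))
    a <- haplotypes(h)
    expD <- oracleTajimaD(a)
    gotD <- tajimasD(h)$D
    if (is.na(expD)) expect_true(is.na(gotD))
    else expect_equal(gotD, expD, tolerance = 1e-9)
  }
})

test_that("r2 matches direct haplotype tallies and is bounded and symmetric", {
  perfect <- matrix(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L), ncol = 2)
  expect_equal(ldR2Pair(perfect, 1, 2), 1)
  indep <- matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L), ncol = 2)
  expect_equal(ldR2Pair(indep, 1, 2), 0)
  expect_equal(ldR2Pair(makeFixture("ld6"), 1, 2), 1 / 9, tolerance = 1e-12)
  set.seed(505)
  for (i in 1:100) {
    x <- rbinom(20, 1, 0.5); y <- rbinom(20, 1, 0.5)
    m <- cbind(x, y)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) {
      expect_true(is.na(ldR2Pair(m, 1, 2)))
    } else {
      r2 <- ldR2Pair(m, 1, 2)
      expect_equal(r2, oracleR2(x, y), tolerance = 1e-9)
      expect_true(r2 >= 0 && r2 <= 1)
      expect_equal(r2, ldR2Pair(m, 2, 1))
    }
  }
})

test_that("Hudson and Weir-Cockerham agree on balanced Balding-Nichols data", {
  sim <- simulateBaldingNichols(nDiploids = c(100, 100), nSites = 4000,
                                F = 0.1, seed = 99)
  st <- siteStatistics(sim$genotypes, sim$assignment, "pop1", "pop2")
  hudson <- hudsonFstRatio(st$hudson_num, st$hudson_den)
  wc <- sum(st$wc_a, na.rm = TRUE) /
    sum(st$wc_a + st$wc_b + st$wc_c, na.rm = TRUE)
  expect_lt(abs(hudson - wc), 0.03)
})

test_that("undefined per-site statistics are NA, never zero-filled", {
  d <- cbind(c(NA, NA, 1L, 1L), c(0L, 1L, 0L, 1L))
  rownames(d) <- paste0("s", 1:4)
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(c(5L, 10L), width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(list("T", "T"))
  g <- GenotypeMatrix(s, d)
  assign <- setNames(c("A", "A", "B", "B"), paste0("s", 1:4))
  st <- siteStatistics(g, assign, "A", "B")
  expect_true(is.na(st$fst_site[1]))   # population A fully missing at site 1
  expect_false(is.na(st$fst_site[2]))
})
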
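test_that("EHH curves match enumeration on the 4-haplotype fixture", {
  h <- makeFixture("ehh4")
  dn <- ehh(h, 3, "downstream")
  expect_equal(dn$values[1], 1)                      # zero-length extension
  expect_equal(dn$values[2], 1 / 3)                  # 2/2 split: (1+1)/6
  expect_equal(dn$values[3], 0)
  expect_equal(dn$status, "cutoff")
  up <- ehh(h, 3, "upstream")
  expect_equal(up$values, c(1, 1, 1 / 3))            # monomorphic plateau
  expect_equal(up$status, "edge")
  # enumeration oracle at each recorded offset
  a <- haplotypes(h)
  expect_equal(dn$values[2], oracleEhh(a, 3, 4))
  expect_equal(up$values[3], oracleEhh(a, 3, 1))
})

test_that("EHH is monotone non-increasing and bounded on random fixtures", {
  set.seed(808)
  for (i in 1:10) {
    h <- randomHaplotypeMatrix(6, 25)
    core <- sample(5:20, 1)
    for (dir in c("downstream", "upstream")) {
      e <- ehh(h, core, dir)
      expect_true(all(diff(e$values) <= 1e-12))
      expect_true(all(e$values >= 0 & e$values <= 1))
      # every recorded refining value equals the string enumeration
      a <- haplotypes(h)
      pos <- GenomicRanges::start(sites(h))
      for (k in seq_along(e$offsets)[-1]) {
        j <- which(abs(pos - (pos[core] + ifelse(dir == "downstream", 1, -1) *
                                e$offsets[k])) == 0)
        if (length(j) == 1)
          expect_equal(e$values[k], oracleEhh(a, core, j), tolerance = 1e-12)
      }
    }
  }
})

test_that("all-identical haplotypes hold EHH at 1 to the chromosome edge", {
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(1:10 * 100L, width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(as.list(rep("T", 10)))
  a <- matrix(rep(c(0L, 1L), each = 2, times = 10), nrow = 4)
  a[, 5] <- c(0L, 1L, 0L, 1L)  # make the core polymorphic, elsewhere equal
  a[] <- 0L
  h <- HaplotypeMatrix(s, a, c("x", "y"))
  e <- ehh(h, 5, "downstream")
  expect_true(all(e$values == 1))
  expect_equal(e$status, "edge")
})

test_that("iHH integrates the trapezoid above the cutoff only", {
  h <- makeFixture("ehh4")
  # upstream: (0->1000: 1) + (1000->2000: (1+1/3)/2); downstream:
  # (0->1000: (1+1/3)/2), the 0 endpoint excluded
  expect_equal(ihh(h, 3)$ihh, 1000 + 1000 * (1 + 1 / 3) / 2 +
                 1000 * (1 + 1 / 3) / 2)
  expect_true(ihh(h, 3)$edgeTruncated)
  # rectangle integral: EHH = 1 over both sides of length L
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(c(1000L, 2000L, 3000L),
                                                    width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(as.list(rep("T", 3)))
  hc <- HaplotypeMatrix(s, matrix(0L, 4, 3), c("x", "y"))
  expect_equal(ihh(hc, 2)$ihh, 2000)               # 2L with L = 1000 each side
  # doubling all gaps doubles the integral
  s2 <- GenomicRanges::GRanges("1", IRanges::IRanges(
    GenomicRanges::start(sites(makeFixture("ehh4"))) * 2L, width = 1L))
  S4Vectors::mcols(s2) <- S4Vectors::mcols(sites(makeFixture("ehh4")))
  h2 <- HaplotypeMatrix(s2, haplotypes(h), sampleIds(h))
  expect_equal(ihh(h2, 3)$ihh, 2 * ihh(h, 3)$ihh)
})

test_that("a max-extend cap keeps plateau scores defined", {
  h <- makeFixture("ehh4")
  capped <- ihh(h, 3, maxExtend = 1500)
  expect_false(capped$edgeTruncated)
  # upstream now stops at the last site within 1500 bp (site 2, offset 1000)
  expect_equal(capped$ihh, 1000 + 1000 * (1 + 1 / 3) / 2)
})

test_that("oversized gaps invalidate the score", {
  s <- GenomicRanges::GRanges("1", IRanges::IRanges(
    c(1000L, 2000L, 300000L), width = 1L))
  S4Vectors::mcols(s)$id <- NA_character_
  S4Vectors::mcols(s)$ref <- "A"
  S4Vectors::mcols(s)$alt <- IRanges::CharacterList(as.list(rep("T", 3)))
  a <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L), c(0L, 1L, 1L, 0L))
  h <- HaplotypeMatrix(s, a, c("x", "y"))
  expect_true(ihh(h, 2, cutoff = 0.0001, maxGap = 200000)$gapUndefined)
  expect_false(ihh(h, 2, cutoff = 0.0001, maxGap = 500000)$gapUndefined)
})

test_that("XP-EHH is zero for identical populations and antisymmetric", {
  set.seed(909)
  h <- randomHaplotypeMatrix(8, 40)
  hSel <- h[paste0("s", 1:4), ]
  hRef0 <- h[paste0("s", 5:8), ]
  # identical haplotype sets whose EHH decays before the edge -> raw = 0
  hRefSame <- HaplotypeMatrix(sites(h), haplotypes(hSel), paste0("r", 1:4))
  core <- 20
  same <- xpehhSite(hSel, hRefSame, core)
  if (!is.na(same$raw)) expect_equal(same$raw, 0)
  # antisymmetry at every scored site
  xpAB <- xpehhScan(hSel, hRef0)
  xpBA <- xpehhScan(hRef0, hSel)
  expect_equal(xpAB$raw, -xpBA$raw, tolerance = 1e-12)
  # constructed long-haplotype population scores positive
  aFix <- haplotypes(hSel)
  aFix[] <- rep(c(0L, 1L), 2)   # two identical long haplotype patterns
  hLong <- HaplotypeMatrix(sites(h), aFix, paste0("l", 1:4))
  xpL <- xpehhScan(hLong, hRef0, maxExtend = 5000)
  pos <- which(!is.na(xpL$raw))
  expect_true(length(pos) == 0 || all(xpL$raw[pos] > 0))
})

test_that("genome-wide standardization matches the population-sd example", {
  z <- standardizeXpehh(c(-1, 0, 1))
  expect_equal(z, c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  set.seed(4)
  raw <- rnorm(200, 3, 2)
  z2 <- standardizeXpehh(raw)
  expect_equal(mean(z2), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z2^2)), 1, tolerance = 1e-12)
  expect_equal(standardizeXpehh(raw + 5), z2, tolerance = 1e-12)
  expect_error(standardizeXpehh(rep(2, 10)), "zero variance")
  expect_error(standardizeXpehh(c(1, NA)), "at least 2")
})
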
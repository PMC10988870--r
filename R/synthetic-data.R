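#' @include AllClasses.R
NULL

#' Simulate two diverged populations under the Balding-Nichols model
#'
#' Fast LD-free generator used to calibrate FST estimators. Per site, an
#' ancestral frequency is drawn from Uniform(0.05, 0.95) and
#' population-specific frequencies from
#' `Beta(p (1 - F) / F, (1 - p) (1 - F) / F)` independently per population,
#' so the divergence parameter `F` equals the expected FST. Genotypes are
#' `Binomial(2, p_i)`; sites are independent (no LD). Identical seeds give
#' identical output.
#'
#' @param nDiploids per-population diploid counts (length 2, default
#'   `c(50, 50)`).
#' @param nSites number of sites (default 2000).
#' @param F divergence parameter in (0, 1).
#' @param seed mandatory integer seed.
#' @param popNames population labels.
#' @param posStep inter-site spacing in bp on the single synthetic
#'   chromosome (default 1000).
#' @return List with `genotypes` ([GenotypeMatrix-class]), `assignment`
#'   (named vector) and `truth` (realized parameters: `F`, `pAnc`,
#'   `pPop`, `mode`, `seed`).
#' @export
simulateBaldingNichols <- function(nDiploids = c(50L, 50L), nSites = 2000L,
                                   F = 0.1, seed, popNames = c("pop1", "pop2"),
                                   posStep = 1000L) {
  if (missing(seed)) stop("seed is mandatory")
  if (F <= 0 || F >= 1) stop("F must lie in (0, 1)")
  set.seed(seed)
  pAnc <- runif(nSites, 0.05, 0.95)
  shape1 <- pAnc * (1 - F) / F
  shape2 <- (1 - pAnc) * (1 - F) / F
  pPop <- cbind(rbeta(nSites, shape1, shape2),
                rbeta(nSites, shape1, shape2))
  colnames(pPop) <- popNames
  dos <- lapply(1:2, function(k)
    matrix(rbinom(nDiploids[k] * nSites, 2L, rep(pPop[, k], each = nDiploids[k])),
           nrow = nDiploids[k], byrow = FALSE))
  d <- rbind(dos[[1]], dos[[2]])
  ids <- c(paste0(popNames[1], "_", seq_len(nDiploids[1])),
           paste0(popNames[2], "_", seq_len(nDiploids[2])))
  rownames(d) <- ids
  s <- GRanges("1", IRanges(seq_len(nSites) * as.integer(posStep), width = 1L))
  mcols(s)$id <- NA_character_
  mcols(s)$ref <- "A"
  mcols(s)$alt <- CharacterList(as.list(rep("T", nSites)))
  assignment <- setNames(rep(popNames, nDiploids), ids)
  list(genotypes = GenotypeMatrix(s, d),
       assignment = assignment,
       truth = list(mode = "balding_nichols", F = F, seed = seed,
                    pAnc = pAnc, pPop = pPop))
}

## stationary neutral SFS seeding: derived-allele count i has weight 1/i
seedAncestralPop <- function(nHap, seqLength, theta) {
  i <- seq_len(nHap - 1L)
  lambda <- theta * sum(1 / i)
  S <- rpois(1L, lambda)
  S <- min(S, seqLength - 1L)
  pos <- sort(sample.int(seqLength, S))
  cnt <- sample(i, S, replace = TRUE, prob = 1 / i)
  hap <- matrix(0L, nHap, S)
  idx <- unlist(lapply(seq_len(S), function(j)
    sample.int(nHap, cnt[j]) + (j - 1L) * nHap))
  hap[idx] <- 1L
  list(hap = hap, pos = pos)
}

evolvePop <- function(state, nGen, mutPerHap, recPerBp, seqLength,
                      sweepPos = -1L, s = 0, h = 0.5) {
  .wf_evolve_cpp(state$hap, state$pos, as.integer(nGen), mutPerHap,
                 recPerBp, seqLength, as.integer(sweepPos), s, h)
}

## merge two evolved populations into one polymorphic sample;
## see the package vignette for the position-collision rule
mergePops <- function(res1, res2, ancestralPos) {
  seg1 <- res1$pos; seg2 <- res2$pos
  fix1 <- res1$fixedPos; fix2 <- res2$fixedPos
  anc <- ancestralPos
  ## post-split positions present in both populations are independent
  ## mutations: bump population 2's site to the next free bp
  own1 <- union(setdiff(seg1, anc), setdiff(fix1, anc))
  own2pos <- c(setdiff(seg2, anc), setdiff(fix2, anc))
  clash <- intersect(own1, own2pos)
  if (length(clash)) {
    taken <- unique(c(seg1, seg2, fix1, fix2, anc))
    for (p in clash) {
      newp <- p + 1L
      while (newp %in% taken) newp <- newp + 1L
      seg2[seg2 == p] <- newp
      fix2[fix2 == p] <- newp
      taken <- c(taken, newp)
    }
  }
  allPos <- sort(unique(c(seg1, seg2, fix1, fix2)))
  n1 <- nrow(res1$hap); n2 <- nrow(res2$hap)
  a <- matrix(0L, n1 + n2, length(allPos))
  i1 <- match(seg1, allPos)
  a[seq_len(n1), i1] <- res1$hap
  f1 <- match(fix1, allPos)
  if (length(f1)) a[seq_len(n1), f1] <- 1L
  i2 <- match(seg2, allPos)
  a[n1 + seq_len(n2), i2] <- res2$hap
  f2 <- match(fix2, allPos)
  if (length(f2)) a[n1 + seq_len(n2), f2] <- 1L
  cnt <- colSums(a)
  poly <- cnt > 0L & cnt < (n1 + n2)
  list(hap = a[, poly, drop = FALSE], pos = allPos[poly])
}

#' Forward Wright-Fisher simulation of a two-population split
#'
#' Discrete-generation Wright-Fisher simulation with recombination,
#' infinite-sites mutation and an optional hard sweep, providing realistic
#' LD for haplotype statistics. A single ancestral population of
#' `nDiploids` individuals is seeded from the stationary neutral
#' site-frequency spectrum (weight `1/i` for derived count `i`), optionally
#' drifted for `ancestralGen` generations, then copied into two populations
#' that drift independently for `splitGen` generations. With `selection`,
#' a focal allele is introduced on one random haplotype of the target
#' population `introGen` generations after the split and evolves with
#' fitnesses 1, `1 + h s`, `1 + s`; runs are conditioned on the focal
#' allele surviving to sampling (restart on loss, restarts logged in the
#' truth record). Fixed and lost sites are pruned every generation
#' (segregating-sites representation).
#'
#' @param nDiploids diploids per population (default 200).
#' @param seqLength chromosome length in bp (default 2e6).
#' @param mutPerHap expected new mutations per haplotype per generation
#'   over the whole sequence (default 1.0).
#' @param recPerBp recombination rate per bp per generation (default 1e-8).
#' @param splitGen generations since the split (default 100, i.e. N/2,
#'   giving between-population FST near the upper end of the 0.05-0.2
#'   divergence target).
#' @param nChrom number of independent chromosomes, named `"1"`, `"2"`, ...
#'   (default 1). Chromosomes are unlinked and simulated as independent
#'   replicates; a sweep is planted on chromosome `"1"` only, so the
#'   remaining chromosomes provide the neutral genome-wide background that
#'   empirical-outlier scans require.
#' @param ancestralGen extra ancestral drift generations after SFS seeding
#'   (default 0; the seeding shortcut stands in for a long burn-in).
#' @param selection `NULL`, or `list(s =, h = 0.5, pos =, introGen = 0,
#'   targetPop = 1)`. The default locus is the midpoint of the 50-kb window
#'   containing the chromosome center (975,000 for the default 2-Mb
#'   chromosome), so the planted truth does not straddle a window boundary.
#' @param sampleSize diploids sampled per population at the end (default:
#'   all).
#' @param seed mandatory integer seed.
#' @param maxRestarts maximum sweep-survival restarts (default 200).
#' @param popNames population labels.
#' @return List with `haplotypes` ([HaplotypeMatrix-class], both
#'   populations merged), `assignment`, and `truth` (`sweepPos`,
#'   `sweepFreq` in the target population, `fixed`, `restarts`, realized
#'   parameters).
#' @export
simulateForwardTwoPop <- function(nDiploids = 200L, seqLength = 2e6,
                                  mutPerHap = 1.0, recPerBp = 1e-8,
                                  splitGen = 100L, ancestralGen = 0L,
                                  selection = NULL, sampleSize = NULL,
                                  seed, maxRestarts = 200L, nChrom = 1L,
                                  popNames = c("pop1", "pop2")) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  chromResults <- vector("list", nChrom)
  for (chromIdx in seq_len(nChrom)) {
    chromResults[[chromIdx]] <- simOneChromosome(
      nDiploids, seqLength, mutPerHap, recPerBp, splitGen, ancestralGen,
      if (chromIdx == 1L) selection else NULL, maxRestarts,
      sampleSize = sampleSize)
  }
  nOut <- if (is.null(sampleSize)) nDiploids else as.integer(sampleSize)
  ids <- c(paste0(popNames[1], "_", seq_len(nOut)),
           paste0(popNames[2], "_", seq_len(nOut)))
  gr <- GRanges(rep(as.character(seq_len(nChrom)),
                    vapply(chromResults, function(cr) length(cr$pos),
                           integer(1))),
                IRanges(unlist(lapply(chromResults, `[[`, "pos")),
                        width = 1L))
  mcols(gr)$id <- NA_character_
  mcols(gr)$ref <- "A"
  mcols(gr)$alt <- CharacterList(as.list(rep("T", length(gr))))
  hapAll <- do.call(cbind, lapply(chromResults, `[[`, "hap"))
  rownames(hapAll) <- paste0(rep(ids, each = 2L), "_", c(1L, 2L))
  h <- HaplotypeMatrix(gr, hapAll, ids)
  assignment <- setNames(rep(popNames, each = nOut), ids)
  one <- chromResults[[1L]]
  truth <- list(mode = "forward_wf", seed = seed, nDiploids = nDiploids,
                seqLength = seqLength, nChrom = nChrom,
                mutPerHap = mutPerHap, recPerBp = recPerBp,
                splitGen = splitGen, ancestralGen = ancestralGen,
                selection = one$sel,
                sweepChrom = if (is.null(one$sel)) NA_character_ else "1",
                sweepPos = if (is.null(one$sel)) NA_integer_ else one$sel$pos,
                sweepFreq = one$sweepFreq,
                fixed = isTRUE(one$sweepState == 2L),
                restarts = sum(vapply(chromResults, `[[`, numeric(1),
                                      "restarts")))
  list(haplotypes = h, assignment = assignment, truth = truth)
}

## one unlinked chromosome: seed from the stationary SFS, optional ancestral
## drift, split, independent drift (with selection in the target population)
simOneChromosome <- function(nDiploids, seqLength, mutPerHap, recPerBp,
                             splitGen, ancestralGen, selection, maxRestarts,
                             sampleSize = NULL) {
  nHap <- 2L * nDiploids
  theta <- 4 * nDiploids * mutPerHap
  state <- seedAncestralPop(nHap, as.integer(seqLength), theta)
  if (ancestralGen > 0) {
    res <- evolvePop(state, ancestralGen, mutPerHap, recPerBp, seqLength)
    ## ancestrally fixed sites are fixed in both daughters: monomorphic in
    ## any sample, so they are dropped here
    state <- list(hap = res$hap, pos = res$pos)
  }
  ancestralPos <- state$pos

  sel <- NULL
  if (!is.null(selection)) {
    ctrWin <- (round(seqLength / 2) - 1) %/% 50000
    sel <- utils::modifyList(
      list(s = 0.1, h = 0.5, pos = ctrWin * 50000 + 25000,
           introGen = 0L, targetPop = 1L), selection)
    if (sel$s < 0) stop("selection coefficient must be >= 0")
  }

  evolveNeutral <- function(st, g) {
    r <- evolvePop(st, g, mutPerHap, recPerBp, seqLength)
    r
  }

  restarts <- 0L
  sweepFreq <- NA_real_
  sweepState <- 0L
  resPops <- vector("list", 2L)
  for (k in 1:2) {
    if (is.null(sel) || sel$targetPop != k) {
      resPops[[k]] <- evolveNeutral(state, splitGen)
      next
    }
    ## target population: neutral phase, introduction, selected phase
    pre <- if (sel$introGen > 0) {
      r0 <- evolveNeutral(state, sel$introGen)
      list(hap = r0$hap, pos = r0$pos, fixedPos = r0$fixedPos)
    } else list(hap = state$hap, pos = state$pos, fixedPos = integer(0))
    pos0 <- pre$pos
    ## nudge the locus off any existing segregating site (realized position
    ## is reported in the truth record)
    while (sel$pos %in% pos0) sel$pos <- sel$pos + 1L
    insAt <- findInterval(sel$pos, pos0)
    newPos <- append(pos0, as.integer(sel$pos), after = insAt)
    carrier <- sample.int(nHap, 1L)
    repeat {
      hap0 <- cbind(pre$hap[, seq_len(insAt), drop = FALSE],
                    0L,
                    pre$hap[, -seq_len(insAt), drop = FALSE])
      if (insAt == 0L)
        hap0 <- cbind(0L, pre$hap)
      hap0[carrier, insAt + 1L] <- 1L
      r1 <- evolvePop(list(hap = hap0, pos = newPos),
                      splitGen - sel$introGen, mutPerHap, recPerBp,
                      seqLength, sweepPos = sel$pos, s = sel$s, h = sel$h)
      if (r1$sweepState != 3L) {
        sweepState <- r1$sweepState
        sweepFreq <- r1$sweepFreq
        r1$fixedPos <- c(pre$fixedPos, r1$fixedPos)
        resPops[[k]] <- r1
        break
      }
      restarts <- restarts + 1L
      if (restarts > maxRestarts)
        stop("sweep allele lost in every attempt (", maxRestarts,
             " restarts); increase s or try another seed")
      carrier <- sample.int(nHap, 1L)
    }
  }

  if (!is.null(sampleSize)) {
    ## samples are exchangeable: take the first sampleSize diploids of each
    ## population before the merge (cheaper than subsetting afterwards)
    for (k in 1:2)
      resPops[[k]]$hap <- resPops[[k]]$hap[seq_len(2L * sampleSize), ,
                                           drop = FALSE]
  }
  merged <- mergePops(resPops[[1]], resPops[[2]], ancestralPos)
  stopifnot(!is.unsorted(merged$pos), !anyDuplicated(merged$pos),
            ncol(merged$hap) == length(merged$pos))
  list(hap = merged$hap, pos = merged$pos, sel = sel,
       sweepFreq = sweepFreq, sweepState = sweepState, restarts = restarts)
}

#' Convert phased haplotypes to genotypes
#'
#' Collapses a [HaplotypeMatrix-class] into a fully phased
#' [GenotypeMatrix-class] (GT strings `"a|b"`), the natural input for the
#' dosage-based estimators, filtering and PCA.
#'
#' @param h a [HaplotypeMatrix-class].
#' @param withGT materialize phased GT strings (default TRUE). `FALSE`
#'   skips the (large) character matrix for dosage-only workflows; the
#'   result then cannot be written to VCF or re-expanded with
#'   [asHaplotypes()].
#' @return A [GenotypeMatrix-class].
#' @export
asGenotypes <- function(h, withGT = TRUE) {
  a <- haplotypes(h)
  n <- nSamples(h)
  left <- a[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  right <- a[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  d <- left + right
  rownames(d) <- sampleIds(h)
  gt <- if (withGT) matrix(paste0(left, "|", right), nrow = n,
                           dimnames = list(sampleIds(h), NULL))
        else matrix(character(0), 0L, 0L)
  GenotypeMatrix(sites(h), d, gt = gt)
}

#' Tiny deterministic fixtures
#'
#' Hand-coded datasets for unit testing and documentation, registered by
#' name:
#' \describe{
#'   \item{`ehh4`}{4 haplotypes x 5 sites (2 diploid samples); around the
#'     middle core site the first extension splits the haplotypes 2/2.}
#'   \item{`ld6`}{6 haplotypes x 2 sites with joint frequencies giving
#'     `D = 1/12`, `r^2 = 1/9`.}
#'   \item{`filter6`}{10 samples x 6 sites tripping each inclusion rule
#'     exactly once (one multi-allelic site, one site with 20% missing,
#'     one site at MAF 0.05); three sites survive.}
#'   \item{`tajd4`}{4 haplotypes x 3 sites with derived counts 1, 2, 3.}
#' }
#'
#' @param name registry name.
#' @return The fixture object (`HaplotypeMatrix` or `GenotypeMatrix`).
#' @export
makeFixture <- function(name) {
  mkSites <- function(pos, nAlt = rep(1L, length(pos))) {
    s <- GRanges("1", IRanges(pos, width = 1L))
    mcols(s)$id <- NA_character_
    mcols(s)$ref <- "A"
    mcols(s)$alt <- CharacterList(lapply(nAlt, function(k)
      c("T", "G", "C")[seq_len(k)]))
    s
  }
  switch(name,
    ehh4 = {
      a <- cbind(c(0L, 0L, 1L, 1L),   # upstream split 2/2
                 c(0L, 0L, 0L, 0L),   # monomorphic neighbour
                 c(0L, 1L, 0L, 1L),   # core
                 c(0L, 0L, 1L, 1L),   # downstream split 2/2
                 c(0L, 1L, 0L, 1L))   # further split -> EHH 0
      HaplotypeMatrix(mkSites(c(1000L, 2000L, 3000L, 4000L, 5000L)), a,
                      c("A", "B"))
    },
    ld6 = {
      a <- cbind(c(1L, 1L, 1L, 0L, 0L, 0L),
                 c(1L, 1L, 0L, 1L, 0L, 0L))
      HaplotypeMatrix(mkSites(c(100L, 200L)), a, c("s1", "s2", "s3"))
    },
    filter6 = {
      pass1 <- c(0L, 0L, 1L, 1L, 2L, 2L, 0L, 1L, 2L, 1L)
      multi <- pass1
      missing2 <- c(NA, NA, 1L, 1L, 2L, 2L, 0L, 1L, 2L, 1L)
      lowMaf <- c(1L, rep(0L, 9L))             # MAF exactly 1/20 = 0.05
      pass5 <- c(rep(0L, 9L), NA)              # exactly 10% missing, kept
      pass6 <- c(rep(0L, 9L), NA)
      pass5[1:4] <- 1L
      pass6[1:6] <- c(2L, 2L, 1L, 1L, 0L, 0L)
      d <- cbind(pass1, multi, missing2, lowMaf, pass5, pass6)
      colnames(d) <- NULL
      rownames(d) <- paste0("s", 1:10)
      GenotypeMatrix(mkSites(100L * (1:6),
                             nAlt = c(1L, 2L, 1L, 1L, 1L, 1L)), d)
    },
    tajd4 = {
      a <- cbind(c(1L, 0L, 0L, 0L),
                 c(1L, 1L, 0L, 0L),
                 c(1L, 1L, 1L, 0L))
      HaplotypeMatrix(mkSites(c(10L, 20L, 30L)), a, c("x", "y"))
    },
    stop("unknown fixture name: ", name)
  )
}
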
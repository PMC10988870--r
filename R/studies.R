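#' @include AllClasses.R
NULL

## Replicate studies used for calibration and power analysis of the scan.
## Each study fixes the generator at its default (study) conditions and
## varies only the replicate seed, derived deterministically from `seed`.

studySeed <- function(seed, rep, stream) {
  (as.integer(seed) * 977L + stream * 7919L + rep * 131L) %% 2000000000L
}

#' Balding-Nichols FST parameter-recovery study
#'
#' For each divergence value, simulates replicate two-population
#' Balding-Nichols datasets (50 + 50 diploids, 2,000 sites by default) and
#' records the genome-wide Hudson ratio-of-averages estimate; the mean
#' estimate recovers the divergence parameter.
#'
#' @param Fvalues divergence parameters (default `c(0.05, 0.1, 0.2)`).
#' @param nReplicates replicates per value (default 20).
#' @param seed study seed.
#' @param nSites,nDiploids per-replicate problem size.
#' @return `data.frame` with `F`, `rep`, `estimate`.
#' @export
fstRecoveryStudy <- function(Fvalues = c(0.05, 0.1, 0.2), nReplicates = 20L,
                             seed = 1L, nSites = 2000L,
                             nDiploids = c(50L, 50L)) {
  out <- expand.grid(F = Fvalues, rep = seq_len(nReplicates))
  out$estimate <- NA_real_
  for (r in seq_len(nrow(out))) {
    sim <- simulateBaldingNichols(
      nDiploids = nDiploids, nSites = nSites, F = out$F[r],
      seed = studySeed(seed, r, 1L))
    st <- siteStatistics(sim$genotypes, sim$assignment, "pop1", "pop2")
    out$estimate[r] <- hudsonFstRatio(st$hudson_num, st$hudson_den)
  }
  out
}

## study-scale genome: ten 2-Mb chromosomes, N = 200 diploids per
## population, 100 + 100 sampled for the scan
studyGenome <- function(seed, selection) {
  simulateForwardTwoPop(nChrom = 10L, sampleSize = 100L,
                        selection = selection, seed = seed)
}

#' Planted-sweep recovery study
#'
#' Simulates replicate two-population genomes with a hard sweep
#' (`s = 0.2`, introduced at the split, conditioned on survival) on
#' chromosome 1 and runs the full scan pipeline on each. Records, per
#' replicate: the realized sweep frequency; whether the planted locus falls
#' inside a called (merged) sweep region; the maximum |z| within 100 kb of
#' the locus; the genome-wide 99th percentile of |z|; and the flagged-window
#' fraction.
#'
#' @param nReplicates replicates (default 20).
#' @param seed study seed.
#' @param s selection coefficient (default 0.2).
#' @param maxExtend XP-EHH extension cap passed to [runSweepScan()].
#' @return `data.frame`, one row per replicate.
#' @export
sweepRecoveryStudy <- function(nReplicates = 20L, seed = 1L, s = 0.2,
                               maxExtend = 5e5) {
  out <- data.frame(rep = seq_len(nReplicates), sweepFreq = NA_real_,
                    locusInSweep = NA, nearLocusMaxZ = NA_real_,
                    z99 = NA_real_, flaggedFraction = NA_real_,
                    nSweeps = NA_integer_)
  for (r in seq_len(nReplicates)) {
    sim <- studyGenome(studySeed(seed, r, 2L), selection = list(s = s))
    res <- suppressWarnings(
      runSweepScan(sim$haplotypes, sim$assignment, "pop1", "pop2",
                   maxExtend = maxExtend))
    sw <- res$sweeps
    locus <- sim$truth$sweepPos
    out$sweepFreq[r] <- sim$truth$sweepFreq
    out$locusInSweep[r] <- length(sw) > 0 &&
      any(as.character(seqnames(sw)) == sim$truth$sweepChrom &
            start(sw) <= locus & end(sw) >= locus)
    xp <- res$xpehh
    near <- xp$chrom == sim$truth$sweepChrom &
      abs(xp$pos - locus) <= 1e5
    out$nearLocusMaxZ[r] <- suppressWarnings(
      max(abs(xp$z[near]), na.rm = TRUE))
    out$z99[r] <- quantile(abs(xp$z), 0.99, na.rm = TRUE, names = FALSE)
    tw <- res$windowTable
    out$flaggedFraction[r] <- mean(tw$sweep_window, na.rm = TRUE)
    out$nSweeps[r] <- length(sw)
  }
  out
}

#' Neutral-genome null study
#'
#' Simulates replicate neutral two-population genomes under the same
#' conditions as [sweepRecoveryStudy()] but without selection and records,
#' per replicate: (a) the flagged-window fraction of the full scan — the
#' specificity of the top-5% FST, top-5% |XP-EHH| and Fisher-enrichment
#' intersection rule; and (b) the XP-EHH bias under an exchangeable
#' relabelling, where all samples are pooled and split into two groups at
#' random. Because genome-wide standardization centers every replicate's
#' z-scores at zero exactly, the bias measure is the uncentered ratio
#' `mean(raw) / sd(raw)` — the mean raw score in units of its own spread;
#' under exchangeability it fluctuates around zero.
#'
#' @param nReplicates replicates (default 20).
#' @param seed study seed.
#' @param maxExtend XP-EHH extension cap passed to [runSweepScan()].
#' @return `data.frame` with `rep`, `flaggedFraction`, `exchMeanOverSd`.
#' @export
nullScanStudy <- function(nReplicates = 20L, seed = 1L, maxExtend = 5e5) {
  out <- data.frame(rep = seq_len(nReplicates),
                    flaggedFraction = NA_real_,
                    exchMeanOverSd = NA_real_)
  for (r in seq_len(nReplicates)) {
    sim <- studyGenome(studySeed(seed, r, 3L), selection = NULL)
    res <- suppressWarnings(
      runSweepScan(sim$haplotypes, sim$assignment, "pop1", "pop2",
                   maxExtend = maxExtend))
    tw <- res$windowTable
    out$flaggedFraction[r] <- mean(tw$sweep_window, na.rm = TRUE)
    ## exchangeable relabelling on the same neutral genome: two random
    ## disjoint groups of 50 samples each
    ids <- sample(sampleIds(sim$haplotypes), 100L)
    hA <- sim$haplotypes[ids[1:50], ]
    hB <- sim$haplotypes[ids[51:100], ]
    xp <- xpehhScan(hA, hB, maxExtend = maxExtend)
    raw <- xp$raw[!is.na(xp$raw)]
    out$exchMeanOverSd[r] <- mean(raw) / sd(raw)
  }
  out
}
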
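---
title: "Detecting selective sweeps between populations with SweepScan"
author: "SweepScan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps between populations with SweepScan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SweepScan)
```

## The problem and the model

SweepScan implements a two-population selective-sweep scan of the kind used
to map local adaptation in livestock and wild populations: one group of
samples (the *selected* population, e.g. breeds from an extreme
environment) is contrasted with a *reference* group, and the genome is
searched for regions where allele frequencies have diverged unusually far
and haplotypes in the selected group are unusually long and homogeneous —
the joint signature of a recent positive-selection sweep.

The scan combines, over consecutive non-overlapping 50-kb windows:

* **Population differentiation.** Per-site FST with the Hudson estimator in
  the Bhatia ratio form — the per-site numerator
  $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$ and
  denominator $p_1(1-p_2)+p_2(1-p_1)$ are kept separate and aggregated as a
  *ratio of averages*, which avoids the upward bias of averaging per-site
  ratios. Window-level "weighted" FST uses the Weir–Cockerham variance
  components $a$, $b$, $c$ (computed from diploid genotypes, including
  observed heterozygosity) as $\sum a / \sum(a+b+c)$, matching what
  VCFtools reports for windowed FST. Per-site values are never clamped to
  $[0,1]$; sites with undefined statistics are masked, not zero-filled,
  so empirical quantiles are not distorted.
* **Haplotype homozygosity.** EHH around each core site, computed over all
  haplotypes of one population; the curve starts at 1 for the zero-length
  extension and, at extension to site $j$,
  $\mathrm{EHH} = \sum_k \binom{m_k}{2} / \binom{N}{2}$ over the counts
  $m_k$ of distinct haplotype strings spanning the sites beyond the core
  through $j$ (the core's own allele is not part of the string, which is
  what makes the zero-length value exactly 1). iHH is the trapezoid
  integral of the curve over physical distance, truncated at the first
  point below the EHH cutoff (0.05, the selscan default), summed over both
  directions. The cross-population statistic is
  $\mathrm{XP\text{-}EHH} = \ln(\mathrm{iHH}_{sel}/\mathrm{iHH}_{ref})$,
  standardized genome-wide in a single bin (no derived-frequency binning,
  which is an iHS convention rather than an XP-EHH one). Scores are
  computed at every site with pooled minor allele frequency above 0.05.
* **Diversity.** Window nucleotide diversity
  $\pi = \sum_{sites} 2p(1-p)\,n/(n-1)$ (equal to the mean pairwise
  Hamming distance), the π-ratio oriented as
  $\pi_{ref}/\pi_{sel}$ so that values above 1 indicate diversity loss in
  the selected population, and Tajima's D per population with the standard
  constants.

Candidate sweeps are windows in the top 5% of weighted FST *and* the top
5% of the per-window maximum |XP-EHH| *and* with a one-sided Fisher
(hypergeometric) enrichment of top-5% FST SNPs at $P < 0.05$; flagged
windows are merged when separated by at most 50 kb (a gap of exactly 50 kb
merges) and annotated with overlapping genes. An alternative single-
statistic rule (top 1% of max |XP-EHH| windows) is available via
`rule = "xpehh_1pct"`. Empirical thresholds use the "higher" quantile so
the cutoff is always an observed value, and ties at the cutoff are all
outliers.

## Conventions that matter

* Intervals are held as `GRanges` (1-based, closed). BED input/output is
  converted at the boundary (0-based half-open), GFF3 is 1-based
  inclusive, and reported windows are 1-based inclusive on the 50-kb grid
  anchored at multiples of 50,000 plus one (a position $p$ belongs to
  window $\lfloor (p-1)/50000 \rfloor$). A gene ending exactly where a
  sweep begins (half-open abutment in BED coordinates) does not overlap it.
* Only the `GT` FORMAT field of a VCF is consumed; `./.` (and half-calls)
  map to missing, never to homozygous reference; ploidy is fixed at two.
  Chromosome names are matched exactly, with an explicit rename map for
  reconciling sources.
* SNP inclusion rules use strict inequalities exactly as stated: a site is
  removed when its missing rate is strictly *higher than* 10% (exactly 10%
  is kept) and kept only when its minor allele frequency is strictly
  *higher than* 5% (exactly 5% is removed); multi-allelic sites are
  removed first. The rules are per-site and independent, so their order
  affects only the attribution of removals in the filter report, never the
  surviving set. Missing rate and MAF are computed on the samples entering
  the scan (each scan pair re-filters its own subset); a per-population
  MAF variant is available via `perPopMaf`.
* The XP-EHH *substrate* keeps every fully-called biallelic polymorphic
  site; the MAF rule selects which cores are *scored*. This mirrors
  selscan, whose input haplotypes retain all sites while `--maf` gates
  scored loci — EHH decay is driven by exactly the rare variants a MAF
  filter would remove.
* Edge handling follows selscan: a curve still above the cutoff at the
  chromosome end marks the score edge-truncated, excluded by default
  (`includeEdgeTruncated` retains them); an inter-site gap above 200 kb
  invalidates the score; extension is capped at `maxExtend` from the core
  with the score kept. selscan's cap default (1 Mb) presumes chromosomes
  much longer than that; on the few-Mb chromosomes produced by the
  bundled simulator the pipeline default is 500 kb, because a cap of at
  least half the chromosome length would leave every high-homozygosity
  curve edge-truncated and hence the entire swept chromosome unscored.

## The synthetic-data generators

Two generators with different purposes:

**Balding–Nichols** (`simulateBaldingNichols()`) draws, per site, an
ancestral frequency from Uniform(0.05, 0.95) and population frequencies
from Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$, then binomial genotypes. Sites are
independent (no LD), and the divergence parameter equals the expected FST,
which makes it the calibration oracle for the FST estimators: with
$F \in \{0.05, 0.1, 0.2\}$, 2,000 sites and 50+50 diploids, the mean
Hudson ratio-of-averages over 20 replicates recovers $F$ within ±0.02.

**Forward Wright–Fisher** (`simulateForwardTwoPop()`) provides LD and
sweeps. Defaults: $N = 200$ diploids per population, 2-Mb chromosomes,
one new mutation per haplotype per generation (so $\theta = 4N\mu = 800$
per chromosome), crossover rate $10^{-8}$ per bp per generation. The
ancestral population is seeded from the stationary neutral site-frequency
spectrum (class $i$ with weight $1/i$) — a documented shortcut standing in
for a long burn-in; an optional `ancestralGen` drift phase can deepen
ancestral LD. The split default is 100 generations ($N/2$): the short end
of the plausible range, chosen because longer splits push the baseline
FST far above the 0.05–0.2 divergence the generator is meant to emulate
(pure drift gives $F_{ST} \approx 1-e^{-t/2N} \approx 0.22$ already at
$t = N/2$). A hard sweep introduces one copy of a focal allele in the
target population at the split (fitnesses $1, 1+hs, 1+s$; $h = 0.5$),
conditioned on survival to sampling by restarting on loss (restart count
kept in the truth record). Fixed and lost sites are pruned each
generation; per-population fixations are recorded so the merged
two-population sample restores them as fixed differences. Positions hit
independently in both populations after the split are disambiguated by
deterministically shifting the second population's site one bp.

With `nChrom > 1` the generator emits several *unlinked* chromosomes as
independent replicates (independent pedigrees, as in coalescent
simulators), with any sweep planted on chromosome 1 only — mirroring the
fact that genome-wide empirical-outlier scans presuppose a mostly neutral
genome. The default sweep locus is the midpoint of the 50-kb window
containing the chromosome center, so the planted truth does not sit
exactly on a window-grid boundary.

What the generator deliberately does **not** reproduce: mutation-rate and
recombination-rate heterogeneity, gene conversion, demographic complexity
(bottlenecks, admixture, migration after the split), genotyping error and
missingness patterns of real resequencing data, and the deep-time
coalescent structure a full burn-in would give. Passing the recovery tests
therefore demonstrates internal consistency of the statistics and the
pipeline's ability to localize a planted signal under clean conditions —
not calibrated power on real data.

## Study conditions and numerical choices

The bundled replicate studies (`fstRecoveryStudy()`,
`sweepRecoveryStudy()`, `nullScanStudy()`, `exchangeableNullStudy()`) fix
the problem sizes used throughout the tests: ten 2-Mb chromosomes (400
windows), 200 diploids per population with 100 sampled per group for the
scan, selection coefficient 0.2, 20 replicates per study. The sampled
group size is in the range of the per-contrast sample sizes typical of
livestock resequencing contrasts, and the neutral chromosomes supply the
empirical null that the outlier thresholds require. Because genome-wide
standardization centers z-scores exactly, the exchangeable-null bias
measure is the uncentered mean(raw)/sd(raw) per replicate.

At these desk-scale parameters a sweep's haplotype footprint spans a large
fraction of its 2-Mb chromosome (the localization scale
$\sim 1/(rT)$ is of megabase order), so recovery is assessed at the level
the data can support: the planted locus falling inside a called, merged
sweep region, with specificity checked on neutral genomes (flagged-window
fraction at most the nominal 5%).

Other numerical choices: Tajima's D is undefined (masked) at $S = 0$;
windows with fewer than 10 SNPs are masked for all statistics and excluded
from quantiles (single-SNP windows would otherwise dominate the tails);
the last window of a chromosome may be short and is retained subject to
the same masking; Fisher p-values are compared to a raw 0.05 as published
(`stats::p.adjust` can be applied to the emitted column for a
Benjamini–Hochberg variant); negative pairwise-FST entries of the distance
matrix are clamped to zero (with a logged count) before neighbor joining;
negative NJ branch lengths are clamped to zero with the deficit moved to
the sibling edge, and Q-criterion ties are broken by the
lexicographically smallest pair of subtree labels, so trees are fully
reproducible; eigenvector signs in PCA are fixed by making each
component's largest-magnitude entry positive.

## Population-structure module

The FST distance matrix between breeds uses the Hudson ratio-of-averages
per pair over all sites with at least two called alleles in both
populations. The tree is built by Saitou–Nei neighbor joining with the
Studier–Keppler criterion; on any additive matrix it reproduces the
pairwise path lengths exactly. (The "Fitch" least-squares program is a
different algorithm; neighbor joining is what this package implements, and
the naming collision in common usage is why the choice is stated
explicitly.) PCA uses Patterson normalization — center at $2\hat p$, scale
by $\sqrt{2\hat p(1-\hat p)}$, mean-impute missing dosages — followed by
eigendecomposition of the sample covariance; coordinates are eigenvectors
scaled by $\sqrt{\lambda}$, so their cross-product is the diagonal matrix
of eigenvalues. LD decay bins all intra-chromosomal pairs within 500 kb by
distance (1-kb bins) using the squared allelic correlation within each
population; the half-decay distance is the smallest bin midpoint at or
below half the maximum binned mean.

## A worked example

```{r example, eval = FALSE}
sim <- simulateForwardTwoPop(nChrom = 5, sampleSize = 50,
                             selection = list(s = 0.2), seed = 1)
res <- runSweepScan(sim$haplotypes, sim$assignment,
                    selected = "pop1", reference = "pop2",
                    outDir = "scan_out")
res$sweeps          # merged candidate regions
head(res$windowTable)
```

`fineMapRegion()` re-evaluates XP-EHH, Tajima's D and the π-ratio on
sliding sub-windows (50-kb default; a 1,000-bp grid is equally supported)
inside any candidate region, and `sharedGenes()` intersects candidate gene
sets across scans of several environmental contrasts.

## Known limitations

* The forward simulator's drift timescale and chromosome length place the
  whole swept chromosome inside the sweep's haplotype footprint;
  fine-mapping resolution within a chromosome is therefore not testable at
  desk scale, only locus recovery at window/region level. Concretely: the
  localization scale of a sweep is about $1/(rT)$, which at
  $r = 10^{-8}$/bp and $T \le 2N$ generations is of megabase order —
  comparable to the whole 2-Mb chromosome. Selection therefore perturbs
  allele frequencies nearly uniformly along the swept chromosome, and
  which of its windows end up in the top-5% tails is driven by drift
  noise rather than by proximity to the locus. In the bundled recovery
  study this shows up as a clean separation between two levels of
  recovery: called sweep regions fall essentially only on the swept
  chromosome and the near-locus XP-EHH maximum exceeds the genome-wide
  99th percentile in almost every replicate, while the planted base pair
  itself lands inside a called (top-5%-limited, merged) region in only a
  majority — not the vast majority — of replicates. The
  mutation-to-recombination ratio of the generator (about fifty-fold
  higher than in real mammalian genomes, a consequence of producing
  enough SNPs on a short chromosome) further erodes the haplotype
  signature of sweeps that fix early.
* XP-EHH scores near chromosome ends are structurally undefined under the
  edge-exclusion rule; real scans share this property but on 2-Mb
  chromosomes the affected fraction is larger.
* The scan assumes fully phased, fully called haplotypes for all
  haplotype statistics (phasing is upstream of this package); sites with
  missing genotypes participate only in the dosage-based statistics.
* Unstated aspects of the original workflow (whether the MAF filter was
  applied once genome-wide or per scan pair; whether edge-truncated
  scores were retained; the fine-mapping window actually used) are
  resolved by documented defaults with switches
  (`perPopMaf`, `includeEdgeTruncated`, `subWindow`).
```
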
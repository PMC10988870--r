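#' @include AllClasses.R
NULL

writeJson <- function(x, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write JSON provenance files")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

writeManifest <- function(outDir, inputs, config) {
  cfgPath <- file.path(outDir, "config.json")
  writeJson(config, cfgPath)
  manifest <- list(
    inputs = inputs,
    configFile = "config.json",
    configMd5 = unname(tools::md5sum(cfgPath)),
    package = "SweepScan",
    version = as.character(utils::packageVersion("SweepScan")))
  writeJson(manifest, file.path(outDir, "manifest.json"))
}

#' Simulate a dataset and write it as VCF + population file + truth JSON
#'
#' Runs [simulateForwardTwoPop()] (or [simulateBaldingNichols()] with
#' `mode = "balding_nichols"`) and writes a self-describing dataset
#' directory: `data.vcf` (phased GT for the forward model), `populations.txt`,
#' `truth.json`, `config.json` and `manifest.json`.
#'
#' @param outDir output directory (created if needed).
#' @param mode `"forward_wf"` or `"balding_nichols"`.
#' @param seed mandatory integer seed.
#' @param ... passed to the chosen simulator.
#' @return The simulation result, invisibly.
#' @export
simulateDataset <- function(outDir, mode = c("forward_wf", "balding_nichols"),
                            seed, ...) {
  mode <- match.arg(mode)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  sim <- if (mode == "forward_wf") {
    simulateForwardTwoPop(seed = seed, ...)
  } else {
    simulateBaldingNichols(seed = seed, ...)
  }
  g <- if (mode == "forward_wf") asGenotypes(sim$haplotypes) else sim$genotypes
  writeVcfGenotypes(g, file.path(outDir, "data.vcf"))
  writePopulationFile(sim$assignment, file.path(outDir, "populations.txt"))
  truth <- sim$truth
  truth$pAnc <- NULL  # keep the JSON small; full truth stays in the return
  truth$pPop <- NULL
  writeJson(truth, file.path(outDir, "truth.json"))
  writeManifest(outDir, inputs = list(),
                config = c(list(command = "simulate", mode = mode,
                                seed = seed),
                           lapply(list(...), function(x)
                             if (is.atomic(x)) x else "complex")))
  invisible(sim)
}

#' Filter a VCF and write the surviving sites
#'
#' @param vcfIn input VCF path.
#' @param vcfOut output VCF path.
#' @param params [filterParams()].
#' @param reportPath optional TSV path for the filter report.
#' @return The filter report, invisibly.
#' @export
filterVcf <- function(vcfIn, vcfOut, params = filterParams(),
                      reportPath = NULL) {
  g <- readVcfGenotypes(vcfIn)
  gf <- filterSites(g, params)
  writeVcfGenotypes(gf, vcfOut)
  rep <- filterReport(gf)
  if (!is.null(reportPath)) writeFilterReport(rep, reportPath)
  invisible(rep)
}

#' Run the full two-population sweep scan
#'
#' End-to-end orchestration of the scan: read (or accept) phased genotypes
#' and the population assignment, subset to the scan pair, apply the SNP
#' inclusion filters, compute per-site FST statistics, XP-EHH scores with
#' genome-wide standardization, aggregate over consecutive 50-kb windows,
#' call sweep windows (top-5% FST and top-5% |XP-EHH| intersection with
#' Fisher enrichment `P < 0.05` by default), merge adjacent sweeps within
#' 50 kb and annotate them with overlapping genes. All outputs are written
#' to `outDir` (window TSV, per-site XP-EHH TSV, sweep BED + gene TSV,
#' filter report, `config.json`, `manifest.json`); inputs are never
#' mutated and identical inputs give byte-identical outputs.
#'
#' @param x a phased [GenotypeMatrix-class], [HaplotypeMatrix-class] or VCF
#'   path.
#' @param assignment named population vector or population-file path.
#' @param selected,reference population labels of the scan pair.
#' @param genes optional gene `GRanges` (or BED/GFF3 path) for annotation.
#' @param thresholds [scanThresholds()].
#' @param filter [filterParams()].
#' @param rule sweep-calling rule, `"intersect"` (default) or
#'   `"xpehh_1pct"`.
#' @param chromLengths optional named chromosome lengths for the window
#'   grid.
#' @param maxExtend XP-EHH extension cap in bp (default 3e5). selscan's own
#'   default is 1e6, designed for chromosomes much longer than that; on
#'   short (few-Mb) chromosomes the cap must stay below half the chromosome
#'   length, or every high-homozygosity curve reaches the chromosome edge
#'   and is discarded by the edge-truncation rule.
#' @param outDir optional output directory; `NULL` computes without
#'   writing.
#' @return List with `windowTable`, `sweeps` (annotated `GRanges`),
#'   `xpehh`, `siteStats`, `cutoffs`, `filterReport`.
#' @export
runSweepScan <- function(x, assignment, selected, reference, genes = NULL,
                         thresholds = scanThresholds(),
                         filter = filterParams(), rule = "intersect",
                         chromLengths = NULL, maxExtend = 3e5,
                         outDir = NULL) {
  if (is.character(x)) x <- readVcfGenotypes(x)
  hFull <- NULL
  if (is(x, "HaplotypeMatrix")) {
    hFull <- x
    x <- asGenotypes(x, withGT = FALSE)
  }
  if (is.character(assignment) && length(assignment) == 1L && is.null(names(assignment)))
    assignment <- readPopulationFile(assignment, samples = sampleIds(x))
  if (is.character(genes)) genes <- readGeneAnnotation(genes)

  scanIds <- sampleIds(x)[assignment[sampleIds(x)] %in%
                            c(selected, reference)]
  if (!length(scanIds)) stop("no samples in the scan populations")
  if (identical(scanIds, sampleIds(x))) {
    g <- x
  } else {
    g <- x[scanIds, ]
    if (!is.null(hFull)) hFull <- hFull[scanIds, ]
  }
  gf <- filterSites(g, filter)

  ## EHH decay is driven by rare variants, so the XP-EHH substrate keeps
  ## every fully-called biallelic polymorphic site; the MAF rule only
  ## selects which cores are scored (selscan semantics). Window statistics
  ## use the filtered scan sites. When the input is already phased
  ## haplotypes, they are subset directly instead of re-parsing GT strings.
  gSub <- filterSites(g, filterParams(maxMissingRate = 0, mafMin = 0,
                                      biallelicOnly = TRUE))
  hSubAll <- if (is.null(hFull)) asHaplotypes(gSub)
             else hFull[, filterReport(gSub)$keptIndex]
  hSub <- splitByPopulation(hSubAll, assignment)
  xpFull <- xpehhScan(hSub[[selected]], hSub[[reference]],
                      minMaf = filter@mafMin, maxExtend = maxExtend)

  h <- if (is.null(hFull)) asHaplotypes(gf)
       else hFull[, filterReport(gf)$keptIndex]
  hs <- splitByPopulation(h, assignment)
  hSel <- hs[[selected]]
  hRef <- hs[[reference]]

  stats <- siteStatistics(gf, assignment, selected, reference)
  sKey <- paste(stats$chrom, stats$pos)
  xp <- xpFull[match(sKey, paste(xpFull$chrom, xpFull$pos)), ]
  rownames(xp) <- NULL
  win <- assignWindows(sites(gf), chromLengths, thresholds@windowSize)
  tbl <- computeWindowStats(stats, xp, hSel, hRef, win, thresholds)
  called <- callSweeps(tbl, thresholds, rule)
  sweeps <- called$sweeps
  if (!is.null(genes) && length(sweeps))
    sweeps <- annotateSweeps(sweeps, genes)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeWindowTable(called$table, file.path(outDir, "windows.tsv"))
    writeXpehhTable(xp, file.path(outDir, "xpehh.tsv"))
    writeSweepBed(sweeps, file.path(outDir, "sweeps.bed"))
    writeFilterReport(filterReport(gf), file.path(outDir, "filter_report.tsv"))
    sweepGenes <- data.frame(
      chrom = as.character(seqnames(sweeps)),
      start1 = start(sweeps), end1 = end(sweeps),
      genes = vapply(
        if ("genes" %in% names(mcols(sweeps))) as.list(mcols(sweeps)$genes)
        else rep(list(character(0)), length(sweeps)),
        paste, character(1), collapse = ","))
    write.table(sweepGenes, file.path(outDir, "sweep_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeManifest(outDir,
      inputs = list(samples = length(scanIds),
                    sitesIn = nSites(g), sitesUsed = nSites(gf)),
      config = list(command = "scan", selected = selected,
                    reference = reference, rule = rule,
                    thresholds = list(
                      fstTail = thresholds@fstTail,
                      xpehhTail = thresholds@xpehhTail,
                      windowTail1pct = thresholds@windowTail1pct,
                      fisherAlpha = thresholds@fisherAlpha,
                      minSnps = thresholds@minSnps,
                      windowSize = thresholds@windowSize,
                      mergeGap = thresholds@mergeGap),
                    filter = list(
                      maxMissingRate = filter@maxMissingRate,
                      mafMin = filter@mafMin,
                      biallelicOnly = filter@biallelicOnly)))
  }
  list(windowTable = called$table, sweeps = sweeps, xpehh = xp,
       siteStats = stats, cutoffs = called$cutoffs,
       filterReport = filterReport(gf))
}

#' Run several scan pairs and report shared candidate genes
#'
#' Runs [runSweepScan()] for each named scan pair (the multi-environment
#' design: e.g. drought, altitude and temperature contrasts against their
#' reference groups), writes per-scan subdirectories, and emits the table
#' of genes shared across all scans and per scan pair.
#'
#' @param x,assignment,genes,thresholds,filter,rule,chromLengths as in
#'   [runSweepScan()].
#' @param pairs named list of `list(selected =, reference =)`.
#' @param outDir optional output directory.
#' @return List with per-scan results, `sharedGenes`, and per-scan gene
#'   sets.
#' @export
runMultiScan <- function(x, assignment, pairs, genes = NULL,
                         thresholds = scanThresholds(),
                         filter = filterParams(), rule = "intersect",
                         chromLengths = NULL, maxExtend = 3e5,
                         outDir = NULL) {
  if (is.character(x)) x <- readVcfGenotypes(x)
  if (is.character(assignment) && length(assignment) == 1L && is.null(names(assignment)))
    assignment <- readPopulationFile(assignment, samples = sampleIds(x))
  if (is.character(genes)) genes <- readGeneAnnotation(genes)
  scans <- lapply(names(pairs), function(nm) {
    runSweepScan(x, assignment, pairs[[nm]]$selected, pairs[[nm]]$reference,
                 genes = genes, thresholds = thresholds, filter = filter,
                 rule = rule, chromLengths = chromLengths,
                 maxExtend = maxExtend,
                 outDir = if (is.null(outDir)) NULL
                          else file.path(outDir, nm))
  })
  names(scans) <- names(pairs)
  geneSets <- lapply(scans, function(sc) {
    if (length(sc$sweeps) && "genes" %in% names(mcols(sc$sweeps)))
      sort(unique(unlist(mcols(sc$sweeps)$genes)))
    else character(0)
  })
  shared <- if (length(geneSets) >= 2L) sharedGenes(geneSets) else NULL
  if (!is.null(outDir) && !is.null(shared)) {
    writeLines(shared$shared, file.path(outDir, "shared_genes.txt"))
    write.table(shared$pairwise, file.path(outDir, "shared_genes_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(scans = scans, sharedGenes = shared, geneSets = geneSets)
}

#' Run the population-structure analyses
#'
#' Pairwise Hudson FST distance matrix between populations with a
#' neighbor-joining tree (Newick), Patterson-normalized PCA of individuals,
#' and per-population LD decay curves (phased input required for LD).
#'
#' @param x [GenotypeMatrix-class], [HaplotypeMatrix-class] or VCF path.
#' @param assignment named population vector or file path.
#' @param k PCA components (default `min(10, samples)`).
#' @param filter [filterParams()] applied before the analyses.
#' @param maxDist,binWidth LD decay parameters, see [ldDecay()].
#' @param doLd compute LD decay (requires phased genotypes; default TRUE).
#' @param outDir optional output directory (`fst_matrix.tsv`, `nj.nwk`,
#'   `pca.tsv`, `eigenvalues.tsv`, `ld_decay.tsv`).
#' @return List with `fst`, `tree`, `pca`, `ld`.
#' @export
runStructureAnalysis <- function(x, assignment, k = NULL,
                                 filter = filterParams(),
                                 maxDist = 500000L, binWidth = 1000L,
                                 doLd = TRUE, outDir = NULL) {
  if (is.character(x)) x <- readVcfGenotypes(x)
  h <- NULL
  if (is(x, "HaplotypeMatrix")) {
    h <- x
    x <- asGenotypes(x)
  }
  if (is.character(assignment) && length(assignment) == 1L && is.null(names(assignment)))
    assignment <- readPopulationFile(assignment, samples = sampleIds(x))
  gf <- filterSites(x, filter)
  fst <- pairwiseFstMatrix(gf, assignment)
  tree <- if (nrow(fst) >= 3) njTree(fst) else NULL
  if (is.null(k)) k <- min(10L, nSamples(gf))
  pca <- genotypePca(gf, k)
  ld <- NULL
  if (doLd) {
    if (is.null(h)) h <- asHaplotypes(gf) else h <- asHaplotypes(filterSites(
      asGenotypes(h), filter))
    ld <- ldDecay(h, assignment, maxDist = maxDist, binWidth = binWidth)
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.table(fst, file.path(outDir, "fst_matrix.tsv"), sep = "\t",
                quote = FALSE)
    if (!is.null(tree)) ape::write.tree(tree, file.path(outDir, "nj.nwk"))
    write.table(data.frame(sample = rownames(pca$coords),
                           population = unname(assignment[rownames(pca$coords)]),
                           pca$coords),
                file.path(outDir, "pca.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(component = seq_along(pca$eigenvalues),
                           eigenvalue = pca$eigenvalues,
                           var_frac = pca$varFrac),
                file.path(outDir, "eigenvalues.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(ld)) writeLdCurves(ld, file.path(outDir, "ld_decay.tsv"))
    writeManifest(outDir,
      inputs = list(samples = nSamples(gf), sitesUsed = nSites(gf)),
      config = list(command = "structure", k = k, maxDist = maxDist,
                    binWidth = binWidth))
  }
  list(fst = fst, tree = tree, pca = pca, ld = ld)
}
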
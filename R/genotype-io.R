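#' @include AllClasses.R
NULL

## VCF pos is 1-based; GRanges is 1-based closed, so positions carry through
## unchanged. BED is converted at the boundary (0-based half-open -> 1-based
## closed) and re-converted on output.

parseRegion <- function(region) {
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L)
    stop("region must have the form chrom:start-end, got '", region, "'")
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF v4.x file (plain or bgzipped) and returns a
#' [GenotypeMatrix-class]. Only the `GT` FORMAT field is consumed; all other
#' FORMAT and INFO fields are ignored. Dosage is the count of non-reference
#' alleles per genotype; genotypes containing a `.` allele (`./.`, `.|.`,
#' half-calls) map to missing, never to homozygous reference. Multi-allelic
#' records are retained with their full alternate-allele list (they are
#' removed later by [filterSites()] when `biallelicOnly` is set). Sites are
#' ordered by (chromosome, position). Ploidy is fixed at two: haploid or
#' polyploid GT values are rejected.
#'
#' @param path VCF file path.
#' @param region optional `"chrom:start-end"` (1-based inclusive) restriction;
#'   a region containing no records yields an empty matrix, not an error.
#' @param renameChrom optional named character vector mapping VCF chromosome
#'   names to the names used elsewhere (matching is otherwise exact; no
#'   implicit "chr" normalization).
#' @return A [GenotypeMatrix-class].
#' @examples
#' vcf <- system.file("extdata", "toy.vcf", package = "SweepScan")
#' g <- readVcfGenotypes(vcf)
#' dosage(g)
#' @export
readVcfGenotypes <- function(path, region = NULL, renameChrom = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  nMeta <- length(v@meta)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    sites <- GRanges()
    mcols(sites)$id <- character(0)
    mcols(sites)$ref <- character(0)
    mcols(sites)$alt <- CharacterList()
    smp <- colnames(v@gt)[-1L]
    d <- matrix(integer(0), nrow = length(smp), ncol = 0L,
                dimnames = list(smp, NULL))
    return(GenotypeMatrix(sites, d, gt = d))
  }
  chrom <- as.character(fix[, "CHROM"])
  if (!is.null(renameChrom)) {
    hit <- chrom %in% names(renameChrom)
    chrom[hit] <- unname(renameChrom[chrom[hit]])
  }
  pos <- as.integer(fix[, "POS"])
  keep <- rep(TRUE, length(pos))
  if (!is.null(region)) {
    rg <- parseRegion(region)
    keep <- chrom == rg$chrom & pos >= rg$start & pos <= rg$end
  }
  gtRaw <- vcfR::extract.gt(v, element = "GT", convertNA = FALSE)
  if (is.null(dim(gtRaw))) gtRaw <- matrix(gtRaw, nrow = nrow(fix))
  samples <- colnames(v@gt)[-1L]
  colnames(gtRaw) <- samples
  idx <- which(keep)
  ord <- idx[order(chrom[idx], pos[idx])]
  gtm <- t(gtRaw[ord, , drop = FALSE])  # samples x sites
  rownames(gtm) <- samples

  ## decode GT -> dosage; diploid only (some parsers surface "./." as NA)
  gtm[is.na(gtm)] <- "./."
  gtv <- as.vector(gtm)
  ok <- grepl("^(\\.|[0-9]+)[/|](\\.|[0-9]+)$", gtv)
  if (any(!ok)) {
    bad <- which(!ok)[1L]
    siteIdx <- (bad - 1L) %/% nrow(gtm) + 1L
    smpIdx <- (bad - 1L) %% nrow(gtm) + 1L
    rec <- ord[siteIdx]
    stop(sprintf(
      "malformed or non-diploid GT '%s' for sample %s at %s:%d (VCF line %d)",
      gtv[bad], samples[smpIdx], chrom[rec], pos[rec], nMeta + 1L + rec))
  }
  left <- sub("^(\\.|[0-9]+)[/|].*$", "\\1", gtv)
  right <- sub("^.*[/|](\\.|[0-9]+)$", "\\1", gtv)
  miss <- left == "." | right == "."
  dos <- suppressWarnings(
    (as.integer(left) > 0L) + (as.integer(right) > 0L))
  dos[miss] <- NA_integer_
  d <- matrix(as.integer(dos), nrow = nrow(gtm), dimnames = dimnames(gtm))

  alt <- strsplit(as.character(fix[ord, "ALT"]), ",", fixed = TRUE)
  id <- as.character(fix[ord, "ID"])
  id[!is.na(id) & id == "."] <- NA_character_
  sitesGR <- GRanges(chrom[ord], IRanges(pos[ord], width = 1L))
  mcols(sitesGR)$id <- id
  mcols(sitesGR)$ref <- as.character(fix[ord, "REF"])
  mcols(sitesGR)$alt <- CharacterList(alt)
  g <- GenotypeMatrix(sitesGR, d, gt = gtm)
  metadata(g)$source <- path
  g
}

#' Write genotypes to a VCF file
#'
#' Writes a minimal VCF v4.2 with the stored raw `GT` strings, so that a
#' phased biallelic file read with [readVcfGenotypes()] round-trips its GT
#' column bit-exactly.
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(g, path) {
  s <- sites(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleIds(g)), collapse = "\t")), con)
  if (length(s)) {
    id <- mcols(s)$id
    id[is.na(id)] <- "."
    alt <- vapply(mcols(s)$alt, paste, character(1), collapse = ",")
    body <- paste(as.character(seqnames(s)), start(s), id, mcols(s)$ref, alt,
                  ".", ".", ".", "GT", sep = "\t")
    gtcol <- apply(gtStrings(g), 2, paste, collapse = "\t")
    writeLines(paste(body, gtcol, sep = "\t"), con)
  }
  invisible(path)
}

#' Expand phased genotypes into haplotypes
#'
#' Converts a fully phased, fully called, biallelic [GenotypeMatrix-class]
#' into a [HaplotypeMatrix-class]. Haplotype rows `2i - 1` and `2i` are sample
#' `i`'s left and right alleles in VCF order, so `"1|0"` and `"0|1"` remain
#' distinguishable. Column sums of the haplotype matrix reproduce the dosage
#' column sums exactly (conservation of allele counts).
#'
#' @param x a `GenotypeMatrix` with phased (`|`) non-missing biallelic GTs.
#' @param ... unused.
#' @return A [HaplotypeMatrix-class].
#' @export
setMethod("asHaplotypes", "GenotypeMatrix", function(x, ...) {
  nAlt <- lengths(mcols(sites(x))$alt)
  if (any(nAlt != 1L))
    stop("all sites must be biallelic; offending site(s): ",
         paste(head(which(nAlt != 1L), 5L), collapse = ", "))
  gtv <- as.vector(gtStrings(x))
  bad <- !grepl("^[01]\\|[01]$", gtv)
  if (any(bad)) {
    b <- which(bad)[1L]
    j <- (b - 1L) %/% nSamples(x) + 1L
    i <- (b - 1L) %% nSamples(x) + 1L
    stop(sprintf(
      "unphased or missing genotype '%s' (sample %s, site %s:%d); %d offending calls in total",
      gtv[b], sampleIds(x)[i], as.character(seqnames(sites(x)))[j],
      start(sites(x))[j], sum(bad)))
  }
  left <- matrix(as.integer(substr(gtv, 1L, 1L)), nrow = nSamples(x))
  right <- matrix(as.integer(substr(gtv, 3L, 3L)), nrow = nSamples(x))
  n <- nSamples(x)
  a <- matrix(0L, nrow = 2L * n, ncol = nSites(x))
  a[seq(1L, 2L * n, by = 2L), ] <- left
  a[seq(2L, 2L * n, by = 2L), ] <- right
  HaplotypeMatrix(sites(x), a, sampleIds(x))
})

#' Read a sample-to-population assignment file
#'
#' Two whitespace-delimited columns: sample id, population label. Every
#' sample belongs to exactly one population.
#'
#' @param path file path.
#' @param samples optional character vector of expected sample ids; ids in
#'   the file but not in `samples` raise an error.
#' @return Named character vector mapping sample id to population label.
#' @export
readPopulationFile <- function(path, samples = NULL) {
  tb <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("sample", "population"),
                   colClasses = "character")
  if (anyDuplicated(tb$sample))
    stop("sample(s) assigned to more than one population: ",
         paste(unique(tb$sample[duplicated(tb$sample)]), collapse = ", "))
  if (!is.null(samples)) {
    unknown <- setdiff(tb$sample, samples)
    if (length(unknown))
      stop("unknown sample(s) in population file: ",
           paste(unknown, collapse = ", "))
  }
  setNames(tb$population, tb$sample)
}

#' Write a population assignment file
#' @param assignment named character vector (names = samples, values =
#'   population labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePopulationFile <- function(assignment, path) {
  write.table(data.frame(sample = names(assignment),
                         population = unname(assignment)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene annotation intervals from BED or GFF3
#'
#' BED input is interpreted as 0-based half-open and converted at the
#' boundary; GFF3 is 1-based inclusive. A BED line `chr7 100 200 GENE1` and a
#' GFF3 line with start 101 and end 200 therefore describe the same interval.
#' For GFF3, records of type `gene` are kept when a type column is present
#' (otherwise all records), and the gene name is taken from the `Name`, then
#' `gene_id`, then `ID` attribute. Overlapping gene records are allowed.
#' Chromosome names are matched exactly; use `renameChrom` to reconcile
#' naming schemes.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @param renameChrom optional named character rename map.
#' @return `GRanges` with a `gene` metadata column.
#' @export
readGeneAnnotation <- function(path, format = c("auto", "bed", "gff3"),
                               renameChrom = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    gene <- if ("name" %in% names(mcols(gr))) mcols(gr)$name
            else paste0("feature_", seq_along(gr))
  } else {
    gr <- rtracklayer::import(path, format = "GFF3")
    if ("type" %in% names(mcols(gr)) && any(mcols(gr)$type == "gene"))
      gr <- gr[mcols(gr)$type == "gene"]
    mc <- mcols(gr)
    gene <- rep(NA_character_, length(gr))
    for (field in c("Name", "gene_id", "ID")) {
      if (field %in% names(mc)) {
        val <- as.character(mc[[field]])
        gene[is.na(gene) & !is.na(val)] <- val[is.na(gene) & !is.na(val)]
      }
    }
    gene[is.na(gene)] <- paste0("feature_", which(is.na(gene)))
  }
  out <- granges(gr)
  if (!is.null(renameChrom)) {
    lv <- seqlevels(out)
    hit <- lv %in% names(renameChrom)
    lv[hit] <- unname(renameChrom[lv[hit]])
    out <- GenomeInfoDb::renameSeqlevels(out, lv)
  }
  mcols(out)$gene <- gene
  out
}

numFormat <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write / read the per-window statistics table
#'
#' TSV with a fixed header; coordinates are 1-based inclusive (matching the
#' reported window style, e.g. 90600001-90650000). Numeric columns are
#' written with 17 significant digits so a written table re-reads identically.
#'
#' @param tbl window statistics `data.frame` from [computeWindowStats()].
#' @param path output path.
#' @return `path` (write) or the table (read).
#' @export
writeWindowTable <- function(tbl, path) {
  out <- tbl
  for (cc in names(out)) {
    if (is.numeric(out[[cc]]) && !is.integer(out[[cc]]))
      out[[cc]] <- numFormat(out[[cc]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeWindowTable
#' @export
readWindowTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}

#' Write merged sweep regions as BED (plus statistics columns)
#'
#' Output is 0-based half-open BED: a 1-based closed sweep
#' `[start1, end1]` becomes `start1 - 1, end1`. Extra columns carry the
#' number of member windows, peak weighted FST, peak |XP-EHH| and the
#' comma-separated overlapping gene list.
#'
#' @param sweeps sweep `GRanges` from [callSweeps()] / [annotateSweeps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSweepBed <- function(sweeps, path) {
  mc <- mcols(sweeps)
  genes <- if ("genes" %in% names(mc))
    vapply(mc$genes, function(gg) paste(gg, collapse = ","), character(1))
  else rep(".", length(sweeps))
  genes[genes == ""] <- "."
  df <- data.frame(
    chrom = as.character(seqnames(sweeps)),
    start = start(sweeps) - 1L,
    end = end(sweeps),
    name = if (length(sweeps)) paste0("sweep_", seq_along(sweeps))
           else character(0),
    n_windows = if ("nWindows" %in% names(mc)) mc$nWindows
                else rep(NA_integer_, length(sweeps)),
    peak_fst = numFormat(if ("peakFst" %in% names(mc)) mc$peakFst
                         else rep(NA_real_, length(sweeps))),
    peak_xpehh = numFormat(if ("peakXpehh" %in% names(mc)) mc$peakXpehh
                           else rep(NA_real_, length(sweeps))),
    genes = genes,
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Split a genotype or haplotype matrix by population
#'
#' @param x `GenotypeMatrix` or `HaplotypeMatrix`.
#' @param assignment named character vector from [readPopulationFile()].
#' @return Named list of per-population subsets (sample order preserved).
#' @export
splitByPopulation <- function(x, assignment) {
  ids <- sampleIds(x)
  missing <- setdiff(ids, names(assignment))
  if (length(missing))
    stop("samples without population assignment: ",
         paste(head(missing, 5L), collapse = ", "))
  pops <- unique(unname(assignment[ids]))
  out <- lapply(pops, function(p) x[ids[assignment[ids] == p], ])
  names(out) <- pops
  out
}
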
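#' Variant identity keys
#'
#' Variants are matched across strains by exact (chromosome, position,
#' ref, alt); inputs are expected to be normalized (the simulator's are;
#' real VCFs should be left-aligned before comparison).
#'
#' @param records variant data.frame.
#' @return Character vector \code{"chrom:pos:ref:alt"}.
#' @export
variantKey <- function(records)
  paste(records$chrom, records$pos, records$ref, records$alt, sep = ":")

#' Filter variant records
#'
#' Keeps records with quality strictly greater than \code{minQuality}
#' (a record at exactly the threshold is removed) and depth within
#' \code{[minDepth, maxDepth]}. Records with unknown depth are kept on the
#' depth criterion (quality still applies). Filtering is idempotent.
#'
#' @param records variant data.frame from \code{\link{readVariants}}.
#' @param config a \linkS4class{FilterConfig}.
#' @return The filtered data.frame.
#' @export
filterVariants <- function(records, config = filterConfig()) {
  stopifnot(is(config, "FilterConfig"))
  if (!nrow(records)) return(records)
  keep <- !is.na(records$qual) & records$qual > config@minQuality
  depthOk <- is.na(records$depth) |
    (records$depth >= config@minDepth & records$depth <= config@maxDepth)
  out <- records[keep & depthOk, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition two strains' variants into shared and strain-specific sets
#'
#' Variants are matched by exact key (\code{\link{variantKey}}). A variant
#' present in only one strain is reported as strain-specific only when the
#' other strain is covered (depth >= \code{minDepth}) at that position,
#' taken from its coverage track; otherwise it is dropped as
#' unresolvable. With \code{requireCoverageBothStrains = FALSE} every
#' single-strain variant is strain-specific.
#'
#' @param wtRecords,mutRecords filtered variant data.frames.
#' @param config a \linkS4class{FilterConfig}.
#' @param wtCoverage,mutCoverage coverage tracks (see
#'   \code{\link{readCoverage}}); required when
#'   \code{requireCoverageBothStrains} is TRUE.
#' @return A list of class \code{ComparisonResult}: \code{shared},
#'   \code{wtOnly}, \code{mutOnly}, \code{dropped} (data.frames; shared
#'   carries both strains' genotypes), \code{snpFraction} (named
#'   percentage per strain) and \code{counts}.
#' @export
classifySharedSpecific <- function(wtRecords, mutRecords,
                                   config = filterConfig(),
                                   wtCoverage = NULL, mutCoverage = NULL) {
  stopifnot(is(config, "FilterConfig"))
  if (config@requireCoverageBothStrains &&
      (is.null(wtCoverage) || is.null(mutCoverage)))
    stop("requireCoverageBothStrains = TRUE needs both coverage tracks")
  wtKeys <- variantKey(wtRecords); mutKeys <- variantKey(mutRecords)

  sharedIdx <- wtKeys %in% mutKeys
  shared <- wtRecords[sharedIdx, , drop = FALSE]
  if (nrow(shared)) {
    m <- match(wtKeys[sharedIdx], mutKeys)
    shared$genotypeWt <- shared$genotype
    shared$genotypeMut <- mutRecords$genotype[m]
    shared$genotype <- NULL
  }

  resolveSpecific <- function(records, otherCoverage) {
    if (!nrow(records))
      return(list(specific = records, dropped = records))
    if (!config@requireCoverageBothStrains)
      return(list(specific = records, dropped = records[0, , drop = FALSE]))
    depth <- depthAt(otherCoverage, records$chrom, records$pos)
    ok <- !is.na(depth) & depth >= config@minDepth
    list(specific = records[ok, , drop = FALSE],
         dropped = records[!ok, , drop = FALSE])
  }
  wtRes <- resolveSpecific(wtRecords[!wtKeys %in% mutKeys, , drop = FALSE],
                           mutCoverage)
  mutRes <- resolveSpecific(mutRecords[!mutKeys %in% wtKeys, , drop = FALSE],
                            wtCoverage)
  dropped <- rbind(cbind(wtRes$dropped,
                         strain = rep("WT", nrow(wtRes$dropped))),
                   cbind(mutRes$dropped,
                         strain = rep("MUT", nrow(mutRes$dropped))))

  snpFraction <- c(
    WT = if (nrow(wtRecords)) 100 * mean(wtRecords$class == "SNP") else NA,
    MUT = if (nrow(mutRecords)) 100 * mean(mutRecords$class == "SNP") else NA)

  structure(list(
    shared = shared, wtOnly = wtRes$specific, mutOnly = mutRes$specific,
    dropped = dropped, snpFraction = snpFraction,
    counts = c(shared = nrow(shared), wtOnly = nrow(wtRes$specific),
               mutOnly = nrow(mutRes$specific), dropped = nrow(dropped))),
    class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat("Strain variant comparison\n")
  cat("  shared:", x$counts[["shared"]],
      "| WT-only:", x$counts[["wtOnly"]],
      "| MUT-only:", x$counts[["mutOnly"]],
      "| dropped (no coverage):", x$counts[["dropped"]], "\n")
  cat("  SNP fraction: WT", format(x$snpFraction[["WT"]], digits = 4),
      "% | MUT", format(x$snpFraction[["MUT"]], digits = 4), "%\n")
  invisible(x)
}

#' Intersect strain-specific variants with predicted off-target sites
#'
#' Reports every strain-specific variant whose position falls inside an
#' off-target window extended by \code{flank} on each side: positions in
#' \code{[site start - flank, site start + 20 + flank)} (0-based
#' half-open). An empty result is the negative off-target outcome.
#'
#' @param specificVariants data.frame of strain-specific variants
#'   (optionally with a \code{strain} column).
#' @param sites off-target \code{GRanges} from \code{\link{findOffTargets}}.
#' @param flank bp added on each side of the 20-nt site (default 20).
#' @return A data.frame with one row per (site, variant) overlap: site
#'   coordinates/mismatches plus the variant columns.
#' @export
intersectOffTargets <- function(specificVariants, sites, flank = 20L) {
  stopifnot(flank >= 0L)
  empty <- data.frame(siteChrom = character(), siteStart = integer(),
                      siteStrand = character(), mismatches = integer(),
                      chrom = character(), pos = integer(), ref = character(),
                      alt = character())
  if (!nrow(specificVariants) || !length(sites)) return(empty)
  # site window [start0 - flank, start0 + 20 + flank) in 0-based coords
  siteStart0 <- BiocGenerics::start(sites) - 1L
  win <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(sites),
    IRanges::IRanges(start = pmax(1L, siteStart0 - flank + 1L),
                     end = siteStart0 + 20L + flank))
  vgr <- GenomicRanges::GRanges(specificVariants$chrom,
                                IRanges::IRanges(specificVariants$pos,
                                                 width = 1L))
  ov <- GenomicRanges::findOverlaps(win, vgr, ignore.strand = TRUE)
  if (!length(ov)) return(empty)
  si <- S4Vectors::queryHits(ov); vi <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    siteChrom = as.character(GenomeInfoDb::seqnames(sites))[si],
    siteStart = siteStart0[si],
    siteStrand = as.character(BiocGenerics::strand(sites))[si],
    mismatches = sites$mismatches[si])
  cbind(out, specificVariants[vi, , drop = FALSE], row.names = NULL)
}
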
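#' Run the full strain-assessment pipeline
#'
#' Orchestrates simulation (or loading of existing inputs), guide
#' scoring and off-target search, variant filtering and shared/specific
#' classification, off-target intersection, windowed heterozygosity and
#' differential LOH calling with mechanism classification, strain
#' similarity, and SV support filtering, summary and comparison, into one
#' consolidated report. When a truth table is available the report gains
#' precision/recall for strain-specific variants, LOH tracts and
#' strain-specific SVs.
#'
#' @param simConfig a \linkS4class{SimulationConfig} to simulate inputs
#'   from, or NULL to use \code{inputs}.
#' @param inputs named list of paths (\code{reference, wtVcf, mutVcf,
#'   wtCoverage, mutCoverage, wtSv, mutSv}, optionally \code{truth}) as
#'   written by \code{\link{simulateAll}}; ignored when \code{simConfig}
#'   is given.
#' @param guide a \linkS4class{GuideRNA}, or NULL to skip the guide and
#'   intersection stages. With \code{simConfig} and a target edit, the
#'   default builds the guide from the target spec.
#' @param maxMismatches off-target scan depth (default 4).
#' @param filterCfg a \linkS4class{FilterConfig}.
#' @param lohCfg an \linkS4class{LOHConfig}.
#' @param svMinSupport SV support filter (default 10).
#' @param svTolerance,svMinReciprocalOverlap SV matching parameters.
#' @param outdir directory for per-stage artifacts and the JSON report,
#'   or NULL to skip writing.
#' @return A list of class \code{RunReport} with one element per stage:
#'   \code{design}, \code{comparison} counts, \code{offtargetIntersection},
#'   \code{loh} segment table, \code{similarity}, \code{sv}, and
#'   \code{truthEvaluation} when truth is present.
#' @export
runPipeline <- function(simConfig = NULL, inputs = NULL, guide = NULL,
                        maxMismatches = 4L, filterCfg = filterConfig(),
                        lohCfg = lohConfig(), svMinSupport = 10L,
                        svTolerance = 1000L, svMinReciprocalOverlap = 0.5,
                        outdir = NULL) {
  if (is.null(simConfig) && is.null(inputs))
    stop("provide either simConfig or inputs")

  if (!is.null(simConfig)) {
    sim <- simulateAll(simConfig, dir = outdir)
    genome <- sim$genome
    wtRaw <- sim$wtVariants; mutRaw <- sim$mutVariants
    wtCov <- sim$wtCoverage; mutCov <- sim$mutCoverage
    wtSv <- sim$wtSv; mutSv <- sim$mutSv
    truth <- sim$truth
    if (is.null(guide) && !is.null(simConfig@targetSpec))
      guide <- guideRNA(simConfig@targetSpec@protospacer,
                        simConfig@targetSpec@pam)
  } else {
    genome <- .checkGenome(Biostrings::readDNAStringSet(inputs$reference))
    names(genome) <- sub("\\s.*$", "", names(genome))
    wtRaw <- readVariants(inputs$wtVcf)
    mutRaw <- readVariants(inputs$mutVcf)
    wtCov <- readCoverage(inputs$wtCoverage)
    mutCov <- readCoverage(inputs$mutCoverage)
    wtSv <- readSvTable(inputs$wtSv)
    mutSv <- readSvTable(inputs$mutSv)
    truth <- if (!is.null(inputs$truth)) readTruth(inputs$truth) else NULL
  }
  genomeLengths <- setNames(as.integer(lengths(genome)), names(genome))

  report <- list(stages = character())

  # guides stage
  sites <- NULL
  if (!is.null(guide)) {
    design <- scoreGuide(genome, guide, maxMismatches)
    sites <- design$sites
    report$design <- design[setdiff(names(design), "sites")]
    report$stages <- c(report$stages, "guides")
  }

  # variants stage
  wtF <- filterVariants(wtRaw, filterCfg)
  mutF <- filterVariants(mutRaw, filterCfg)
  cmp <- classifySharedSpecific(wtF, mutF, filterCfg, wtCov, mutCov)
  report$comparison <- list(counts = as.list(cmp$counts),
                            snpFraction = as.list(cmp$snpFraction))
  report$stages <- c(report$stages, "variants")

  # off-target intersection stage
  if (!is.null(sites)) {
    specific <- rbind(
      cbind(cmp$wtOnly, strain = rep("WT", nrow(cmp$wtOnly))),
      cbind(cmp$mutOnly, strain = rep("MUT", nrow(cmp$mutOnly))))
    offIdx <- sites[sites$mismatches > 0L]
    inter <- intersectOffTargets(specific, offIdx)
    report$offtargetIntersection <- list(
      nVariantsInOfftargets = nrow(inter),
      verdict = if (nrow(inter)) "variants_in_offtargets" else "negative",
      hits = inter)
    report$stages <- c(report$stages, "offtarget_intersection")
  }

  # loh stage
  wtStats <- windowCounts(wtF, genomeLengths, lohCfg@windowSize)
  mutStats <- windowCounts(mutF, genomeLengths, lohCfg@windowSize)
  segments <- callLohSegments(wtStats, mutStats, wtF, mutF, lohCfg,
                              wtCov, mutCov)
  report$loh <- list(
    nSegments = length(segments),
    segments = as.data.frame(segments))
  report$stages <- c(report$stages, "loh")

  # similarity stage
  gm <- encodeGenotypes(list(WT = wtF, MUT = mutF),
                        coverage = list(WT = wtCov, MUT = mutCov),
                        minDepth = filterCfg@minDepth)
  simres <- pairwiseSimilarity(gm, c("WT", "MUT"))
  report$similarity <- simres[c("pearson", "euclidean", "nSitesUsed",
                                "afPearson", "flag")]
  report$stages <- c(report$stages, "similarity")

  # sv stage
  wtSvF <- filterBySupport(wtSv, svMinSupport)
  mutSvF <- filterBySupport(mutSv, svMinSupport)
  svCmp <- compareSvStrains(wtSvF, mutSvF, svTolerance,
                            svMinReciprocalOverlap)
  delEvidence <- lapply(seq_len(nrow(svCmp$mutSpecific)), function(i) {
    rec <- svCmp$mutSpecific[i, , drop = FALSE]
    if (rec$type != "DEL") return(NULL)
    ev <- deletionCoverageEvidence(rec, mutCov, medianDepth(mutCov))
    data.frame(chrom = rec$chrom1, pos1 = rec$pos1, pos2 = rec$pos2,
               ratio = ev$ratio, verdict = ev$verdict)
  })
  delEvidence <- do.call(rbind, delEvidence)
  report$sv <- list(
    summaryWt = unclass(summarizeSv(wtSvF)),
    summaryMut = unclass(summarizeSv(mutSvF)),
    nShared = nrow(svCmp$shared),
    wtSpecific = svCmp$wtSpecific,
    mutSpecific = svCmp$mutSpecific,
    mutDeletionEvidence = delEvidence)
  report$stages <- c(report$stages, "sv")

  if (!is.null(truth))
    report$truthEvaluation <- .evaluateAgainstTruth(truth, cmp, segments,
                                                    svCmp)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    if (!is.null(sites))
      writeOffTargetBed(sites, file.path(outdir, "offtargets.bed"))
    writeLohBed(segments, file.path(outdir, "loh_segments.bed"))
    write.table(wtStats, file.path(outdir, "wt_windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(mutStats, file.path(outdir, "mut_windows.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  structure(report, class = "RunReport")
}

# precision/recall of predicted strain-specific variants, LOH segments
# (matched at >= 50% reciprocal overlap) and strain-specific SVs
.evaluateAgainstTruth <- function(truth, cmp, segments, svCmp) {
  pr <- function(predicted, actual) {
    tp <- length(intersect(predicted, actual))
    list(precision = if (length(predicted)) tp / length(predicted) else NA,
         recall = if (length(actual)) tp / length(actual) else NA)
  }
  variantEval <- list(
    wtOnly = pr(variantKey(cmp$wtOnly), truth$wtOnlyKeys),
    mutOnly = pr(variantKey(cmp$mutOnly), truth$mutOnlyKeys))

  lohEval <- NULL
  tracts <- truth$lohTracts
  if (!is.null(tracts) && nrow(tracts)) {
    segDf <- as.data.frame(segments)
    segDf$start0 <- segDf$start - 1L
    matched <- logical(nrow(tracts))
    segHit <- logical(nrow(segDf))
    for (i in seq_len(nrow(tracts))) {
      for (j in seq_len(nrow(segDf))) {
        if (segDf$seqnames[j] != tracts$chromosome[i] ||
            segDf$affectedStrain[j] != tracts$strain[i]) next
        ov <- min(segDf$end[j], tracts$end[i]) -
          max(segDf$start0[j], tracts$start[i])
        if (ov > 0 &&
            ov / (tracts$end[i] - tracts$start[i]) >= 0.5 &&
            ov / (segDf$end[j] - segDf$start0[j]) >= 0.5) {
          matched[i] <- TRUE; segHit[j] <- TRUE
        }
      }
    }
    lohEval <- list(
      precision = if (nrow(segDf)) mean(segHit) else NA,
      recall = mean(matched))
  }

  svKey <- function(df) if (nrow(df))
    paste(df$type, df$chrom1, df$pos1, df$chrom2, df$pos2) else character()
  svEval <- NULL
  if (!is.null(truth$svs) && nrow(truth$svs)) {
    ts <- truth$svs
    svEval <- list(
      wtSpecific = pr(svKey(svCmp$wtSpecific),
                      svKey(ts[ts$strain == "WT", , drop = FALSE])),
      mutSpecific = pr(svKey(svCmp$mutSpecific),
                       svKey(ts[ts$strain == "MUT", , drop = FALSE])))
  }
  list(variants = variantEval, loh = lohEval, sv = svEval)
}

#' @export
print.RunReport <- function(x, ...) {
  cat("crisprStrainScan run report -- stages:",
      paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$design))
    cat("  guide GC%:", format(x$design$gcPercent, digits = 4),
        "| off-targets:", sum(x$design$nOfftargetsByMismatch), "\n")
  cat("  variants: shared", x$comparison$counts$shared, "| WT-only",
      x$comparison$counts$wtOnly, "| MUT-only",
      x$comparison$counts$mutOnly, "\n")
  if (!is.null(x$offtargetIntersection))
    cat("  off-target intersection:", x$offtargetIntersection$verdict, "\n")
  cat("  LOH segments:", x$loh$nSegments, "\n")
  cat("  similarity: r =", format(x$similarity$pearson, digits = 4),
      "| d =", format(x$similarity$euclidean, digits = 6), "\n")
  cat("  SV: MUT-specific", nrow(x$sv$mutSpecific), "| WT-specific",
      nrow(x$sv$wtSpecific), "\n")
  invisible(x)
}
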
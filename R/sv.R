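.SV_TYPES <- c("DEL", "INV", "ITX", "CTX")

.validateSv <- function(df, source = "SV table") {
  if (!nrow(df)) {
    df$size <- integer()
    return(df)
  }
  bad <- !df$type %in% .SV_TYPES
  if (any(bad))
    stop(source, ": unknown sv type '", df$type[bad][1L],
         "' (expected DEL, INV, ITX or CTX)")
  intra <- df$type != "CTX"
  if (any(intra & df$chrom1 != df$chrom2))
    stop(source, ": intra-chromosomal record with differing chromosomes")
  if (any(!intra & df$chrom1 == df$chrom2))
    stop(source, ": CTX record with identical chromosomes")
  if (any(intra & df$pos2 <= df$pos1))
    stop(source, ": intra-chromosomal record needs pos2 > pos1")
  df$size <- ifelse(intra, df$pos2 - df$pos1, NA_integer_)
  df
}

#' Read a structural-variant table
#'
#' Parses a BEDPE-like TSV (Breakdancer-style consumer) with header
#' columns \code{chrom1, pos1, chrom2, pos2, type, size, supportingReads}.
#' Types are DEL (deletion), INV (inversion), ITX (intra-chromosomal
#' translocation) and CTX (inter-chromosomal translocation). Sizes of
#' intra-chromosomal records are recomputed as \code{pos2 - pos1}
#' (half-open convention); CTX records have no size. Invariants are
#' enforced: CTX iff the chromosomes differ; intra-chromosomal records
#' need \code{pos2 > pos1}.
#'
#' @param path TSV path.
#' @return A validated SV data.frame.
#' @export
readSvTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("chrom1", "pos1", "chrom2", "pos2", "type", "supportingReads")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SV table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  .validateSv(df, source = path)
}

#' Write a structural-variant table
#'
#' @param records SV data.frame.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSvTable <- function(records, path) {
  cols <- c("chrom1", "pos1", "chrom2", "pos2", "type", "size",
            "supportingReads")
  if (!"size" %in% names(records))
    records <- .validateSv(records)
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Filter structural variants by read support
#'
#' Keeps records supported by at least \code{minSupport} reads
#' (inclusive).
#'
#' @param records SV data.frame.
#' @param minSupport minimum supporting reads (default 10).
#' @return The filtered data.frame.
#' @export
filterBySupport <- function(records, minSupport = 10L) {
  out <- records[records$supportingReads >= minSupport, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise a structural-variant table
#'
#' Per-class counts, total, and mean size over intra-chromosomal records
#' (CTX records carry no size; the mean of an empty set is \code{NA}).
#'
#' @param records SV data.frame.
#' @return A list of class \code{SVSummary}: \code{countsByType} (named
#'   over DEL/INV/ITX/CTX), \code{total}, \code{meanSize}.
#' @export
summarizeSv <- function(records) {
  counts <- setNames(integer(length(.SV_TYPES)), .SV_TYPES)
  if (nrow(records)) {
    tab <- table(factor(records$type, levels = .SV_TYPES))
    counts[names(tab)] <- as.integer(tab)
  }
  intra <- records[records$type != "CTX", , drop = FALSE]
  sizes <- if (nrow(intra)) intra$pos2 - intra$pos1 else numeric()
  structure(list(countsByType = counts, total = sum(counts),
                 meanSize = if (length(sizes)) mean(sizes) else NA_real_),
            class = "SVSummary")
}

#' @export
print.SVSummary <- function(x, ...) {
  cat("SV summary: total", x$total, "\n")
  print(x$countsByType)
  cat("  mean size (intra-chromosomal):",
      if (is.na(x$meanSize)) "undefined" else format(x$meanSize, digits = 7),
      "bp\n")
  invisible(x)
}

.svMatches <- function(a, b, tolerance, minReciprocalOverlap) {
  if (a$type != b$type) return(Inf)
  if (a$chrom1 != b$chrom1 || a$chrom2 != b$chrom2) return(Inf)
  d1 <- abs(a$pos1 - b$pos1); d2 <- abs(a$pos2 - b$pos2)
  if (d1 > tolerance || d2 > tolerance) return(Inf)
  if (a$type != "CTX") {
    ov <- min(a$pos2, b$pos2) - max(a$pos1, b$pos1)
    if (ov <= 0) return(Inf)
    if (ov / (a$pos2 - a$pos1) < minReciprocalOverlap ||
        ov / (b$pos2 - b$pos1) < minReciprocalOverlap) return(Inf)
  }
  d1 + d2
}

#' Compare two strains' structural variants
#'
#' Records match when they have the same type, both breakpoints within
#' \code{tolerance}, and -- for intra-chromosomal types -- reciprocal
#' overlap of at least \code{minReciprocalOverlap}. Matching is greedy by
#' total breakpoint distance, each record used at most once. Every input
#' record ends up either shared or specific to its strain.
#'
#' @param wtRecords,mutRecords SV data.frames.
#' @param tolerance breakpoint tolerance in bp (default 1000).
#' @param minReciprocalOverlap minimum reciprocal overlap fraction for
#'   intra-chromosomal records (default 0.5).
#' @return A list of class \code{SVComparison}: \code{shared} (data.frame
#'   of matched index pairs with both records' coordinates),
#'   \code{wtSpecific}, \code{mutSpecific}, \code{params}.
#' @export
compareSvStrains <- function(wtRecords, mutRecords, tolerance = 1000L,
                             minReciprocalOverlap = 0.5) {
  wtRecords <- .validateSv(wtRecords, "WT records")
  mutRecords <- .validateSv(mutRecords, "MUT records")
  nW <- nrow(wtRecords); nM <- nrow(mutRecords)
  cand <- NULL
  if (nW && nM) {
    for (i in seq_len(nW)) for (j in seq_len(nM)) {
      d <- .svMatches(wtRecords[i, ], mutRecords[j, ], tolerance,
                      minReciprocalOverlap)
      if (is.finite(d))
        cand <- rbind(cand, data.frame(wt = i, mut = j, dist = d))
    }
  }
  wtMatched <- logical(nW); mutMatched <- logical(nM)
  pairs <- NULL
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), , drop = FALSE]
    for (r in seq_len(nrow(cand))) {
      i <- cand$wt[r]; j <- cand$mut[r]
      if (!wtMatched[i] && !mutMatched[j]) {
        wtMatched[i] <- TRUE; mutMatched[j] <- TRUE
        pairs <- rbind(pairs, data.frame(wtIndex = i, mutIndex = j,
                                         type = wtRecords$type[i],
                                         chrom1 = wtRecords$chrom1[i],
                                         wtPos1 = wtRecords$pos1[i],
                                         mutPos1 = mutRecords$pos1[j],
                                         breakpointDistance = cand$dist[r]))
      }
    }
  }
  structure(list(
    shared = if (is.null(pairs))
      data.frame(wtIndex = integer(), mutIndex = integer()) else pairs,
    wtSpecific = wtRecords[!wtMatched, , drop = FALSE],
    mutSpecific = mutRecords[!mutMatched, , drop = FALSE],
    params = list(tolerance = tolerance,
                  minReciprocalOverlap = minReciprocalOverlap)),
    class = "SVComparison")
}

#' @export
print.SVComparison <- function(x, ...) {
  cat("SV strain comparison: shared", nrow(x$shared), "| WT-specific",
      nrow(x$wtSpecific), "| MUT-specific", nrow(x$mutSpecific), "\n")
  invisible(x)
}

#' Coverage-ratio evidence for a deletion call
#'
#' A hemizygous deletion halves the read depth over the deleted interval,
#' a homozygous deletion removes it. The deletion's mean depth (from the
#' coverage track, over \code{[pos1, pos2)}) is divided by the
#' genome-wide median: ratios at or below 0.1 are supported as homozygous,
#' at or below 0.6 (inclusive) as hemizygous, anything higher is
#' unsupported.
#'
#' @param record one-row SV data.frame of type DEL.
#' @param coverageTrack coverage track of the carrying strain.
#' @param genomeMedian that strain's genome-wide median depth.
#' @param hemizygousMax,homozygousMax ratio thresholds (defaults 0.6, 0.1).
#' @return A list: \code{ratio} and \code{verdict}
#'   (\code{"supported_homozygous"}, \code{"supported_hemizygous"} or
#'   \code{"unsupported"}).
#' @export
deletionCoverageEvidence <- function(record, coverageTrack, genomeMedian,
                                     hemizygousMax = 0.6,
                                     homozygousMax = 0.1) {
  stopifnot(nrow(record) == 1L, record$type == "DEL")
  depth <- meanDepthOver(coverageTrack, record$chrom1, record$pos1 - 1L,
                         record$pos2 - 1L)
  ratio <- depth / genomeMedian
  verdict <- if (is.na(ratio)) "unsupported"
  else if (ratio <= homozygousMax) "supported_homozygous"
  else if (ratio <= hemizygousMax) "supported_hemizygous"
  else "unsupported"
  list(ratio = ratio, verdict = verdict)
}
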
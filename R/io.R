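#' Write a single-sample VCF 4.2
#'
#' Writes variant records as a minimal single-sample VCF (GT and DP in the
#' FORMAT field) with contig header lines. Records are sorted by
#' (chromosome, position).
#'
#' @param records variant data.frame with columns \code{chrom, pos, ref,
#'   alt, qual, genotype, depth} (see \code{\link{readVariants}}).
#' @param path output path.
#' @param sampleName sample column name.
#' @param contigLengths named vector of chromosome lengths for the header
#'   (optional).
#' @return \code{path}, invisibly.
#' @export
writeVcf <- function(records, path, sampleName = "sample",
                     contigLengths = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=crisprStrainScan",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
             con)
  if (!is.null(contigLengths))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
                       as.integer(contigLengths)), con)
  writeLines(paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleName, sep = "\t"), con)
  if (nrow(records)) {
    lev <- if (!is.null(contigLengths)) names(contigLengths) else
      unique(records$chrom)
    records <- records[order(factor(records$chrom, levels = lev),
                             records$pos), , drop = FALSE]
    dp <- ifelse(is.na(records$depth), ".", as.character(records$depth))
    writeLines(paste(records$chrom, records$pos, ".", records$ref,
                     records$alt, format(records$qual, trim = TRUE),
                     "PASS", ".", "GT:DP",
                     paste(records$genotype, dp, sep = ":"), sep = "\t"), con)
  }
  invisible(path)
}

.variantClass <- function(ref, alt)
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "indel")

#' Read a genotyped VCF into variant records
#'
#' Parses a VCF 4.2 with a GT field (DP optional) into a flat record
#' table, splitting multi-allelic rows into one record per (position, alt
#' allele); the genotype of each split record is re-expressed as the
#' dosage of that alternate allele (0/0, 0/1 or 1/1). Records whose GT
#' contains a missing allele get genotype \code{"missing"}; missing DP is
#' reported as \code{NA}.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param sample sample column to read (default: first).
#' @return A data.frame with columns \code{chrom, pos} (1-based),
#'   \code{ref, alt, qual, genotype, depth, class} (\code{"SNP"} or
#'   \code{"indel"}).
#' @export
readVariants <- function(path, sample = NULL) {
  .checkVcfShape(path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) return(.emptyVariants())
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gtMat <- vcfR::extract.gt(v, element = "GT")
  dpMat <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
                    error = function(e) NULL)
  col <- if (is.null(sample)) 1L else sample
  gt <- gtMat[, col]
  dp <- if (is.null(dpMat)) rep(NA_real_, nrow(fix)) else dpMat[, col]

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    alleles <- strsplit(gsub("|", "/", gt[i], fixed = TRUE), "/",
                        fixed = TRUE)[[1L]]
    lapply(seq_along(alts), function(j) {
      geno <- if (anyNA(alleles) || any(alleles == ".") || is.na(gt[i]))
        "missing"
      else c("0/0", "0/1", "1/1")[min(sum(alleles == as.character(j)), 2L) + 1L]
      data.frame(chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
                 ref = fix$REF[i], alt = alts[j],
                 qual = suppressWarnings(as.numeric(fix$QUAL[i])),
                 genotype = geno, depth = as.integer(round(dp[i])))
    })
  })
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  out$class <- .variantClass(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

.emptyVariants <- function()
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), genotype = character(),
             depth = integer(), class = character())

.checkVcfShape <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  if (!length(body)) return(invisible(TRUE))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- body[nf < 10L]
  if (length(bad))
    stop("malformed VCF line ", bad[1L], " in ", path,
         ": expected at least 10 tab-separated fields, found ",
         nf[which(body == bad[1L])])
  pos <- vapply(strsplit(lines[body], "\t", fixed = TRUE), `[`, "", 2L)
  badPos <- body[is.na(suppressWarnings(as.integer(pos)))]
  if (length(badPos))
    stop("malformed VCF line ", badPos[1L], " in ", path,
         ": POS is not an integer")
  invisible(TRUE)
}

#' Coverage track I/O
#'
#' Coverage tracks are BED-like TSVs with columns \code{chrom, start}
#' (0-based), \code{end} (half-open) and \code{meanDepth}. Intervals are
#' window-resolution; the simulator splits windows at the boundaries of
#' depth-changing features.
#'
#' @param track coverage data.frame.
#' @param path file path.
#' @return \code{readCoverage}: the coverage data.frame; \code{writeCoverage}:
#'   \code{path}, invisibly.
#' @export
writeCoverage <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "meanDepth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeCoverage
#' @export
readCoverage <- function(path) {
  read.table(path, sep = "\t", header = TRUE,
             colClasses = c("character", "integer", "integer", "numeric"))
}

#' Mean depth of a coverage track at single positions
#'
#' @param track coverage data.frame.
#' @param chrom chromosome name(s), recycled against \code{pos}.
#' @param pos 1-based position(s).
#' @return Numeric vector of interval mean depths (\code{NA} where no
#'   interval covers the position).
#' @export
depthAt <- function(track, chrom, pos) {
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  out <- rep(NA_real_, n)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (!nrow(tr)) next
    p0 <- pos[sel] - 1L  # 0-based
    idx <- findInterval(p0, tr$start)
    ok <- idx >= 1L & p0 < tr$end[pmax(idx, 1L)]
    res <- rep(NA_real_, sum(sel))
    res[ok] <- tr$meanDepth[idx[ok]]
    out[sel] <- res
  }
  out
}

#' Length-weighted mean depth over a region
#'
#' @param track coverage data.frame.
#' @param chrom chromosome name.
#' @param start,end region, 0-based half-open.
#' @return Mean depth over the overlapped portion of the track, or
#'   \code{NA} if nothing overlaps.
#' @export
meanDepthOver <- function(track, chrom, start, end) {
  tr <- track[track$chrom == chrom & track$end > start & track$start < end, ,
              drop = FALSE]
  if (!nrow(tr)) return(NA_real_)
  w <- pmin(tr$end, end) - pmax(tr$start, start)
  sum(tr$meanDepth * w) / sum(w)
}

#' Genome-wide median depth of a coverage track
#'
#' Median of interval mean depths weighted by interval length.
#'
#' @param track coverage data.frame.
#' @return Median depth.
#' @export
medianDepth <- function(track) {
  if (!nrow(track)) return(NA_real_)
  w <- track$end - track$start
  ord <- order(track$meanDepth)
  cw <- cumsum(w[ord])
  track$meanDepth[ord][which(cw >= sum(w) / 2)[1L]]
}

#' Truth table I/O
#'
#' The simulator's ground truth is serialized as JSON: per-strain planted
#' variant tables, expected shared/WT-only/MUT-only keys, LOH tracts,
#' off-target sites, SV records and target-edit coordinates.
#'
#' @param truth truth list from \code{\link{simulateStrainPair}}.
#' @param path file path.
#' @return \code{readTruth}: the truth list; \code{writeTruth}:
#'   \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  truth <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in intersect(c("wtVariants", "mutVariants", "lohTracts",
                         "offtargetSites", "svs"), names(truth)))
    truth[[nm]] <- as.data.frame(truth[[nm]])
  truth
}
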
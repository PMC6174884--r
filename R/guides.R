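#' GC content of a DNA sequence
#'
#' @param sequence DNA string, ACGT only (case-insensitive).
#' @return Percentage of G+C bases, in \code{[0, 100]}.
#' @examples
#' gcContent("ATACTATGCTTGGATGGCGG")  # 50
#' @export
gcContent <- function(sequence) {
  if (is(sequence, "DNAString")) sequence <- as.character(sequence)
  sequence <- toupper(sequence)
  if (length(sequence) != 1L || !.validDNA(sequence))
    stop("sequence must be a single non-empty ACGT string")
  chars <- strsplit(sequence, "")[[1L]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

.pamRegex <- function(pattern) {
  paste0("^", paste(.IUPAC_REGEX[strsplit(pattern, "")[[1L]]], collapse = ""),
         "$")
}

.checkGenome <- function(genome) {
  if (is.character(genome)) {
    genome <- toupper(genome)
    if (any(grepl("[^ACGTN]", genome)))
      stop("genome contains characters outside ACGTN")
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!is(genome, "DNAStringSet"))
    stop("genome must be a DNAStringSet or named character vector")
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome sequences must carry unique names")
  freq <- Biostrings::alphabetFrequency(genome)
  used <- colSums(freq) > 0
  if (any(used & !colnames(freq) %in% c("A", "C", "G", "T", "N")))
    stop("genome contains characters outside ACGTN")
  genome
}

.mismatchCounts <- function(siteSeqs, protospacer, seedLength) {
  # per-site total and seed (3'-proximal) Hamming mismatches vs protospacer
  guideChars <- strsplit(protospacer, "")[[1L]]
  m <- do.call(rbind, strsplit(siteSeqs, ""))
  diff <- m != matrix(guideChars, nrow(m), 20L, byrow = TRUE)
  seedCols <- (20L - seedLength + 1L):20L
  list(total = as.integer(rowSums(diff)),
       seed = as.integer(rowSums(diff[, seedCols, drop = FALSE])))
}

#' Exhaustive PAM-constrained off-target search
#'
#' Scans both strands of a genome for every 20-nt window within
#' \code{maxMismatches} Hamming mismatches of the protospacer whose
#' adjacent 3 nt 3' of the protospacer match the PAM pattern. The scan is
#' exhaustive: its result is defined to equal a naive position-by-position
#' comparison. Windows containing N are skipped.
#'
#' @param genome \code{DNAStringSet} (or named character vector) of
#'   chromosome sequences.
#' @param guide a \linkS4class{GuideRNA}.
#' @param maxMismatches maximum protospacer mismatches, in \code{[0, 20]}.
#' @return A \code{GRanges}, sorted by (chromosome, start, strand), one
#'   range per site covering the 20-nt protospacer-aligned window on the
#'   plus reference strand, with metadata columns \code{siteSeq} (read in
#'   protospacer orientation), \code{pamSeq}, \code{mismatches} and
#'   \code{seedMismatches}.
#' @seealso \code{\link{scoreGuide}}
#' @export
findOffTargets <- function(genome, guide, maxMismatches = 4L) {
  stopifnot(is(guide, "GuideRNA"))
  maxMismatches <- as.integer(maxMismatches)
  if (maxMismatches < 0L || maxMismatches > 20L)
    stop("maxMismatches must lie in [0, 20]")
  genome <- .checkGenome(genome)
  pamRe <- .pamRegex(guide@pamPattern)
  proto <- Biostrings::DNAString(guide@protospacer)
  protoRC <- Biostrings::reverseComplement(proto)

  hits <- list()
  for (chromName in names(genome)) {
    chrom <- genome[[chromName]]
    L <- length(chrom)
    if (L < 23L) next
    chromStr <- as.character(chrom)

    # plus strand: protospacer window [s, s+19], PAM [s+20, s+22]
    fw <- Biostrings::matchPattern(proto, chrom, max.mismatch = maxMismatches)
    s <- BiocGenerics::start(fw)
    s <- s[s >= 1L & s + 22L <= L]
    if (length(s)) {
      pam <- substring(chromStr, s + 20L, s + 22L)
      keep <- grepl(pamRe, pam)
      s <- s[keep]; pam <- pam[keep]
      if (length(s)) {
        site <- substring(chromStr, s, s + 19L)
        ok <- !grepl("N", site, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
        s <- s[ok]; pam <- pam[ok]; site <- site[ok]
      }
      if (length(s)) {
        mm <- .mismatchCounts(site, guide@protospacer, guide@seedLength)
        keep <- mm$total <= maxMismatches
        if (any(keep))
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chromName, start = s[keep], strand = "+",
            siteSeq = site[keep], pamSeq = pam[keep],
            mismatches = mm$total[keep], seedMismatches = mm$seed[keep])
      }
    }

    # minus strand: revcomp(protospacer) window at [s, s+19] on plus,
    # PAM is revcomp of plus-strand [s-3, s-1]
    rv <- Biostrings::matchPattern(protoRC, chrom, max.mismatch = maxMismatches)
    s <- BiocGenerics::start(rv)
    s <- s[s >= 4L & s + 19L <= L]
    if (length(s)) {
      pamPlus <- substring(chromStr, s - 3L, s - 1L)
      pam <- .revcompChar(pamPlus)
      keep <- grepl(pamRe, pam)
      s <- s[keep]; pam <- pam[keep]
      if (length(s)) {
        sitePlus <- substring(chromStr, s, s + 19L)
        site <- .revcompChar(sitePlus)
        ok <- !grepl("N", site, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
        s <- s[ok]; pam <- pam[ok]; site <- site[ok]
      }
      if (length(s)) {
        mm <- .mismatchCounts(site, guide@protospacer, guide@seedLength)
        keep <- mm$total <= maxMismatches
        if (any(keep))
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chromName, start = s[keep], strand = "-",
            siteSeq = site[keep], pamSeq = pam[keep],
            mismatches = mm$total[keep], seedMismatches = mm$seed[keep])
      }
    }
  }

  df <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), strand = character(),
               siteSeq = character(), pamSeq = character(),
               mismatches = integer(), seedMismatches = integer())
  ord <- order(factor(df$chrom, levels = names(genome)), df$start, df$strand)
  df <- df[ord, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = names(genome)),
    ranges = IRanges::IRanges(start = df$start, width = 20L),
    strand = df$strand)
  GenomeInfoDb::seqlengths(gr) <- lengths(genome)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    siteSeq = df$siteSeq, pamSeq = df$pamSeq,
    mismatches = df$mismatches, seedMismatches = df$seedMismatches)
  gr
}

.revcompChar <- function(x) {
  if (!length(x)) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Aggregate guide design report
#'
#' Runs \code{\link{findOffTargets}} and summarises the result into a
#' design report: off-target counts per mismatch level (excluding one
#' designated on-target site -- the first 0-mismatch hit), the number of
#' chromosomes carrying off-targets, the number of off-targets with a
#' perfect seed, and the GC rule verdict (GC content above 70\% is
#' associated with increased off-target activity).
#'
#' @inheritParams findOffTargets
#' @param gcRuleMax GC percentage above which the guide fails the GC rule
#'   (default 70).
#' @return A list of class \code{DesignReport}: \code{gcPercent},
#'   \code{gcRulePass}, \code{nOfftargetsByMismatch} (named vector over
#'   0..maxMismatches), \code{nChromosomesHit}, \code{nSeedPerfectOfftargets},
#'   \code{onTargetFound}, and the site table (\code{sites}).
#' @export
scoreGuide <- function(genome, guide, maxMismatches = 4L, gcRuleMax = 70) {
  sites <- findOffTargets(genome, guide, maxMismatches)
  gc <- gcContent(guide@protospacer)
  onIdx <- which(sites$mismatches == 0L)
  onTargetFound <- length(onIdx) > 0L
  if (!onTargetFound)
    warning("no 0-mismatch on-target site found in genome; ",
            "all sites counted as off-targets")
  off <- if (onTargetFound) sites[-onIdx[1L]] else sites
  byMm <- setNames(integer(maxMismatches + 1L), 0:maxMismatches)
  if (length(off)) {
    tab <- table(off$mismatches)
    byMm[names(tab)] <- as.integer(tab)
  }
  structure(list(
    gcPercent = gc,
    gcRulePass = gc <= gcRuleMax,
    nOfftargetsByMismatch = byMm,
    nChromosomesHit = length(unique(as.character(
      GenomeInfoDb::seqnames(off)))),
    nSeedPerfectOfftargets = sum(off$seedMismatches == 0L),
    onTargetFound = onTargetFound,
    sites = sites), class = "DesignReport")
}

#' @export
print.DesignReport <- function(x, ...) {
  cat("Guide design report\n")
  cat("  GC%:", format(x$gcPercent, digits = 4),
      if (x$gcRulePass) "(passes <=70% rule)" else "(FAILS <=70% rule)", "\n")
  cat("  on-target found:", x$onTargetFound, "\n")
  cat("  off-targets by mismatch count:\n")
  print(x$nOfftargetsByMismatch)
  cat("  chromosomes hit:", x$nChromosomesHit,
      "| seed-perfect off-targets:", x$nSeedPerfectOfftargets, "\n")
  invisible(x)
}

#' Write off-target sites as BED6+
#'
#' Columns: chrom, start (0-based), end, name (site sequence), score
#' (mismatches), strand, seedMismatches, pam.
#'
#' @param sites \code{GRanges} from \code{\link{findOffTargets}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeOffTargetBed <- function(sites, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(sites)),
    start = BiocGenerics::start(sites) - 1L,
    end = BiocGenerics::end(sites),
    name = sites$siteSeq,
    score = sites$mismatches,
    strand = as.character(BiocGenerics::strand(sites)),
    seedMismatches = sites$seedMismatches,
    pam = sites$pamSeq)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read off-target sites from BED6+
#'
#' Inverse of \code{\link{writeOffTargetBed}}.
#'
#' @param path BED6+ file written by \code{\link{writeOffTargetBed}}.
#' @return A \code{GRanges} with the same metadata columns as
#'   \code{\link{findOffTargets}}.
#' @export
readOffTargetBed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand", "seedMismatches", "pam"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "integer", "character",
                                  "integer", "character"))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    siteSeq = df$name, pamSeq = df$pam, mismatches = df$score,
    seedMismatches = df$seedMismatches)
  gr
}
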
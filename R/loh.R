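#' Windowed heterozygosity counts
#'
#' Tiles each chromosome with half-open windows of \code{windowSize} (the
#' last window is truncated at the chromosome end) and counts, per window,
#' heterozygous (0/1) and homozygous (1/1 or 0/0) genotyped variants.
#' Variants with missing genotypes are excluded. Two heterozygosity
#' definitions are reported: \code{hzOfVariants}, the percentage of
#' heterozygous calls among genotyped variants in the window (\code{NA}
#' when the window has none), and \code{hzPerBp}, heterozygous sites per
#' window length as a percentage (always defined).
#'
#' @param variants variant data.frame (1-based positions).
#' @param genomeLengths named vector of chromosome lengths.
#' @param windowSize window size in bp (default 50000).
#' @return A data.frame: \code{chrom, start, end} (0-based half-open),
#'   \code{nHet, nHom, hzOfVariants, hzPerBp}.
#' @export
windowCounts <- function(variants, genomeLengths, windowSize = 50000L) {
  windowSize <- as.integer(windowSize)
  stopifnot(windowSize > 0L, !is.null(names(genomeLengths)))
  grid <- do.call(rbind, lapply(names(genomeLengths), function(ch) {
    len <- as.integer(genomeLengths[[ch]])
    start <- seq(0L, len - 1L, by = windowSize)
    data.frame(chrom = ch, start = start, end = pmin(start + windowSize, len))
  }))
  grid$nHet <- 0L; grid$nHom <- 0L

  v <- variants[variants$genotype %in% c("0/1", "0/0", "1/1"), , drop = FALSE]
  if (nrow(v)) {
    bad <- !(v$chrom %in% names(genomeLengths)) |
      v$pos > genomeLengths[v$chrom] | v$pos < 1L
    if (any(bad))
      stop("variant outside chromosome bounds: ",
           v$chrom[bad][1L], ":", v$pos[bad][1L])
    widx <- (v$pos - 1L) %/% windowSize  # 0-based window index
    key <- paste(v$chrom, widx)
    gkey <- paste(grid$chrom, grid$start %/% windowSize)
    het <- table(key[v$genotype == "0/1"])
    hom <- table(key[v$genotype != "0/1"])
    grid$nHet[match(names(het), gkey)] <- as.integer(het)
    grid$nHom[match(names(hom), gkey)] <- as.integer(hom)
  }
  n <- grid$nHet + grid$nHom
  grid$hzOfVariants <- ifelse(n > 0L, 100 * grid$nHet / n, NA_real_)
  grid$hzPerBp <- 100 * grid$nHet / (grid$end - grid$start)
  grid
}

#' Loess-smooth a windowed heterozygosity profile
#'
#' Per-chromosome local linear regression (tricube weights, degree 1) of
#' the chosen heterozygosity value on window midpoints, for display
#' alongside the raw profile. Windows with undefined values are excluded
#' from the fit and interpolated from it. Chromosomes with fewer than 3
#' defined windows are returned unsmoothed with a warning. Smoothing is
#' cosmetic: segment calling never consumes it.
#'
#' @param stats data.frame from \code{\link{windowCounts}}.
#' @param span loess span as a fraction of windows (default 0.3).
#' @param value column to smooth: \code{"hzOfVariants"} (default) or
#'   \code{"hzPerBp"}.
#' @return \code{stats} with an added \code{smoothed} column.
#' @export
smoothProfile <- function(stats, span = 0.3, value = "hzOfVariants") {
  stopifnot(value %in% names(stats))
  stats$smoothed <- NA_real_
  for (ch in unique(stats$chrom)) {
    sel <- which(stats$chrom == ch)
    x <- (stats$start[sel] + stats$end[sel]) / 2
    y <- stats[[value]][sel]
    def <- !is.na(y)
    if (sum(def) < 3L) {
      warning("chromosome ", ch, " has fewer than 3 defined windows; ",
              "returned unsmoothed")
      stats$smoothed[sel] <- y
      next
    }
    # loess needs enough local points: widen tiny spans on short profiles
    spanUse <- max(span, min(1, 4 / sum(def)))
    fit <- loess(y[def] ~ x[def], span = spanUse, degree = 1,
                 family = "gaussian",
                 control = loess.control(surface = "direct"))
    stats$smoothed[sel] <- predict(fit, newdata = x)
  }
  stats
}

#' Heterozygosity of a region and its chromosome
#'
#' Heterozygous sites over region length, as a percentage -- the per-bp
#' definition used for regional LOH summaries.
#'
#' @param variants variant data.frame.
#' @param chromosome chromosome name.
#' @param start,end region bounds, 0-based half-open.
#' @param chromosomeLength chromosome length; when supplied the
#'   chromosome-wide value is computed over it, otherwise over the span of
#'   observed variants.
#' @return A list: \code{region} and \code{chromosome} (percentages),
#'   \code{nHetRegion}.
#' @export
regionHeterozygosity <- function(variants, chromosome, start, end,
                                 chromosomeLength = NULL) {
  if (end <= start) stop("end must exceed start")
  v <- variants[variants$chrom == chromosome & variants$genotype == "0/1", ,
                drop = FALSE]
  inRegion <- sum(v$pos - 1L >= start & v$pos - 1L < end)
  chrLen <- if (is.null(chromosomeLength)) {
    if (nrow(v)) max(v$pos) else end
  } else chromosomeLength
  list(region = 100 * inRegion / (end - start),
       chromosome = 100 * nrow(v) / chrLen,
       nHetRegion = inRegion)
}

# informative-site discordance for one affected strain: sites het in the
# other strain, marked discordant where the affected strain is not het
.discordance <- function(affected, other, chrom) {
  inf <- other[other$chrom == chrom & other$genotype == "0/1", , drop = FALSE]
  if (!nrow(inf)) return(NULL)
  inf <- inf[order(inf$pos), , drop = FALSE]
  affHet <- variantKey(affected[affected$genotype == "0/1", , drop = FALSE])
  data.frame(pos = inf$pos, discordant = !(variantKey(inf) %in% affHet))
}

# Gap-tolerant runs of discordant sites: a run extends while the next
# discordant site is separated by <= maxGap concordant sites. For each
# run three nested intervals (0-based half-open) are reported: inner
# spans the outermost discordant sites; outer extends to (but excludes)
# the flanking concordant informative sites, the maximal interval
# consistent with LOH; mid takes the midpoint of each flanking gap --
# the breakpoint is equally likely anywhere in it -- and is the reported
# boundary estimate.
.discordantRuns <- function(disc, maxGap, chromLength) {
  dIdx <- which(disc$discordant)
  if (!length(dIdx)) return(NULL)
  runStart <- dIdx[1L]; runEnd <- dIdx[1L]; n <- 1L
  runs <- list()
  for (i in dIdx[-1L]) {
    if (i - runEnd - 1L <= maxGap) {
      runEnd <- i; n <- n + 1L
    } else {
      runs[[length(runs) + 1L]] <- c(runStart, runEnd, n)
      runStart <- i; runEnd <- i; n <- 1L
    }
  }
  runs[[length(runs) + 1L]] <- c(runStart, runEnd, n)
  first <- vapply(runs, `[`, 0, 1L); last <- vapply(runs, `[`, 0, 2L)
  innerStart <- disc$pos[first] - 1L
  innerEnd <- disc$pos[last]
  # flanking concordant informative sites (0-based positions)
  outerStart <- rep(0L, length(first))
  hasPrev <- first > 1L
  outerStart[hasPrev] <- disc$pos[first[hasPrev] - 1L]
  outerEnd <- rep(as.integer(chromLength), length(last))
  hasNext <- last < nrow(disc)
  outerEnd[hasNext] <- disc$pos[last[hasNext] + 1L] - 1L
  data.frame(innerStart = innerStart, innerEnd = innerEnd,
             midStart = floor((innerStart + outerStart) / 2),
             midEnd = ceiling((innerEnd + outerEnd) / 2),
             outerStart = outerStart, outerEnd = outerEnd,
             nDiscordant = vapply(runs, `[`, 0, 3L))
}

# cluster candidate intervals whose mid bounds lie within `gap`, taking
# the union of each interval flavour per cluster
.clusterCandidates <- function(cand, gap) {
  cand <- cand[order(cand$midStart), , drop = FALSE]
  cl <- integer(nrow(cand)); cur <- 1L; cl[1L] <- 1L
  hi <- cand$midEnd[1L]
  for (i in seq_len(nrow(cand))[-1L]) {
    if (cand$midStart[i] > hi + gap) cur <- cur + 1L
    cl[i] <- cur
    hi <- max(hi, cand$midEnd[i])
  }
  do.call(rbind, lapply(split(cand, cl), function(g)
    data.frame(midStart = min(g$midStart), midEnd = max(g$midEnd),
               outerStart = min(g$outerStart), outerEnd = max(g$outerEnd),
               nDiscordant = sum(g$nDiscordant))))
}

.mergeIntervals <- function(start, end, gap) {
  ord <- order(start)
  start <- start[ord]; end <- end[ord]
  outS <- start[1L]; outE <- end[1L]
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= outE[length(outE)] + gap) {
      outE[length(outE)] <- max(outE[length(outE)], end[i])
    } else {
      outS <- c(outS, start[i]); outE <- c(outE, end[i])
    }
  }
  data.frame(start = outS, end = outE)
}

#' Call differential LOH segments between two strains
#'
#' Candidate regions come from two detectors, run for each direction
#' (affected strain MUT, then WT): (i) window flagging -- windows where the
#' affected strain's per-bp heterozygosity is at most
#' \code{affectedMaxHz} while the other strain's is at least
#' \code{otherMinHz}, merged across runs tolerating up to
#' \code{maxGapWindows} unflagged windows; and (ii) variant-level
#' discordant runs -- maximal runs of informative sites (heterozygous in
#' the unaffected strain) at which the affected strain is homozygous or
#' absent, tolerating up to \code{maxConcordantGap} intervening concordant
#' sites, with at least \code{minDiscordantSites} discordant sites. Window
#' candidates are refined to their overlapping discordant runs. A run's
#' reported boundaries are the midpoints between its outermost discordant
#' sites and the flanking concordant informative sites: the breakpoint is
#' equally likely anywhere in that gap, so the midpoint is the unbiased
#' estimate. The union of candidates is merged (\code{mergeGap}); a
#' candidate is kept when its maximal consistent extent -- reaching up to,
#' but excluding, the flanking concordant sites -- is at least
#' \code{minSegmentLength} (end - start) and the per-bp heterozygosity
#' contrast over the refined interval still satisfies the thresholds. The
#' variant-level pass is what resolves tracts smaller than one window.
#'
#' @param wtStats,mutStats window tables from \code{\link{windowCounts}}
#'   on the identical grid.
#' @param wtVariants,mutVariants the genotyped variant data.frames the
#'   window tables were computed from.
#' @param config an \linkS4class{LOHConfig}.
#' @param wtCoverage,mutCoverage optional coverage tracks; when supplied,
#'   each segment's mechanism is classified with
#'   \code{\link{classifyMechanism}}.
#' @return A \code{GRanges} (1-based ranges over the segment's 0-based
#'   half-open interval) with metadata columns \code{affectedStrain},
#'   \code{hzAffected}, \code{hzOther}, \code{nDiscordant},
#'   \code{mechanism}, \code{coverageRatio}.
#' @export
callLohSegments <- function(wtStats, mutStats, wtVariants, mutVariants,
                            config = lohConfig(),
                            wtCoverage = NULL, mutCoverage = NULL) {
  stopifnot(is(config, "LOHConfig"))
  if (!identical(wtStats[, c("chrom", "start", "end")],
                 mutStats[, c("chrom", "start", "end")]))
    stop("window grids of the two strains differ")

  segs <- list()
  for (affectedStrain in c("MUT", "WT")) {
    affStats <- if (affectedStrain == "MUT") mutStats else wtStats
    othStats <- if (affectedStrain == "MUT") wtStats else mutStats
    affVar <- if (affectedStrain == "MUT") mutVariants else wtVariants
    othVar <- if (affectedStrain == "MUT") wtVariants else mutVariants
    affCov <- if (affectedStrain == "MUT") mutCoverage else wtCoverage

    for (ch in unique(wtStats$chrom)) {
      sel <- wtStats$chrom == ch
      aff <- affStats[sel, , drop = FALSE]
      oth <- othStats[sel, , drop = FALSE]
      disc <- .discordance(affVar, othVar, ch)

      # variant-level candidate runs
      chromLength <- max(aff$end)
      runs <- if (!is.null(disc))
        .discordantRuns(disc, config@maxConcordantGap, chromLength) else NULL
      cand <- NULL
      if (!is.null(runs))
        cand <- runs[runs$nDiscordant >= config@minDiscordantSites, ,
                     drop = FALSE]

      # window-level candidates, refined to overlapping discordant runs
      flagged <- aff$hzPerBp <= config@affectedMaxHz &
        oth$hzPerBp >= config@otherMinHz
      if (any(flagged)) {
        merged <- .mergeIntervals(aff$start[flagged], aff$end[flagged],
                                  gap = config@maxGapWindows *
                                    config@windowSize + 1L)
        if (!is.null(runs)) {
          for (i in seq_len(nrow(merged))) {
            ov <- runs$innerEnd > merged$start[i] &
              runs$innerStart < merged$end[i]
            if (any(ov))
              cand <- rbind(cand, runs[ov, , drop = FALSE])
          }
        }
      }
      if (is.null(cand) || !nrow(cand)) next
      cand <- .clusterCandidates(cand, gap = config@mergeGap)

      for (i in seq_len(nrow(cand))) {
        s0 <- cand$midStart[i]; e0 <- cand$midEnd[i]
        # a candidate is discarded only when even its maximal consistent
        # extent falls short of the minimum segment length
        if (cand$outerEnd[i] - cand$outerStart[i] < config@minSegmentLength)
          next
        hzAff <- regionHeterozygosity(affVar, ch, s0, e0)$region
        hzOth <- regionHeterozygosity(othVar, ch, s0, e0)$region
        if (hzAff > config@affectedMaxHz || hzOth < config@otherMinHz) next
        nDisc <- sum(disc$discordant & disc$pos - 1L >= s0 & disc$pos <= e0)
        mech <- NA_character_; ratio <- NA_real_
        if (!is.null(affCov)) {
          cls <- classifyMechanism(ch, s0, e0, affCov,
                                   medianDepth(affCov), config)
          mech <- cls$mechanism; ratio <- cls$coverageRatio
        }
        segs[[length(segs) + 1L]] <- data.frame(
          chrom = ch, start = s0, end = e0, affectedStrain = affectedStrain,
          hzAffected = hzAff, hzOther = hzOth, nDiscordant = nDisc,
          mechanism = mech, coverageRatio = ratio)
      }
    }
  }

  df <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               affectedStrain = character(), hzAffected = numeric(),
               hzOther = numeric(), nDiscordant = integer(),
               mechanism = character(), coverageRatio = numeric())
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(start = df$start + 1L,
                                                end = pmax(df$end,
                                                           df$start + 1L)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    affectedStrain = df$affectedStrain, hzAffected = df$hzAffected,
    hzOther = df$hzOther, nDiscordant = df$nDiscordant,
    mechanism = df$mechanism, coverageRatio = df$coverageRatio)
  sort(gr, ignore.strand = TRUE)
}

#' Classify an LOH segment as deletion or gene conversion
#'
#' Hemizygous deletion halves the mapped read depth over the lost region,
#' while gene conversion leaves it unchanged. The segment's mean depth in
#' the affected strain is divided by that strain's genome-wide median
#' depth: a ratio at or below \code{deletionRatioMax} is a deletion, a
#' ratio inside \code{conversionRatioRange} is gene conversion, anything
#' else (or missing coverage) is ambiguous.
#'
#' @param chrom chromosome name.
#' @param start,end segment bounds, 0-based half-open.
#' @param affectedCoverage coverage track of the affected strain.
#' @param genomeMedianCoverage that strain's genome-wide median depth
#'   (see \code{\link{medianDepth}}).
#' @param config an \linkS4class{LOHConfig}.
#' @return A list: \code{mechanism} (\code{"deletion"},
#'   \code{"gene_conversion"} or \code{"ambiguous"}) and
#'   \code{coverageRatio}.
#' @export
classifyMechanism <- function(chrom, start, end, affectedCoverage,
                              genomeMedianCoverage, config = lohConfig()) {
  stopifnot(is(config, "LOHConfig"))
  depth <- meanDepthOver(affectedCoverage, chrom, start, end)
  if (is.na(depth) || is.na(genomeMedianCoverage) ||
      genomeMedianCoverage <= 0) {
    warning("no coverage overlapping segment ", chrom, ":", start, "-", end)
    return(list(mechanism = "ambiguous", coverageRatio = NA_real_))
  }
  ratio <- depth / genomeMedianCoverage
  mech <- if (ratio <= config@deletionRatioMax) "deletion"
  else if (ratio >= config@conversionRatioRange[1L] &&
           ratio <= config@conversionRatioRange[2L]) "gene_conversion"
  else "ambiguous"
  list(mechanism = mech, coverageRatio = ratio)
}

#' Write LOH segments as BED6+
#'
#' Columns: chrom, start (0-based), end, name
#' (affectedStrain:mechanism), score (discordant sites), strand (.),
#' hzAffected, hzOther, coverageRatio.
#'
#' @param segments \code{GRanges} from \code{\link{callLohSegments}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLohBed <- function(segments, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(segments)),
    start = BiocGenerics::start(segments) - 1L,
    end = BiocGenerics::end(segments),
    name = paste(segments$affectedStrain, segments$mechanism, sep = ":"),
    score = segments$nDiscordant,
    strand = rep(".", length(segments)),
    hzAffected = signif(segments$hzAffected, 4),
    hzOther = signif(segments$hzOther, 4),
    coverageRatio = signif(segments$coverageRatio, 4))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
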
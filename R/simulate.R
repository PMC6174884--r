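.BASES <- c("A", "C", "G", "T")

.randomSeq <- function(len) paste(sample(.BASES, len, replace = TRUE),
                                  collapse = "")

.concretePam <- function(pattern) {
  chars <- strsplit(pattern, "")[[1L]]
  paste(vapply(chars, function(ch) {
    allowed <- strsplit(gsub("\\[|\\]", "", .IUPAC_REGEX[[ch]]), "")[[1L]]
    if (length(allowed) == 1L) allowed else sample(allowed, 1L)
  }, character(1L)), collapse = "")
}

.mutateSeq <- function(seq, positions) {
  chars <- strsplit(seq, "")[[1L]]
  for (p in positions) chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
  paste(chars, collapse = "")
}

`substrAssign<-` <- function(x, start, value) {
  substr(x, start, start + nchar(value) - 1L) <- value
  x
}

#' Simulate a reference genome with a planted target and off-target decoys
#'
#' Generates \code{nChromosomes} uniform-composition random chromosomes of
#' the configured length, plants the protospacer + concrete PAM once at a
#' recorded locus, and plants each requested off-target decoy with exactly
#' its specified total and seed mismatch counts (PAM intact). After
#' planting, the genome is scanned with \code{\link{findOffTargets}} and
#' re-drawn if the random background created any additional site at or
#' below the largest decoy mismatch count, so the planted sites are the
#' only matches.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param maxAttempts genome re-draws allowed before giving up when the
#'   background keeps producing accidental near-matches (default 20).
#' @return A named \code{DNAStringSet} (chr1, chr2, ...). Its
#'   \code{S4Vectors::metadata} carries \code{target} (planted locus
#'   coordinates) and \code{decoySites} (data.frame with \code{chrom,
#'   start} (0-based), \code{strand, mismatches, seedMismatches}).
#' @export
simulateReference <- function(config, maxAttempts = 20L) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@rngSeed)
  spec <- config@targetSpec
  decoys <- config@offtargetDecoys
  if (nrow(decoys) && is.null(spec))
    stop("off-target decoys require a targetSpec protospacer")

  chromNames <- paste0("chr", seq_len(config@nChromosomes))
  len <- config@chromosomeLength

  for (attempt in seq_len(maxAttempts)) {
    seqs <- setNames(vapply(chromNames, function(ch) .randomSeq(len),
                            character(1L)), chromNames)
    target <- NULL
    decoySites <- data.frame(chrom = character(), start = integer(),
                             strand = character(), mismatches = integer(),
                             seedMismatches = integer())
    if (!is.null(spec)) {
      if (!spec@chromosome %in% chromNames)
        stop("targetSpec chromosome not in simulated genome")
      # plant protospacer+PAM near mid-chromosome (0-based start t0)
      t0 <- floor(runif(1L, 0.3 * len, 0.7 * len - 23L))
      pamConcrete <- .concretePam(spec@pam)
      seqs[spec@chromosome] <- `substrAssign<-`(
        seqs[[spec@chromosome]], t0 + 1L,
        paste0(spec@protospacer, pamConcrete))
      pamStart1 <- t0 + 21L  # 1-based first PAM base
      smallDelPos <- pamStart1 + spec@smallDeletionOffset  # 1-based deleted base
      largeDelStart <- smallDelPos - 12L
      target <- list(chrom = spec@chromosome, protoStart0 = as.integer(t0),
                     pamStart0 = as.integer(t0 + 20L), strand = "+",
                     smallDeletionPos = as.integer(smallDelPos),
                     smallDeletionVcfPos = as.integer(smallDelPos - 1L),
                     largeDeletionStart = as.integer(largeDelStart),
                     largeDeletionEnd = as.integer(largeDelStart +
                                                   spec@largeDeletionLength),
                     largeDeletionLength = spec@largeDeletionLength)

      occupied <- list(c(spec@chromosome, t0 - 30L, t0 + 53L))
      if (nrow(decoys)) {
        seed12 <- 12L
        for (i in seq_len(nrow(decoys))) {
          m <- decoys$mismatches[i]
          s <- if ("seedMismatches" %in% names(decoys))
            decoys$seedMismatches[i] else 0L
          if (s > m || m > 20L)
            stop("decoy spec ", i, ": need seedMismatches <= mismatches <= 20")
          for (k in seq_len(decoys$copies[i])) {
            seedPos <- sample((20L - seed12 + 1L):20L, s)
            nonSeedPos <- sample(seq_len(20L - seed12), m - s)
            dSeq <- .mutateSeq(spec@protospacer, c(seedPos, nonSeedPos))
            repeat {
              ch <- sample(chromNames, 1L)
              d0 <- floor(runif(1L, 100L, len - 130L))
              clash <- any(vapply(occupied, function(o)
                o[1L] == ch & d0 < as.numeric(o[3L]) &
                  d0 + 23L > as.numeric(o[2L]), logical(1L)))
              if (!clash) break
            }
            seqs[ch] <- `substrAssign<-`(seqs[[ch]], d0 + 1L,
                                         paste0(dSeq, .concretePam(spec@pam)))
            occupied[[length(occupied) + 1L]] <- c(ch, d0 - 30L, d0 + 53L)
            decoySites <- rbind(decoySites, data.frame(
              chrom = ch, start = as.integer(d0), strand = "+",
              mismatches = as.integer(m), seedMismatches = as.integer(s)))
          }
        }
      }
    }

    genome <- Biostrings::DNAStringSet(seqs)
    if (is.null(spec)) {
      S4Vectors::metadata(genome) <- list(target = NULL,
                                          decoySites = decoySites)
      return(genome)
    }

    # verify: planted sites are the only matches up to the decoy level
    verifyMm <- max(c(2L, decoySites$mismatches))
    guide <- guideRNA(spec@protospacer, spec@pam)
    found <- findOffTargets(genome, guide, verifyMm)
    expected <- rbind(
      data.frame(chrom = target$chrom, start = target$protoStart0,
                 strand = "+", mismatches = 0L),
      decoySites[decoySites$mismatches <= verifyMm,
                 c("chrom", "start", "strand", "mismatches")])
    foundKey <- sort(paste(as.character(GenomeInfoDb::seqnames(found)),
                           BiocGenerics::start(found) - 1L,
                           as.character(BiocGenerics::strand(found)),
                           found$mismatches))
    expKey <- sort(paste(expected$chrom, expected$start, expected$strand,
                         expected$mismatches))
    if (identical(foundKey, expKey)) {
      S4Vectors::metadata(genome) <- list(target = target,
                                          decoySites = decoySites)
      return(genome)
    }
  }
  stop("could not place decoys without accidental near-matches after ",
       maxAttempts, " attempts; enlarge the genome or lower mismatch counts")
}

.drawPositions <- function(len, density) {
  if (density <= 0) return(integer())
  which(runif(len) < density)  # 1-based positions
}

.newVariants <- function(n = 0L)
  data.frame(chrom = character(n), pos = integer(n), ref = character(n),
             alt = character(n), qual = numeric(n), genotype = character(n),
             depth = integer(n), class = character(n))

.altBase <- function(refs)
  vapply(refs, function(r) sample(setdiff(.BASES, r), 1L), character(1L),
         USE.NAMES = FALSE)

#' Simulate a wild-type/mutant strain pair
#'
#' Draws a shared heterozygous SNP background at the configured density
#' (genotype 0/1 in both strains), independent strain-specific small
#' variants (81\% SNPs, 19\% 1-bp indels), applies the planted LOH tracts
#' (inside a tract the affected strain's shared sites become homozygous,
#' except for a residual fraction that stays heterozygous), plants the
#' biallelic target edit in the mutant only (a 1-bp deletion VCF record on
#' one allele and a large-deletion SV record on the other), and emits
#' per-strain window coverage tracks -- Poisson around the configured mean,
#' halved across hemizygous deletions -- plus SV tables and a truth table.
#'
#' @param genome reference from \code{\link{simulateReference}} (its
#'   metadata supplies the planted target coordinates).
#' @param config the same \linkS4class{SimulationConfig}.
#' @return A list: \code{wtVariants}, \code{mutVariants} (record
#'   data.frames as in \code{\link{readVariants}}), \code{wtCoverage},
#'   \code{mutCoverage} (coverage tracks), \code{wtSv}, \code{mutSv}
#'   (SV data.frames), and \code{truth} (see \code{\link{writeTruth}}).
#' @export
simulateStrainPair <- function(genome, config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  .checkPlantedOverlaps(config)
  set.seed(config@rngSeed + 999331L)
  chromNames <- names(genome)
  chromLens <- setNames(as.integer(lengths(genome)), chromNames)
  target <- S4Vectors::metadata(genome)$target
  decoySites <- S4Vectors::metadata(genome)$decoySites

  wt <- .newVariants(); mut <- .newVariants()
  for (ch in chromNames) {
    chromStr <- as.character(genome[[ch]])
    len <- chromLens[[ch]]

    # shared heterozygous background (SNPs, genotype 0/1 in both strains)
    pos <- .drawPositions(len, config@hetSiteDensity)
    pos <- pos[pos > 1L & pos < len]
    if (length(pos)) {
      refs <- substring(chromStr, pos, pos)
      shared <- data.frame(chrom = ch, pos = pos, ref = refs,
                           alt = .altBase(refs),
                           qual = round(runif(length(pos), 40, 1500), 1),
                           genotype = "0/1", depth = NA_integer_,
                           class = "SNP")
      wtShared <- shared
      mutShared <- shared
      wtShared$depth <- rpois(nrow(shared), config@coverageMean)
      mutShared$depth <- rpois(nrow(shared), config@coverageMean)

      wtShared <- .applyLoh(wtShared, config@lohSpecs, "WT", config, ch)
      mutShared <- .applyLoh(mutShared, config@lohSpecs, "MUT", config, ch)
      if (!is.null(target) && target$chrom == ch)
        mutShared <- .applyHemizygosity(mutShared,
                                        target$largeDeletionStart - 1L,
                                        target$largeDeletionEnd - 1L)
      wt <- rbind(wt, wtShared)
      mut <- rbind(mut, mutShared)
    }

    # independent strain-specific variants
    for (strain in c("WT", "MUT")) {
      sp <- .drawPositions(len, config@strainSnvRate)
      sp <- setdiff(sp[sp > 1L & sp < len - 1L], pos)
      if (!length(sp)) next
      isSnp <- runif(length(sp)) < 0.81
      refs <- substring(chromStr, sp, sp)
      alts <- refs
      alts[isSnp] <- .altBase(refs[isSnp])
      # non-SNPs: half 1-bp deletions (anchored REF of 2), half insertions
      isDel <- !isSnp & runif(length(sp)) < 0.5
      isIns <- !isSnp & !isDel
      refs[isDel] <- substring(chromStr, sp[isDel], sp[isDel] + 1L)
      alts[isIns] <- paste0(refs[isIns],
                            sample(.BASES, sum(isIns), replace = TRUE))
      rec <- data.frame(chrom = ch, pos = sp, ref = refs, alt = alts,
                        qual = round(runif(length(sp), 40, 1500), 1),
                        genotype = "0/1",
                        depth = rpois(length(sp), config@coverageMean),
                        class = ifelse(isSnp, "SNP", "indel"))
      if (strain == "WT") wt <- rbind(wt, rec) else mut <- rbind(mut, rec)
    }
  }

  # target edit: 1-bp deletion record in MUT only (other allele carries the
  # large deletion, represented as an SV)
  if (!is.null(target)) {
    chromStr <- as.character(genome[[target$chrom]])
    a <- target$smallDeletionVcfPos  # 1-based anchor base
    edit <- data.frame(chrom = target$chrom, pos = a,
                       ref = substring(chromStr, a, a + 1L),
                       alt = substring(chromStr, a, a),
                       qual = round(runif(1L, 500, 1500), 1),
                       genotype = "0/1",
                       depth = rpois(1L, config@coverageMean),
                       class = "indel")
    mut <- mut[!(mut$chrom == target$chrom & mut$pos == a), , drop = FALSE]
    wt <- wt[!(wt$chrom == target$chrom & wt$pos == a), , drop = FALSE]
    mut <- rbind(mut, edit)
  }

  wt <- wt[order(factor(wt$chrom, levels = chromNames), wt$pos), ]
  mut <- mut[order(factor(mut$chrom, levels = chromNames), mut$pos), ]
  rownames(wt) <- rownames(mut) <- NULL

  # SV tables
  svCols <- c("chrom1", "pos1", "chrom2", "pos2", "type", "size",
              "supportingReads")
  emptySv <- emptySvSpecs()[, setdiff(names(emptySvSpecs()), "strain")]
  emptySv$size <- integer()
  emptySv <- emptySv[, svCols]
  wtSv <- emptySv; mutSv <- emptySv
  if (nrow(config@svSpecs)) {
    sv <- config@svSpecs
    sv$size <- ifelse(sv$chrom1 == sv$chrom2, sv$pos2 - sv$pos1, NA_integer_)
    for (i in seq_len(nrow(sv))) {
      row <- sv[i, svCols]
      if (sv$strain[i] %in% c("WT", "both")) wtSv <- rbind(wtSv, row)
      if (sv$strain[i] %in% c("MUT", "both")) mutSv <- rbind(mutSv, row)
    }
  }
  if (!is.null(target)) {
    mutSv <- rbind(mutSv, data.frame(
      chrom1 = target$chrom, pos1 = target$largeDeletionStart,
      chrom2 = target$chrom, pos2 = target$largeDeletionEnd, type = "DEL",
      size = target$largeDeletionLength,
      supportingReads = max(10L, rpois(1L, config@coverageMean / 2))))
  }
  rownames(wtSv) <- rownames(mutSv) <- NULL

  # coverage tracks: windows split at hemizygous-deletion boundaries
  wtCoverage <- .simulateCoverage(chromLens, config, .halvedIntervals(
    config, target, wtSv, "WT"))
  mutCoverage <- .simulateCoverage(chromLens, config, .halvedIntervals(
    config, target, mutSv, "MUT"))

  wtKeys <- variantKey(wt); mutKeys <- variantKey(mut)
  truth <- list(
    seed = config@rngSeed,
    genome = list(nChromosomes = config@nChromosomes,
                  chromosomeLength = config@chromosomeLength,
                  chromNames = chromNames),
    target = target,
    offtargetSites = decoySites,
    lohTracts = config@lohSpecs,
    svs = rbind(
      if (nrow(config@svSpecs)) config@svSpecs else NULL,
      if (!is.null(target)) data.frame(
        chrom1 = target$chrom, pos1 = target$largeDeletionStart,
        chrom2 = target$chrom, pos2 = target$largeDeletionEnd,
        type = "DEL", supportingReads = mutSv$supportingReads[nrow(mutSv)],
        strain = "MUT") else NULL),
    wtVariants = wt, mutVariants = mut,
    sharedKeys = intersect(wtKeys, mutKeys),
    wtOnlyKeys = setdiff(wtKeys, mutKeys),
    mutOnlyKeys = setdiff(mutKeys, wtKeys))

  list(wtVariants = wt, mutVariants = mut, wtCoverage = wtCoverage,
       mutCoverage = mutCoverage, wtSv = wtSv, mutSv = mutSv, truth = truth)
}

.checkPlantedOverlaps <- function(config) {
  ls <- config@lohSpecs
  if (nrow(ls) > 1L) {
    for (i in seq_len(nrow(ls) - 1L)) for (j in (i + 1L):nrow(ls)) {
      if (ls$chromosome[i] == ls$chromosome[j] &&
          ls$strain[i] == ls$strain[j] &&
          ls$start[i] < ls$end[j] && ls$start[j] < ls$end[i])
        stop("planted LOH tracts ", i, " and ", j, " overlap")
    }
  }
  invisible(TRUE)
}

# convert shared het sites inside LOH tracts of `strain`: a residual
# fraction stays 0/1, the rest becomes 0/0 (record dropped) or 1/1
.applyLoh <- function(records, lohSpecs, strain, config, chrom) {
  if (!nrow(lohSpecs) || !nrow(records)) return(records)
  specs <- lohSpecs[lohSpecs$strain == strain & lohSpecs$chromosome == chrom, ,
                    drop = FALSE]
  drop <- logical(nrow(records))
  for (i in seq_len(nrow(specs))) {
    inTract <- which(records$pos - 1L >= specs$start[i] &
                     records$pos - 1L < specs$end[i])
    if (!length(inTract)) next
    pResid <- if (config@hetSiteDensity > 0)
      min(1, specs$residualHetDensity[i] / config@hetSiteDensity) else 0
    convert <- inTract[runif(length(inTract)) >= pResid]
    toHomAlt <- convert[runif(length(convert)) < 0.5]
    toHomRef <- setdiff(convert, toHomAlt)
    records$genotype[toHomAlt] <- "1/1"
    drop[toHomRef] <- TRUE
    if (specs$mechanism[i] == "deletion") {
      sel <- setdiff(inTract, toHomRef)
      records$depth[sel] <- rpois(length(sel), config@coverageMean / 2)
    }
  }
  records[!drop, , drop = FALSE]
}

# inside the hemizygous target deletion every shared het site loses one
# allele: 50/50 homozygous-reference (dropped) or homozygous-alternate
.applyHemizygosity <- function(records, start0, end0) {
  inDel <- which(records$pos - 1L >= start0 & records$pos - 1L < end0)
  if (!length(inDel)) return(records)
  toHomAlt <- inDel[runif(length(inDel)) < 0.5]
  toHomRef <- setdiff(inDel, toHomAlt)
  records$genotype[toHomAlt] <- "1/1"
  records$depth[inDel] <- pmax(1L, floor(records$depth[inDel] / 2))
  records[setdiff(seq_len(nrow(records)), toHomRef), , drop = FALSE]
}

# intervals (0-based half-open) where a strain's depth is halved
.halvedIntervals <- function(config, target, svTable, strain) {
  out <- list()
  ls <- config@lohSpecs
  del <- ls[ls$strain == strain & ls$mechanism == "deletion", , drop = FALSE]
  for (i in seq_len(nrow(del)))
    out[[length(out) + 1L]] <- list(chrom = del$chromosome[i],
                                    start = del$start[i], end = del$end[i])
  delSv <- svTable[svTable$type == "DEL", , drop = FALSE]
  for (i in seq_len(nrow(delSv)))
    out[[length(out) + 1L]] <- list(chrom = delSv$chrom1[i],
                                    start = delSv$pos1[i] - 1L,
                                    end = delSv$pos2[i] - 1L)
  out
}

.simulateCoverage <- function(chromLens, config, halved) {
  w <- config@windowSize
  tracks <- lapply(names(chromLens), function(ch) {
    len <- chromLens[[ch]]
    cuts <- seq(0L, len, by = w)
    if (cuts[length(cuts)] < len) cuts <- c(cuts, len)
    for (h in halved) if (h$chrom == ch)
      cuts <- c(cuts, max(0L, h$start), min(len, h$end))
    cuts <- sort(unique(cuts))
    start <- cuts[-length(cuts)]; end <- cuts[-1L]
    factor <- rep(1, length(start))
    for (h in halved) if (h$chrom == ch)
      factor[start >= h$start & end <= h$end] <- factor[
        start >= h$start & end <= h$end] * 0.5
    data.frame(chrom = ch, start = as.integer(start), end = as.integer(end),
               meanDepth = rpois(length(start), config@coverageMean * factor))
  })
  do.call(rbind, tracks)
}

#' Run a full simulation and (optionally) write its artifacts
#'
#' Convenience wrapper: \code{\link{simulateReference}} then
#' \code{\link{simulateStrainPair}}; with \code{dir} set, writes
#' reference FASTA, per-strain VCFs, coverage TSVs, SV tables, the JSON
#' truth table and the YAML config. Re-running with the same config (and
#' seed) reproduces every file byte for byte.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir output directory, or NULL to skip writing.
#' @return The \code{\link{simulateStrainPair}} list, plus \code{genome}
#'   and (when written) \code{paths}.
#' @export
simulateAll <- function(config, dir = NULL) {
  genome <- simulateReference(config)
  sim <- simulateStrainPair(genome, config)
  sim$genome <- genome
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    p <- list(
      reference = file.path(dir, "reference.fasta"),
      wtVcf = file.path(dir, "wt.vcf"), mutVcf = file.path(dir, "mut.vcf"),
      wtCoverage = file.path(dir, "wt_coverage.tsv"),
      mutCoverage = file.path(dir, "mut_coverage.tsv"),
      wtSv = file.path(dir, "wt_sv.tsv"), mutSv = file.path(dir, "mut_sv.tsv"),
      truth = file.path(dir, "truth.json"),
      config = file.path(dir, "config.yaml"))
    Biostrings::writeXStringSet(genome, p$reference)
    lens <- setNames(as.integer(lengths(genome)), names(genome))
    writeVcf(sim$wtVariants, p$wtVcf, "WT", lens)
    writeVcf(sim$mutVariants, p$mutVcf, "MUT", lens)
    writeCoverage(sim$wtCoverage, p$wtCoverage)
    writeCoverage(sim$mutCoverage, p$mutCoverage)
    writeSvTable(sim$wtSv, p$wtSv)
    writeSvTable(sim$mutSv, p$mutSv)
    writeTruth(sim$truth, p$truth)
    writeSimulationConfig(config, p$config)
    sim$paths <- p
  }
  sim
}

#' Serialize a SimulationConfig to YAML
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path YAML file path.
#' @return \code{readSimulationConfig}: a \linkS4class{SimulationConfig};
#'   \code{writeSimulationConfig}: \code{path}, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
  spec <- config@targetSpec
  lst <- list(
    nChromosomes = config@nChromosomes,
    chromosomeLength = config@chromosomeLength,
    hetSiteDensity = config@hetSiteDensity,
    strainSnvRate = config@strainSnvRate,
    targetSpec = if (is.null(spec)) NULL else list(
      chromosome = spec@chromosome, protospacer = spec@protospacer,
      pam = spec@pam, smallDeletionOffset = spec@smallDeletionOffset,
      largeDeletionLength = spec@largeDeletionLength,
      editedAlleleSmall = spec@editedAlleleSmall,
      editedAlleleLarge = spec@editedAlleleLarge),
    lohSpecs = if (nrow(config@lohSpecs)) config@lohSpecs else NULL,
    offtargetDecoys = if (nrow(config@offtargetDecoys))
      config@offtargetDecoys else NULL,
    svSpecs = if (nrow(config@svSpecs)) config@svSpecs else NULL,
    coverageMean = config@coverageMean,
    windowSize = config@windowSize,
    rngSeed = config@rngSeed)
  yaml::write_yaml(lst, path, column.major = FALSE)
  invisible(path)
}

#' @rdname writeSimulationConfig
#' @export
readSimulationConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  ts <- lst$targetSpec
  simulationConfig(
    nChromosomes = lst$nChromosomes,
    chromosomeLength = lst$chromosomeLength,
    hetSiteDensity = lst$hetSiteDensity,
    strainSnvRate = lst$strainSnvRate,
    targetSpec = if (is.null(ts)) NULL else targetEditSpec(
      chromosome = ts$chromosome, protospacer = ts$protospacer, pam = ts$pam,
      smallDeletionOffset = ts$smallDeletionOffset,
      largeDeletionLength = ts$largeDeletionLength,
      editedAlleleSmall = ts$editedAlleleSmall,
      editedAlleleLarge = ts$editedAlleleLarge),
    lohSpecs = if (is.null(lst$lohSpecs)) emptyLohSpecs() else
      do.call(rbind, lapply(lst$lohSpecs, as.data.frame)),
    offtargetDecoys = if (is.null(lst$offtargetDecoys)) emptyDecoySpecs() else
      do.call(rbind, lapply(lst$offtargetDecoys, as.data.frame)),
    svSpecs = if (is.null(lst$svSpecs)) emptySvSpecs() else
      do.call(rbind, lapply(lst$svSpecs, as.data.frame)),
    coverageMean = lst$coverageMean,
    windowSize = lst$windowSize,
    rngSeed = lst$rngSeed)
}
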
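#' @import methods
#' @importFrom stats median rpois runif cor sd loess loess.control predict setNames
#' @importFrom utils read.table write.table
NULL

.IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

.validDNA <- function(x) nzchar(x) && grepl("^[ACGT]+$", x)

#' Guide RNA description
#'
#' A 20-nt protospacer together with the PAM pattern it requires 3' of the
#' protospacer and the length of the PAM-proximal seed region used when
#' counting seed mismatches.
#'
#' @slot protospacer 20-nt DNA string (ACGT), stored uppercase.
#' @slot pamPattern 3-letter IUPAC pattern, default \code{"NGG"} (SpCas9).
#' @slot seedLength integer in \code{[8, 12]}; the seed is the
#'   \code{seedLength} PAM-proximal (3') bases of the protospacer.
#' @exportClass GuideRNA
setClass("GuideRNA",
  representation(protospacer = "character", pamPattern = "character",
                 seedLength = "integer"))

setValidity("GuideRNA", function(object) {
  msg <- character()
  if (length(object@protospacer) != 1L || nchar(object@protospacer) != 20L ||
      !.validDNA(object@protospacer))
    msg <- c(msg, "protospacer must be a single 20-nt ACGT string")
  if (length(object@pamPattern) != 1L || nchar(object@pamPattern) != 3L ||
      !grepl("^[ACGTRYSWKMBDHVN]+$", object@pamPattern))
    msg <- c(msg, "pamPattern must be a 3-letter IUPAC string")
  if (length(object@seedLength) != 1L || is.na(object@seedLength) ||
      object@seedLength < 8L || object@seedLength > 12L)
    msg <- c(msg, "seedLength must be in [8, 12]")
  if (length(msg)) msg else TRUE
})

#' Construct a GuideRNA
#'
#' @param protospacer 20-nt protospacer sequence (case-insensitive).
#' @param pamPattern IUPAC PAM pattern, default \code{"NGG"}.
#' @param seedLength seed region length (PAM-proximal bases), default 12.
#' @return A \linkS4class{GuideRNA} object.
#' @examples
#' guideRNA("ATACTATGCTTGGATGGCGG")
#' @export
guideRNA <- function(protospacer, pamPattern = "NGG", seedLength = 12L) {
  new("GuideRNA", protospacer = toupper(protospacer),
      pamPattern = toupper(pamPattern), seedLength = as.integer(seedLength))
}

setMethod("show", "GuideRNA", function(object) {
  cat("GuideRNA: ", object@protospacer, " + PAM ", object@pamPattern,
      " (seed ", object@seedLength, " nt, GC ",
      format(gcContent(object@protospacer), digits = 3), "%)\n", sep = "")
})

#' Target edit specification
#'
#' Describes the biallelic heterozygous edit planted at the protospacer by
#' the simulator: a 1-bp deletion at a PAM-relative offset on one allele
#' and a multi-kb deletion on the other allele. Position -1 is the base
#' immediately 5' of the PAM; Cas9 cleaves between -4 and -3.
#'
#' @slot chromosome chromosome the protospacer is planted on.
#' @slot protospacer 20-nt protospacer.
#' @slot pam 3-letter PAM pattern (NGG).
#' @slot smallDeletionOffset PAM-relative position of the deleted base,
#'   default -4 (the 4th base 5' of the PAM's first base).
#' @slot largeDeletionLength length in bp of the deletion on the other
#'   allele, default 3639.
#' @slot editedAlleleSmall,editedAlleleLarge allele index (1 or 2) carrying
#'   each edit; must differ.
#' @exportClass TargetEditSpec
setClass("TargetEditSpec",
  representation(chromosome = "character", protospacer = "character",
                 pam = "character", smallDeletionOffset = "integer",
                 largeDeletionLength = "integer",
                 editedAlleleSmall = "integer", editedAlleleLarge = "integer"))

setValidity("TargetEditSpec", function(object) {
  msg <- character()
  if (nchar(object@protospacer) != 20L || !.validDNA(object@protospacer))
    msg <- c(msg, "protospacer must be a 20-nt ACGT string")
  if (object@smallDeletionOffset >= 0L)
    msg <- c(msg, "smallDeletionOffset must be negative (5' of the PAM)")
  if (object@largeDeletionLength < 1L)
    msg <- c(msg, "largeDeletionLength must be positive")
  if (!object@editedAlleleSmall %in% 1:2 || !object@editedAlleleLarge %in% 1:2)
    msg <- c(msg, "allele indices must be 1 or 2")
  if (object@editedAlleleSmall == object@editedAlleleLarge)
    msg <- c(msg, "small and large edits must sit on different alleles")
  if (length(msg)) msg else TRUE
})

#' Construct a TargetEditSpec
#'
#' @param chromosome chromosome name the edit is planted on.
#' @param protospacer 20-nt protospacer sequence.
#' @param pam PAM pattern, default \code{"NGG"}.
#' @param smallDeletionOffset deleted-base position relative to the PAM
#'   (default -4).
#' @param largeDeletionLength large-deletion size in bp (default 3639).
#' @param editedAlleleSmall,editedAlleleLarge allele carrying each edit.
#' @return A \linkS4class{TargetEditSpec}.
#' @export
targetEditSpec <- function(chromosome, protospacer, pam = "NGG",
                           smallDeletionOffset = -4L,
                           largeDeletionLength = 3639L,
                           editedAlleleSmall = 1L, editedAlleleLarge = 2L) {
  new("TargetEditSpec", chromosome = chromosome,
      protospacer = toupper(protospacer), pam = toupper(pam),
      smallDeletionOffset = as.integer(smallDeletionOffset),
      largeDeletionLength = as.integer(largeDeletionLength),
      editedAlleleSmall = as.integer(editedAlleleSmall),
      editedAlleleLarge = as.integer(editedAlleleLarge))
}

#' Simulation configuration
#'
#' Full generative specification of a synthetic diploid strain pair. The
#' defaults reproduce the study conditions the package is tested under: a
#' shared heterozygous background at 0.98 sites per 100 bp (the
#' genome-wide heterozygosity of the sequenced strains), strain-specific
#' small variants at 4e-4 per bp, 50 kb analysis windows, and window-level
#' Poisson coverage.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromosomeLength length of each chromosome (bp).
#' @slot hetSiteDensity shared heterozygous-site density per bp
#'   (default 0.0098, i.e. 0.98\%).
#' @slot strainSnvRate strain-specific small-variant rate per bp per strain.
#' @slot targetSpec a \linkS4class{TargetEditSpec} or NULL.
#' @slot lohSpecs data.frame of LOH tracts to plant: columns
#'   \code{chromosome, start, end} (0-based half-open), \code{strain}
#'   (WT/MUT), \code{mechanism} (gene_conversion/deletion),
#'   \code{residualHetDensity} (per bp).
#' @slot offtargetDecoys data.frame: columns \code{mismatches,
#'   seedMismatches, copies}.
#' @slot svSpecs data.frame of SVs to plant: columns \code{chrom1, pos1,
#'   chrom2, pos2, type, supportingReads, strain} (WT/MUT/both).
#' @slot coverageMean mean read depth per window.
#' @slot windowSize coverage/heterozygosity window size (bp), default 50000.
#' @slot rngSeed integer seed; a fixed seed gives byte-identical outputs.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(nChromosomes = "integer", chromosomeLength = "integer",
                 hetSiteDensity = "numeric", strainSnvRate = "numeric",
                 targetSpec = "ANY", lohSpecs = "data.frame",
                 offtargetDecoys = "data.frame", svSpecs = "data.frame",
                 coverageMean = "numeric", windowSize = "integer",
                 rngSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nChromosomes < 1L) msg <- c(msg, "need at least one chromosome")
  if (object@chromosomeLength < 2L * object@windowSize)
    msg <- c(msg, "chromosomeLength must be >= 2 * windowSize")
  for (d in c(object@hetSiteDensity, object@strainSnvRate))
    if (d < 0 || d > 1) msg <- c(msg, "densities must lie in [0, 1]")
  if (!is.null(object@targetSpec) && !is(object@targetSpec, "TargetEditSpec"))
    msg <- c(msg, "targetSpec must be a TargetEditSpec or NULL")
  if (nrow(object@lohSpecs)) {
    ls <- object@lohSpecs
    if (any(ls$end <= ls$start)) msg <- c(msg, "LOH tract end must exceed start")
    if (any(ls$end - ls$start < 1000)) msg <- c(msg, "LOH tracts must be >= 1 kb")
    if (!all(ls$strain %in% c("WT", "MUT")))
      msg <- c(msg, "LOH strain must be WT or MUT")
    if (!all(ls$mechanism %in% c("gene_conversion", "deletion")))
      msg <- c(msg, "LOH mechanism must be gene_conversion or deletion")
  }
  if (nrow(object@offtargetDecoys) &&
      any(object@offtargetDecoys$mismatches > 20))
    msg <- c(msg, "decoy mismatch count cannot exceed 20")
  if (object@coverageMean < 0) msg <- c(msg, "coverageMean must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param nChromosomes,chromosomeLength genome dimensions.
#' @param hetSiteDensity shared heterozygous-site density per bp.
#' @param strainSnvRate strain-specific variant rate per bp.
#' @param targetSpec \linkS4class{TargetEditSpec} or NULL for no edit.
#' @param lohSpecs,offtargetDecoys,svSpecs data.frames as documented in
#'   \linkS4class{SimulationConfig}; empty by default.
#' @param coverageMean mean window depth (default 100).
#' @param windowSize window size in bp (default 50000).
#' @param rngSeed integer seed (default 1).
#' @return A \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nChromosomes = 2L, chromosomeLength = 1000000L,
                             hetSiteDensity = 0.0098, strainSnvRate = 4e-4,
                             targetSpec = NULL,
                             lohSpecs = emptyLohSpecs(),
                             offtargetDecoys = emptyDecoySpecs(),
                             svSpecs = emptySvSpecs(),
                             coverageMean = 100, windowSize = 50000L,
                             rngSeed = 1L) {
  new("SimulationConfig", nChromosomes = as.integer(nChromosomes),
      chromosomeLength = as.integer(chromosomeLength),
      hetSiteDensity = hetSiteDensity, strainSnvRate = strainSnvRate,
      targetSpec = targetSpec, lohSpecs = as.data.frame(lohSpecs),
      offtargetDecoys = as.data.frame(offtargetDecoys),
      svSpecs = as.data.frame(svSpecs), coverageMean = coverageMean,
      windowSize = as.integer(windowSize), rngSeed = as.integer(rngSeed))
}

#' Empty planting tables
#'
#' Zero-row data.frames with the column layout \code{simulationConfig()}
#' expects for LOH tracts, off-target decoys and structural variants.
#' @return A zero-row data.frame.
#' @export
emptyLohSpecs <- function()
  data.frame(chromosome = character(), start = integer(), end = integer(),
             strain = character(), mechanism = character(),
             residualHetDensity = numeric())

#' @rdname emptyLohSpecs
#' @export
emptyDecoySpecs <- function()
  data.frame(mismatches = integer(), seedMismatches = integer(),
             copies = integer())

#' @rdname emptyLohSpecs
#' @export
emptySvSpecs <- function()
  data.frame(chrom1 = character(), pos1 = integer(), chrom2 = character(),
             pos2 = integer(), type = character(),
             supportingReads = integer(), strain = character())

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nChromosomes, "chromosome(s) x",
      object@chromosomeLength, "bp\n")
  cat("  het density", object@hetSiteDensity, "| strain SNV rate",
      object@strainSnvRate, "| coverage", object@coverageMean,
      "| window", object@windowSize, "bp | seed", object@rngSeed, "\n")
  cat("  planted:", if (is.null(object@targetSpec)) "no target edit" else
      paste0("target edit on ", object@targetSpec@chromosome), "|",
      nrow(object@lohSpecs), "LOH tract(s) |",
      nrow(object@offtargetDecoys), "decoy spec(s) |",
      nrow(object@svSpecs), "SV spec(s)\n")
})

#' Variant filter configuration
#'
#' Post-calling filters applied to per-strain variant records. The
#' defaults keep variants with quality strictly above 30 (phred-scaled)
#' and depth between 5 and 200 reads, and require the non-carrier strain
#' to be covered before a variant may be called strain-specific.
#' Upstream caller options (mapping quality 30, base quality 20) apply at
#' the read level and are not re-applied here.
#'
#' @slot minQuality quality must be strictly greater than this (default 30).
#' @slot minDepth,maxDepth inclusive depth bounds (defaults 5, 200).
#' @slot requireCoverageBothStrains if TRUE (default), a variant seen in
#'   one strain only counts as strain-specific only when the other strain
#'   has depth >= minDepth there; otherwise it is dropped as unresolvable.
#' @exportClass FilterConfig
setClass("FilterConfig",
  representation(minQuality = "numeric", minDepth = "integer",
                 maxDepth = "integer", requireCoverageBothStrains = "logical"))

setValidity("FilterConfig", function(object) {
  if (object@minDepth < 0L || object@minDepth > object@maxDepth)
    "need 0 <= minDepth <= maxDepth" else TRUE
})

#' Construct a FilterConfig
#'
#' @param minQuality strict lower bound on variant quality (default 30).
#' @param minDepth,maxDepth inclusive depth bounds (defaults 5 and 200).
#' @param requireCoverageBothStrains see \linkS4class{FilterConfig}.
#' @return A \linkS4class{FilterConfig}.
#' @export
filterConfig <- function(minQuality = 30, minDepth = 5L, maxDepth = 200L,
                         requireCoverageBothStrains = TRUE) {
  new("FilterConfig", minQuality = minQuality, minDepth = as.integer(minDepth),
      maxDepth = as.integer(maxDepth),
      requireCoverageBothStrains = requireCoverageBothStrains)
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig: QUAL >", object@minQuality, "| depth in [",
      object@minDepth, ",", object@maxDepth, "] | coverage in both strains:",
      object@requireCoverageBothStrains, "\n")
})

#' LOH calling configuration
#'
#' Parameters for differential loss-of-heterozygosity calling. Window-level
#' thresholds separate Table-1-scale contrasts (affected regions at
#' 0.04--0.09\% heterozygous sites per bp against chromosome backgrounds of
#' 1.1--1.3\%) by more than 5x. Variant-level parameters drive the
#' discordant-run refinement that resolves tracts smaller than one window.
#'
#' @slot windowSize analysis window (bp), default 50000.
#' @slot affectedMaxHz max per-bp heterozygosity (\%) for the affected
#'   strain in a flagged window/segment (default 0.2).
#' @slot otherMinHz min per-bp heterozygosity (\%) for the unaffected
#'   strain (default 0.5).
#' @slot minSegmentLength shortest reported segment (bp), default 20000.
#' @slot maxGapWindows unflagged windows tolerated inside a window-level
#'   run (default 1).
#' @slot smoothingSpan loess span used for profile smoothing (default 0.3);
#'   smoothing is for display only and never feeds segment calling.
#' @slot deletionRatioMax coverage ratio at or below which a segment is
#'   classified as a hemizygous deletion (default 0.6).
#' @slot conversionRatioRange coverage-ratio band classified as gene
#'   conversion (default c(0.8, 1.2)); ratios between the bands are
#'   ambiguous.
#' @slot minDiscordantSites minimum discordant informative sites for a
#'   variant-level candidate run (default 20).
#' @slot maxConcordantGap concordant informative sites tolerated inside a
#'   discordant run before it ends (default 3).
#' @slot mergeGap candidate segments on the same strain closer than this
#'   (bp) are merged (default 2000).
#' @exportClass LOHConfig
setClass("LOHConfig",
  representation(windowSize = "integer", affectedMaxHz = "numeric",
                 otherMinHz = "numeric", minSegmentLength = "integer",
                 maxGapWindows = "integer", smoothingSpan = "numeric",
                 deletionRatioMax = "numeric", conversionRatioRange = "numeric",
                 minDiscordantSites = "integer", maxConcordantGap = "integer",
                 mergeGap = "integer"))

setValidity("LOHConfig", function(object) {
  msg <- character()
  if (object@affectedMaxHz >= object@otherMinHz)
    msg <- c(msg, "affectedMaxHz must be < otherMinHz")
  if (any(c(object@affectedMaxHz, object@otherMinHz, object@windowSize,
            object@minSegmentLength) <= 0))
    msg <- c(msg, "thresholds must be positive")
  if (length(object@conversionRatioRange) != 2L ||
      diff(object@conversionRatioRange) <= 0)
    msg <- c(msg, "conversionRatioRange must be an increasing pair")
  if (object@deletionRatioMax >= object@conversionRatioRange[1L])
    msg <- c(msg, "deletionRatioMax must fall below conversionRatioRange")
  if (length(msg)) msg else TRUE
})

#' Construct an LOHConfig
#'
#' @param windowSize,affectedMaxHz,otherMinHz,minSegmentLength,maxGapWindows
#'   window-level calling parameters; see \linkS4class{LOHConfig}.
#' @param smoothingSpan loess span for display smoothing.
#' @param deletionRatioMax,conversionRatioRange mechanism thresholds.
#' @param minDiscordantSites,maxConcordantGap,mergeGap variant-level
#'   refinement parameters.
#' @return An \linkS4class{LOHConfig}.
#' @export
lohConfig <- function(windowSize = 50000L, affectedMaxHz = 0.2,
                      otherMinHz = 0.5, minSegmentLength = 20000L,
                      maxGapWindows = 1L, smoothingSpan = 0.3,
                      deletionRatioMax = 0.6,
                      conversionRatioRange = c(0.8, 1.2),
                      minDiscordantSites = 20L, maxConcordantGap = 3L,
                      mergeGap = 2000L) {
  new("LOHConfig", windowSize = as.integer(windowSize),
      affectedMaxHz = affectedMaxHz, otherMinHz = otherMinHz,
      minSegmentLength = as.integer(minSegmentLength),
      maxGapWindows = as.integer(maxGapWindows),
      smoothingSpan = smoothingSpan, deletionRatioMax = deletionRatioMax,
      conversionRatioRange = conversionRatioRange,
      minDiscordantSites = as.integer(minDiscordantSites),
      maxConcordantGap = as.integer(maxConcordantGap),
      mergeGap = as.integer(mergeGap))
}

setMethod("show", "LOHConfig", function(object) {
  cat("LOHConfig: window", object@windowSize, "bp | hz <=",
      object@affectedMaxHz, "vs >=", object@otherMinHz,
      "| min segment", object@minSegmentLength, "bp\n")
  cat("  mechanism: deletion <=", object@deletionRatioMax,
      "| conversion in [", paste(object@conversionRatioRange, collapse = ", "),
      "]\n")
})
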
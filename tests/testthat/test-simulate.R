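PROTO <- "ATACTATGCTTGGATGGCGG"

quietConfig <- function(...) {
  defaults <- list(nChromosomes = 2L, chromosomeLength = 200000L,
                   hetSiteDensity = 0, strainSnvRate = 0, rngSeed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationConfig, args)
}

test_that("reference dimensions and target locus follow the config", {
  cfg <- quietConfig(targetSpec = targetEditSpec("chr1", PROTO))
  genome <- simulateReference(cfg)
  expect_equal(names(genome), c("chr1", "chr2"))
  expect_equal(unname(lengths(genome)), c(200000L, 200000L))
  target <- S4Vectors::metadata(genome)$target
  expect_equal(target$chrom, "chr1")
  planted <- substring(as.character(genome[["chr1"]]),
                       target$protoStart0 + 1L, target$protoStart0 + 20L)
  expect_equal(planted, PROTO)
  # PAM-relative small-deletion coordinate: 4 bases 5' of the PAM start
  expect_equal(target$smallDeletionPos, target$pamStart0 + 1L - 4L)
})

test_that("decoys are recovered by an exhaustive scan at their mismatch level", {
  cfg <- quietConfig(targetSpec = targetEditSpec("chr1", PROTO),
                     offtargetDecoys = data.frame(mismatches = 2L,
                                                  seedMismatches = 0L,
                                                  copies = 3L))
  genome <- simulateReference(cfg)
  sites <- findOffTargets(genome, guideRNA(PROTO), 2L)
  expect_length(sites, 4L)  # 1 on-target + 3 decoys
  expect_equal(sum(sites$mismatches == 0L), 1L)
  expect_equal(sum(sites$mismatches == 2L), 3L)
  truthDecoys <- S4Vectors::metadata(genome)$decoySites
  expect_setequal(
    paste(truthDecoys$chrom, truthDecoys$start),
    paste(as.character(GenomeInfoDb::seqnames(sites)),
          BiocGenerics::start(sites) - 1L)[sites$mismatches == 2L])
})

test_that("the same config and seed reproduce byte-identical artifacts", {
  cfg <- quietConfig(hetSiteDensity = 0.005, strainSnvRate = 2e-4,
                     targetSpec = targetEditSpec("chr1", PROTO))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateAll(cfg, dir = d1)
  simulateAll(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("a null model yields empty VCFs and flat coverage", {
  cfg <- quietConfig()
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  expect_equal(nrow(sim$wtVariants), 0L)
  expect_equal(nrow(sim$mutVariants), 0L)
  expect_equal(nrow(sim$wtSv), 0L)
  # Poisson(100) per 50 kb window: mean across windows near the mean
  expect_lt(abs(mean(sim$wtCoverage$meanDepth) - cfg@coverageMean), 10)
})

test_that("realized heterozygous-site density matches the configured 0.98%", {
  cfg <- simulationConfig(nChromosomes = 1L, chromosomeLength = 1000000L,
                          hetSiteDensity = 0.0098, strainSnvRate = 0,
                          rngSeed = 5L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  expected <- 0.0098 * 1000000
  nHet <- sum(sim$wtVariants$genotype == "0/1")
  expect_lt(abs(nHet - expected), 3 * sqrt(expected))
  # identical shared background in both strains
  expect_identical(variantKey(sim$wtVariants), variantKey(sim$mutVariants))
})

test_that("the target edit appears as a 1-bp deletion in MUT only", {
  cfg <- quietConfig(hetSiteDensity = 0.0098,
                     targetSpec = targetEditSpec("chr1", PROTO))
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  target <- sim$truth$target
  dels <- sim$mutVariants[sim$mutVariants$class == "indel", , drop = FALSE]
  expect_equal(nrow(dels), 1L)
  expect_equal(nchar(dels$ref) - nchar(dels$alt), 1L)
  # anchored record sits one base left of the deleted base
  expect_equal(dels$pos, target$smallDeletionPos - 1L)
  expect_false(any(sim$wtVariants$pos == dels$pos &
                     sim$wtVariants$ref == dels$ref &
                     sim$wtVariants$alt == dels$alt))
  # large deletion on the other allele: MUT SV with the end-start size
  expect_equal(nrow(sim$mutSv), 1L)
  expect_equal(sim$mutSv$type, "DEL")
  expect_equal(sim$mutSv$size,
               target$largeDeletionEnd - target$largeDeletionStart)
  expect_equal(sim$mutSv$size, 3639L)
})

test_that("coverage is halved across deletion tracts but not conversion tracts", {
  cfg <- simulationConfig(
    nChromosomes = 2L, chromosomeLength = 500000L, hetSiteDensity = 0.0098,
    strainSnvRate = 0, coverageMean = 100,
    lohSpecs = data.frame(
      chromosome = c("chr1", "chr2"), start = c(100000L, 100000L),
      end = c(300000L, 300000L), strain = "MUT",
      mechanism = c("gene_conversion", "deletion"),
      residualHetDensity = 6e-4),
    rngSeed = 11L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  convRatio <- meanDepthOver(sim$mutCoverage, "chr1", 100000, 300000) /
    meanDepthOver(sim$wtCoverage, "chr1", 100000, 300000)
  delRatio <- meanDepthOver(sim$mutCoverage, "chr2", 100000, 300000) /
    meanDepthOver(sim$wtCoverage, "chr2", 100000, 300000)
  expect_gt(convRatio, 0.9); expect_lt(convRatio, 1.1)
  expect_gt(delRatio, 0.4); expect_lt(delRatio, 0.6)
  # heterozygosity collapses inside the tract for MUT only
  hzMut <- regionHeterozygosity(sim$mutVariants, "chr1", 100000, 300000)
  hzWt <- regionHeterozygosity(sim$wtVariants, "chr1", 100000, 300000)
  expect_lt(hzMut$region, 0.2)
  expect_gt(hzWt$region, 0.5)
})

test_that("every truth-table entry is recoverable from the emitted files", {
  cfg <- quietConfig(hetSiteDensity = 0.005, strainSnvRate = 2e-4,
                     targetSpec = targetEditSpec("chr1", PROTO),
                     offtargetDecoys = data.frame(mismatches = 1L,
                                                  seedMismatches = 1L,
                                                  copies = 2L),
                     svSpecs = data.frame(chrom1 = "chr2", pos1 = 50000L,
                                          chrom2 = "chr2", pos2 = 80000L,
                                          type = "INV",
                                          supportingReads = 25L,
                                          strain = "both"))
  dir <- withr::local_tempdir()
  sim <- simulateAll(cfg, dir = dir)
  truth <- readTruth(file.path(dir, "truth.json"))

  wt <- readVariants(file.path(dir, "wt.vcf"))
  mut <- readVariants(file.path(dir, "mut.vcf"))
  expect_setequal(variantKey(wt), variantKey(truth$wtVariants))
  expect_setequal(variantKey(mut), variantKey(truth$mutVariants))

  genome <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
  sites <- findOffTargets(setNames(as.character(genome), names(genome)),
                          guideRNA(PROTO), 1L)
  expect_setequal(
    paste(truth$offtargetSites$chrom, truth$offtargetSites$start),
    paste(as.character(GenomeInfoDb::seqnames(sites)),
          BiocGenerics::start(sites) - 1L)[sites$mismatches == 1L])

  mutSv <- readSvTable(file.path(dir, "mut_sv.tsv"))
  truthMutSv <- truth$svs[truth$svs$strain %in% c("MUT", "both"), ]
  expect_setequal(paste(mutSv$type, mutSv$chrom1, mutSv$pos1, mutSv$pos2),
                  paste(truthMutSv$type, truthMutSv$chrom1, truthMutSv$pos1,
                        truthMutSv$pos2))

  cfgBack <- readSimulationConfig(file.path(dir, "config.yaml"))
  expect_equal(cfgBack@rngSeed, cfg@rngSeed)
  expect_equal(cfgBack@targetSpec@protospacer, PROTO)
  expect_equal(cfgBack@svSpecs$pos2, 80000L)
})

test_that("overlapping planted LOH tracts are rejected", {
  cfg <- quietConfig(lohSpecs = data.frame(
    chromosome = "chr1", start = c(10000L, 40000L), end = c(50000L, 90000L),
    strain = "MUT", mechanism = "gene_conversion",
    residualHetDensity = 0))
  genome <- simulateReference(cfg)
  expect_error(simulateStrainPair(genome, cfg), "overlap")
})

test_that("config validity catches impossible requests", {
  expect_error(simulationConfig(chromosomeLength = 10000L), "windowSize")
  expect_error(simulationConfig(
    offtargetDecoys = data.frame(mismatches = 25L, seedMismatches = 0L,
                                 copies = 1L)), "20")
  expect_error(targetEditSpec("chr1", PROTO, editedAlleleSmall = 1L,
                              editedAlleleLarge = 1L), "different alleles")
})
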
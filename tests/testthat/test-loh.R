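test_that("window counts match a hand tally on a toy chromosome", {
  v <- testVariants("chr1",
                    pos = c(10, 49999, 50000, 50001, 99999, 100001,
                            120000, 150000, 199999, 200000),
                    genotype = c("0/1", "0/1", "0/1", "1/1", "0/1", "0/0",
                                 "0/1", "missing", "0/1", "0/1"))
  stats <- windowCounts(v, c(chr1 = 200000L), 50000L)
  expect_equal(stats$start, c(0L, 50000L, 100000L, 150000L))
  # 1-based pos p lands in window floor((p-1)/w): 50000 stays in window 0,
  # 50001 opens window 1; the "missing" call at 150000 is excluded
  expect_equal(stats$nHet, c(3L, 1L, 1L, 2L))
  expect_equal(stats$nHom, c(0L, 1L, 1L, 0L))
  expect_equal(stats$hzOfVariants,
               100 * c(3 / 3, 1 / 2, 1 / 2, 2 / 2))
  expect_equal(stats$hzPerBp, 100 * c(3, 1, 1, 2) / 50000)
  # conservation: counted variants = genotyped (non-missing) variants
  expect_equal(sum(stats$nHet + stats$nHom), 9L)
})

test_that("empty input yields zero counts with undefined per-variant rates", {
  stats <- windowCounts(testVariants("chr1", integer()), c(chr1 = 100000L))
  expect_true(all(stats$nHet == 0L))
  expect_true(all(is.na(stats$hzOfVariants)))
  expect_true(all(stats$hzPerBp == 0))
})

test_that("window tiling truncates the final window at the chromosome end", {
  stats <- windowCounts(testVariants("chr1", integer()), c(chr1 = 125000L),
                        50000L)
  expect_equal(stats$start, c(0L, 50000L, 100000L))
  expect_equal(stats$end, c(50000L, 100000L, 125000L))
  expect_error(windowCounts(testVariants("chr1", 130000), c(chr1 = 125000L)),
               "bounds")
})

test_that("smoothing preserves constants, reproduces linear ramps, and keeps steps monotone", {
  grid <- windowCounts(testVariants("chr1", integer()), c(chr1 = 1000000L))
  n <- nrow(grid)
  const <- grid; const$hzOfVariants <- 1.0
  expect_equal(smoothProfile(const, 0.3)$smoothed, rep(1.0, n))
  ramp <- grid; ramp$hzOfVariants <- seq(0, 2, length.out = n)
  expect_equal(smoothProfile(ramp, 0.3)$smoothed, ramp$hzOfVariants,
               tolerance = 1e-6)
  step <- grid; step$hzOfVariants <- rep(c(1, 0), each = n / 2)
  sm <- smoothProfile(step, 0.3)$smoothed
  expect_true(all(diff(sm) <= 1e-8))
  # undefined windows are interpolated from the fit
  holey <- ramp; holey$hzOfVariants[7L] <- NA
  smh <- smoothProfile(holey, 0.5)$smoothed
  expect_equal(smh[7L], ramp$hzOfVariants[7L], tolerance = 1e-6)
  # too few defined windows: unsmoothed with warning
  tiny <- grid[1:3, ]; tiny$hzOfVariants <- c(1, NA, NA)
  expect_warning(smoothProfile(tiny, 0.3), "fewer than 3")
})

test_that("region heterozygosity is het sites over region length", {
  set.seed(29)
  pos <- sort(sample(1065985:1448384, 344))
  v <- testVariants("chr3", pos)
  hz <- regionHeterozygosity(v, "chr3", 1065985L, 1448384L)
  expect_equal(hz$nHetRegion, 344L)
  expect_equal(round(hz$region, 2), 0.09)  # 344 / 382399 * 100
  expect_equal(regionHeterozygosity(testVariants("chr1", integer()),
                                    "chr1", 0, 1000)$region, 0)
  expect_error(regionHeterozygosity(v, "chr3", 10, 10), "exceed")
})

test_that("whole-genome heterozygosity recovers the simulated density", {
  cfg <- simulationConfig(nChromosomes = 1L, chromosomeLength = 1000000L,
                          hetSiteDensity = 0.0098, strainSnvRate = 0,
                          rngSeed = 3L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  hz <- regionHeterozygosity(sim$wtVariants, "chr1", 0L, 1000000L,
                             chromosomeLength = 1000000L)
  expect_equal(hz$region, 0.98, tolerance = 0.05)
})

test_that("a planted 300 kb conversion tract is called once with true boundaries", {
  cfg <- simulationConfig(
    nChromosomes = 1L, chromosomeLength = 1000000L, hetSiteDensity = 0.0098,
    strainSnvRate = 4e-4,
    lohSpecs = data.frame(chromosome = "chr1", start = 300000L,
                          end = 600000L, strain = "MUT",
                          mechanism = "gene_conversion",
                          residualHetDensity = 6e-4),
    rngSeed = 23L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  lens <- c(chr1 = 1000000L)
  segs <- callLohSegments(windowCounts(sim$wtVariants, lens),
                          windowCounts(sim$mutVariants, lens),
                          sim$wtVariants, sim$mutVariants, lohConfig(),
                          sim$wtCoverage, sim$mutCoverage)
  expect_length(segs, 1L)
  expect_equal(segs$affectedStrain, "MUT")
  expect_lt(abs(BiocGenerics::start(segs) - 1L - 300000L), 2000L)
  expect_lt(abs(BiocGenerics::end(segs) - 600000L), 2000L)
  expect_true(segs$hzAffected < segs$hzOther)
  expect_equal(segs$mechanism, "gene_conversion")
})

test_that("matched densities without tracts produce no segments", {
  cfg <- simulationConfig(nChromosomes = 2L, chromosomeLength = 400000L,
                          hetSiteDensity = 0.0098, strainSnvRate = 4e-4,
                          rngSeed = 27L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  lens <- c(chr1 = 400000L, chr2 = 400000L)
  segs <- callLohSegments(windowCounts(sim$wtVariants, lens),
                          windowCounts(sim$mutVariants, lens),
                          sim$wtVariants, sim$mutVariants)
  expect_length(segs, 0L)
})

test_that("a 20 kb tract is recovered by variant-level refinement", {
  cfg <- simulationConfig(
    nChromosomes = 1L, chromosomeLength = 1000000L, hetSiteDensity = 0.0098,
    strainSnvRate = 4e-4,
    lohSpecs = data.frame(chromosome = "chr1", start = 400000L,
                          end = 420000L, strain = "WT",
                          mechanism = "gene_conversion",
                          residualHetDensity = 6e-4),
    rngSeed = 31L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  lens <- c(chr1 = 1000000L)
  segs <- callLohSegments(windowCounts(sim$wtVariants, lens),
                          windowCounts(sim$mutVariants, lens),
                          sim$wtVariants, sim$mutVariants)
  expect_length(segs, 1L)
  expect_equal(segs$affectedStrain, "WT")
  expect_lt(abs(BiocGenerics::start(segs) - 1L - 400000L), 2000L)
  expect_lt(abs(BiocGenerics::end(segs) - 420000L), 2000L)
})

test_that("mismatched window grids are a contract error", {
  lens <- c(chr1 = 200000L)
  a <- windowCounts(testVariants("chr1", integer()), lens, 50000L)
  b <- windowCounts(testVariants("chr1", integer()), lens, 25000L)
  expect_error(callLohSegments(a, b, testVariants("chr1", integer()),
                               testVariants("chr1", integer())), "grids")
})

test_that("mechanism classification follows the coverage ratio bands", {
  cov <- flatCoverage("chr1", 500000L, 100)
  med <- medianDepth(cov)
  full <- classifyMechanism("chr1", 100000, 200000, cov, med)
  expect_equal(full$mechanism, "gene_conversion")
  expect_equal(full$coverageRatio, 1.0)
  half <- cov; half$meanDepth[3:4] <- 50
  del <- classifyMechanism("chr1", 100000, 200000, half, medianDepth(half))
  expect_equal(del$mechanism, "deletion")
  expect_equal(del$coverageRatio, 0.5)
  mid <- cov; mid$meanDepth[3:4] <- 70
  amb <- classifyMechanism("chr1", 100000, 200000, mid, medianDepth(mid))
  expect_equal(amb$mechanism, "ambiguous")
  expect_warning(
    none <- classifyMechanism("chr2", 0, 1000, cov, med), "no coverage")
  expect_equal(none$mechanism, "ambiguous")
})

test_that("classification is monotone in simulated depth", {
  cov <- flatCoverage("chr1", 500000L, 100)
  med <- medianDepth(cov)
  labels <- vapply(seq(1, 0.1, by = -0.05), function(f) {
    c2 <- cov; c2$meanDepth[3:4] <- 100 * f
    classifyMechanism("chr1", 100000, 200000, c2, med)$mechanism
  }, character(1L))
  # once deletion, never back to gene_conversion as depth keeps dropping
  firstDel <- match("deletion", labels)
  expect_false(any(labels[firstDel:length(labels)] == "gene_conversion"))
})

test_that("the two heterozygosity definitions rank windows concordantly", {
  cfg <- simulationConfig(nChromosomes = 1L, chromosomeLength = 1000000L,
                          hetSiteDensity = 0.0098, strainSnvRate = 0,
                          rngSeed = 37L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  # impose a smooth gradient of homozygosity so both definitions vary:
  # at constant variant density they should rank windows the same way
  v <- sim$wtVariants
  set.seed(1)
  pHom <- 0.8 * (v$pos %/% 50000L) / 20
  v$genotype[runif(nrow(v)) < pHom] <- "1/1"
  stats <- windowCounts(v, c(chr1 = 1000000L))
  ok <- !is.na(stats$hzOfVariants)
  expect_gt(cor(stats$hzOfVariants[ok], stats$hzPerBp[ok],
                method = "spearman"), 0.9)
})
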
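svRecord <- function(type, chrom1, pos1, pos2, chrom2 = chrom1,
                     support = 20L) {
  data.frame(chrom1 = chrom1, pos1 = as.integer(pos1), chrom2 = chrom2,
             pos2 = as.integer(pos2), type = type,
             supportingReads = as.integer(support))
}

variantKeySv <- function(df) paste(df$type, df$chrom1, df$pos1, df$chrom2,
                                   df$pos2)

test_that("SV tables round-trip and invariants are enforced on read", {
  recs <- rbind(svRecord("DEL", "chr1", 1000, 5000),
                svRecord("CTX", "chr1", 2000, 7000, chrom2 = "chr3"),
                svRecord("INV", "chr2", 100, 900))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSvTable(recs, path)
  back <- readSvTable(path)
  expect_equal(back$type, recs$type)
  expect_equal(back$size, c(4000L, NA_integer_, 800L))

  bad <- svRecord("CTX", "chr1", 100, 900)  # CTX needs different chromosomes
  writeSvTable(transform(bad, size = NA_integer_), path)
  expect_error(readSvTable(path), "CTX")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom1\tpos1\tchrom2\tpos2\ttype\tsize\tsupportingReads\nchr1\t1\tchr1\t100\tDUP\t99\t12",
             path2)
  expect_error(readSvTable(path2), "unknown sv type")
  path3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chrom1\tpos1", path3)
  expect_error(readSvTable(path3), "lacks column")
  # empty table reads back empty
  writeSvTable(recs[0, ], path)
  expect_equal(nrow(readSvTable(path)), 0L)
})

test_that("support filtering keeps records at exactly the threshold", {
  recs <- rbind(svRecord("DEL", "chr1", 1000, 5000, support = 10L),
                svRecord("DEL", "chr1", 9000, 12000, support = 9L))
  out <- filterBySupport(recs, 10L)
  expect_equal(nrow(out), 1L)
  expect_equal(out$supportingReads, 10L)
  expect_equal(nrow(filterBySupport(recs[0, ], 10L)), 0L)
})

test_that("class summary reproduces per-class totals and mean sizes", {
  toy <- rbind(
    do.call(rbind, replicate(303, svRecord("CTX", "chr1", 100, 200,
                                           chrom2 = "chr2"),
                             simplify = FALSE)),
    do.call(rbind, replicate(294, svRecord("DEL", "chr1", 100, 600),
                             simplify = FALSE)),
    do.call(rbind, replicate(37, svRecord("INV", "chr1", 100, 600),
                             simplify = FALSE)),
    do.call(rbind, replicate(79, svRecord("ITX", "chr1", 100, 600),
                             simplify = FALSE)))
  s <- summarizeSv(toy)
  expect_equal(unname(s$countsByType[c("CTX", "DEL", "INV", "ITX")]),
               c(303L, 294L, 37L, 79L))
  expect_equal(s$total, 713L)

  one <- svRecord("DEL", "chr1", 100, 600)
  expect_equal(summarizeSv(one)$meanSize, 500)
  two <- rbind(svRecord("DEL", "chr1", 1000, 2000),
               svRecord("DEL", "chr2", 1000, 28594))
  expect_equal(summarizeSv(two)$meanSize, 14297)
  # translocation-only input has no defined size
  ctx <- svRecord("CTX", "chr1", 100, 200, chrom2 = "chr2")
  expect_true(is.na(summarizeSv(ctx)$meanSize))
  expect_equal(summarizeSv(ctx[0, ])$total, 0L)
})

test_that("summary totals are conserved under partition and merge", {
  set.seed(61)
  recs <- do.call(rbind, lapply(1:50, function(i)
    svRecord(sample(c("DEL", "INV", "ITX"), 1L), "chr1",
             i * 1000, i * 1000 + sample(500:5000, 1L))))
  whole <- summarizeSv(recs)
  half <- sample(nrow(recs), 25)
  a <- summarizeSv(recs[half, ]); b <- summarizeSv(recs[-half, ])
  expect_equal(a$countsByType + b$countsByType, whole$countsByType)
  expect_equal(a$total + b$total, whole$total)
})

test_that("identical tables are fully shared", {
  recs <- rbind(svRecord("DEL", "chr1", 1000, 5000),
                svRecord("INV", "chr2", 100, 900))
  cmp <- compareSvStrains(recs, recs)
  expect_equal(nrow(cmp$shared), 2L)
  expect_equal(nrow(cmp$wtSpecific), 0L)
  expect_equal(nrow(cmp$mutSpecific), 0L)
})

test_that("breakpoint tolerance and reciprocal overlap govern matching", {
  a <- svRecord("DEL", "chr1", 10000, 20000)
  shifted <- svRecord("DEL", "chr1", 10999, 20999)   # 999 bp, overlap 0.9
  cmp <- compareSvStrains(a, shifted)
  expect_equal(nrow(cmp$shared), 1L)
  tooFar <- svRecord("DEL", "chr1", 11001, 21001)
  cmp2 <- compareSvStrains(a, tooFar)
  expect_equal(nrow(cmp2$shared), 0L)
  # same breakpoint distance but poor reciprocal overlap
  small <- svRecord("DEL", "chr1", 10000, 10500)
  big <- svRecord("DEL", "chr1", 10000, 20000)
  expect_equal(nrow(compareSvStrains(small, big)$shared), 0L)
  # types never cross-match
  inv <- svRecord("INV", "chr1", 10000, 20000)
  expect_equal(nrow(compareSvStrains(a, inv)$shared), 0L)
})

test_that("raising the tolerance never unshares a pair", {
  set.seed(67)
  wt <- do.call(rbind, lapply(1:30, function(i)
    svRecord("DEL", "chr1", i * 10000, i * 10000 + 4000)))
  mut <- wt
  mut$pos1 <- mut$pos1 + sample(0:1500, 30, replace = TRUE)
  mut$pos2 <- mut$pos2 + sample(0:1500, 30, replace = TRUE)
  mut$pos2 <- pmax(mut$pos2, mut$pos1 + 100L)
  prev <- -1L
  for (tol in c(250L, 500L, 1000L, 2000L)) {
    nShared <- nrow(compareSvStrains(wt, mut, tolerance = tol)$shared)
    expect_gte(nShared, prev)
    prev <- nShared
  }
})

test_that("comparison equals the brute-force matcher on random tables", {
  set.seed(71)
  mk <- function(n) do.call(rbind, lapply(seq_len(n), function(i) {
    type <- sample(c("DEL", "INV", "ITX", "CTX"), 1L)
    c1 <- sample(paste0("chr", 1:3), 1L)
    p1 <- sample(1:500000, 1L)
    if (type == "CTX")
      svRecord(type, c1, p1, sample(1:500000, 1L),
               chrom2 = sample(setdiff(paste0("chr", 1:3), c1), 1L))
    else svRecord(type, c1, p1, p1 + sample(500:20000, 1L))
  }))
  for (rep in 1:5) {
    wt <- mk(40); mut <- mk(40)
    # seed some true matches with jitter
    mut[1:10, ] <- wt[1:10, ]
    mut$pos1[1:10] <- mut$pos1[1:10] + sample(-400:400, 10, replace = TRUE)
    mut$pos2[1:10] <- mut$pos2[1:10] + sample(-400:400, 10, replace = TRUE)
    keep <- mut$type == "CTX" | mut$pos2 > mut$pos1
    mut <- mut[keep, ]
    cmp <- compareSvStrains(wt, mut)
    oracle <- naiveSvCompare(wt, mut)
    expect_equal(nrow(cmp$shared), oracle$nShared)
    expect_equal(sort(variantKeySv(cmp$wtSpecific)),
                 sort(variantKeySv(wt[oracle$wtSpecific, ])))
    expect_equal(sort(variantKeySv(cmp$mutSpecific)),
                 sort(variantKeySv(mut[oracle$mutSpecific, ])))
    # every record lands in exactly one category
    expect_equal(nrow(cmp$shared) + nrow(cmp$wtSpecific), nrow(wt))
    expect_equal(nrow(cmp$shared) + nrow(cmp$mutSpecific), nrow(mut))
  }
})

test_that("deletion coverage evidence follows the depth-ratio thresholds", {
  cov <- flatCoverage("chr1", 500000L, 100)
  med <- medianDepth(cov)
  del <- svRecord("DEL", "chr1", 100001, 200001)
  full <- deletionCoverageEvidence(del, cov, med)
  expect_equal(full$verdict, "unsupported")
  half <- cov; half$meanDepth[3:4] <- 50
  hemi <- deletionCoverageEvidence(del, half, medianDepth(half))
  expect_equal(hemi$verdict, "supported_hemizygous")
  expect_equal(hemi$ratio, 0.5)
  gone <- cov; gone$meanDepth[3:4] <- 0
  expect_equal(deletionCoverageEvidence(del, gone, medianDepth(gone))$verdict,
               "supported_homozygous")
  # the 0.6 boundary is inclusive
  edge <- cov; edge$meanDepth[3:4] <- 60
  expect_equal(deletionCoverageEvidence(del, edge, medianDepth(edge))$verdict,
               "supported_hemizygous")
})

test_that("the simulated target deletion is supported by halved coverage", {
  cfg <- simulationConfig(nChromosomes = 1L, chromosomeLength = 200000L,
                          hetSiteDensity = 0, strainSnvRate = 0,
                          windowSize = 50000L,
                          targetSpec = targetEditSpec(
                            "chr1", "ATACTATGCTTGGATGGCGG"),
                          rngSeed = 73L)
  sim <- simulateStrainPair(simulateReference(cfg), cfg)
  ev <- deletionCoverageEvidence(sim$mutSv, sim$mutCoverage,
                                 medianDepth(sim$mutCoverage))
  expect_equal(ev$verdict, "supported_hemizygous")
  expect_equal(ev$ratio, 0.5, tolerance = 0.2)
})
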
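test_that("cohort generation is deterministic given its seed", {
  sp <- smallCohortSpec(seed = 77L)
  c1 <- simulateCohort(sp)
  c2 <- simulateCohort(sp)
  expect_identical(c1$labels, c2$labels)
  for (id in names(c1$peaks))
    expect_identical(peakRanges(c1$peaks[[id]]), peakRanges(c2$peaks[[id]]))
  c3 <- simulateCohort(smallCohortSpec(seed = 78L))
  expect_false(identical(peakRanges(c1$peaks[[1]]),
                         peakRanges(c3$peaks[[1]])))
})

test_that("zero jitter and zero noise make within-type tracks identical", {
  sp <- cohortSpec(samplesPerType = 2L, kInfo = 40L, kNoise = 0L,
                   jitterSD = 0, seed = 5L)
  co <- simulateCohort(sp)
  tracks <- lapply(co$peaks, binarize)
  expect_equal(hammingDistance(tracks$TypeA_1, tracks$TypeA_2), 0)
  expect_gt(hammingDistance(tracks$TypeA_1, tracks$TypeB_1), 0)
})

test_that("truncation at kInfo removes all noise and yields zero penalty", {
  co <- simulateCohort(smallCohortSpec(seed = 29L))
  kInfo <- co$spec$kInfo
  noiseMax <- max(co$spec$noiseScores)
  for (rp in co$peaks) {
    kept <- peakRanges(truncatePeaks(rp, kInfo))
    expect_true(all(kept$negLog10P > noiseMax))
  }
  tracks <- lapply(co$peaks, binarize, mCut = kInfo)
  lam <- globalPenalty(agglomerate(distanceMatrix(tracks), "ward"),
                       co$labels)
  expect_equal(lam, 0)
})

test_that("spec validation rejects infeasible or marginless settings", {
  expect_error(cohortSpec(infoScores = c(5, 10), noiseScores = c(2, 6)),
               "margin")
  expect_error(cohortSpec(noiseScores = c(1, 10), pG = 1e-2),
               "pG threshold")
  bad <- cohortSpec(chromLengths = c(chr1 = 5000L), kInfo = 300L)
  expect_error(simulateCohort(bad), "generation error")
})

test_that("cohort export emits the formats the pipeline consumes", {
  co <- simulateCohort(cohortSpec(samplesPerType = 1L, kInfo = 20L,
                                  kNoise = 5L, seed = 3L))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  lab <- readLabels(file.path(dir, "labels.tsv"))
  expect_identical(lab, co$labels)
  lay <- readChromLengths(file.path(dir, "chrom_lengths.tsv"))
  id <- names(co$peaks)[1]
  back <- readNarrowPeak(file.path(dir, paste0(id, ".narrowPeak")), lay)
  expect_equal(GenomicRanges::start(back),
               GenomicRanges::start(peakRanges(co$peaks[[id]])))
})

test_that("simulated reads respect depth and background settings", {
  co <- simulateCohort(cohortSpec(samplesPerType = 1L, kInfo = 30L,
                                  kNoise = 0L, seed = 9L))
  rp <- co$peaks[[1]]
  # background 0: every read overlaps some peak
  reads <- simulateReads(rp, depthPerPeak = 10, backgroundRate = 0,
                         seed = 4)
  expect_length(reads, 30 * 10)
  support <- binarize(rp)
  expect_true(all(IRanges::overlapsAny(reads, peakRanges(support))))
  # depth 0, background 0: empty read set
  expect_length(simulateReads(rp, 0, 0, seed = 4), 0)
  # expected total count within 3 Poisson sd
  bg <- 1e-3
  genomeLen <- sum(as.numeric(GenomeInfoDb::seqlengths(co$layout)))
  r2 <- simulateReads(rp, depthPerPeak = 5, backgroundRate = bg, seed = 8)
  expected <- 30 * 5 + bg * genomeLen
  expect_lt(abs(length(r2) - expected), 3 * sqrt(bg * genomeLen) + 1)
})

test_that("the toy caller recovers pileup blocks deterministically", {
  layout <- genomeLayout("chr1", 10000)
  # 50 stacked reads over [100, 150]
  reads <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(rep(100, 50), rep(150, 50)))
  GenomeInfoDb::seqinfo(reads) <- layout
  pk <- toyPeakCaller(reads, coverageThreshold = 10, pG = 1e-2)
  expect_length(pk, 1)
  expect_equal(GenomicRanges::start(pk), 100)
  expect_equal(GenomicRanges::end(pk), 150)
  expect_gte(pk$negLog10P, 2)  # implied p <= pG

  # nothing reaches the threshold: empty set
  few <- reads[1:3]
  expect_length(toyPeakCaller(few, coverageThreshold = 10), 0)
})

test_that("the toy caller recalls planted peaks at high depth", {
  co <- simulateCohort(cohortSpec(samplesPerType = 1L, kInfo = 40L,
                                  kNoise = 0L, seed = 17L))
  rp <- co$peaks[[1]]
  reads <- simulateReads(rp, depthPerPeak = 60, backgroundRate = 0,
                         seed = 2)
  called <- toyPeakCaller(reads, coverageThreshold = 8, pG = 1e-2)
  planted <- peakRanges(binarize(rp))
  inter <- GenomicRanges::intersect(GenomicRanges::reduce(called), planted)
  recall <- sum(GenomicRanges::width(inter)) /
    sum(GenomicRanges::width(planted))
  expect_gte(recall, 0.95)
})
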
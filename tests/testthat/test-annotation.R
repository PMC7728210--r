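test_that("annotation fractions count peak centers inside state intervals", {
  layout <- genomeLayout("chr1", 100000)
  # 10 peaks, all centers inside the ActiveTSS block
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(100, 1000, by = 100), width = 50),
    negLog10P = 10:1)
  GenomeInfoDb::seqinfo(gr) <- layout
  ranked <- rankPeaks(gr)
  seg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 2001), c(2000, 100000)),
    state = c("ActiveTSS", "Quiescent_Low"))
  GenomeInfoDb::seqinfo(seg) <- layout
  prof <- annotationProfile(ranked, seg, window = 10, nWindows = 5)
  expect_equal(prof$fraction[prof$state == "ActiveTSS"], 1.0)
  expect_equal(prof$fraction[prof$state == "Quiescent_Low"], 0.0)
})

test_that("the center rule is boundary-inclusive with exact integer arithmetic", {
  layout <- genomeLayout("chr1", 10000)
  # center (alpha+beta)/2 = 100 exactly at sigma = 100
  atSigma <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 110),
                                    negLog10P = 5)
  # half-integer center 100.5: 2*sigma <= 201 <= 2*eps requires [<=100, >=101]
  halfIn <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 110),
                                   negLog10P = 4)
  # center 115.5 just outside [100, 115]
  halfOut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(106, 125),
                                    negLog10P = 3)
  gr <- c(atSigma, halfIn, halfOut)
  GenomeInfoDb::seqinfo(gr) <- layout
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 115),
                                state = "Enhancers")
  GenomeInfoDb::seqinfo(seg) <- layout
  prof <- annotationProfile(rankPeaks(gr), seg, window = 3, nWindows = 1)
  expect_equal(prof$fraction, 2 / 3)
})

test_that("window starts follow 1 + (j-1)*window and incomplete windows drop", {
  layout <- genomeLayout("chr1", 1000000)
  n <- 2500
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, 999000, length.out = n), width = 100),
    negLog10P = seq(50, 2, length.out = n))
  GenomeInfoDb::seqinfo(gr) <- layout
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000000),
                                state = "Quiescent_Low")
  GenomeInfoDb::seqinfo(seg) <- layout
  prof <- annotationProfile(rankPeaks(gr), seg, window = 1000, nWindows = 80)
  # only 2 complete windows of 1000 fit into 2500 peaks
  expect_equal(sort(unique(prof$windowStart)), c(1, 1001))
  expect_error(annotationProfile(rankPeaks(gr), seg, window = 0),
               "positive")
})

test_that("per-window fractions over disjoint states sum to at most one", {
  layout <- genomeLayout("chr1", 50000)
  withr::local_seed(27)
  st <- sample.int(49000, 200)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + 99),
                               negLog10P = runif(200, 2, 40))
  GenomeInfoDb::seqinfo(gr) <- layout
  seg <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 20001), c(20000, 40000)),
    state = c("ActiveTSS", "Enhancers"))
  GenomeInfoDb::seqinfo(seg) <- layout
  prof <- annotationProfile(rankPeaks(gr), seg, window = 50, nWindows = 4)
  sums <- tapply(prof$fraction, prof$windowStart, sum)
  expect_true(all(sums <= 1 + 1e-12))
})

test_that("aggregation reports per-type means and SDs", {
  p1 <- data.frame(windowStart = c(1, 1), state = c("A", "B"),
                   fraction = c(0.6, 0.4))
  p2 <- data.frame(windowStart = c(1, 1), state = c("A", "B"),
                   fraction = c(0.8, 0.2))
  labels <- c(s1 = "X", s2 = "X", s3 = "Y")
  agg <- aggregateProfiles(list(s1 = p1, s2 = p2, s3 = p1), labels)
  xa <- agg[agg$type == "X" & agg$state == "A", ]
  expect_equal(xa$mean, 0.7)
  expect_equal(xa$sd, sd(c(0.6, 0.8)))
  # single sample: mean equals profile, SD 0
  ya <- agg[agg$type == "Y" & agg$state == "A", ]
  expect_equal(ya$mean, 0.6)
  expect_equal(ya$sd, 0)
  # identical profiles: SD 0
  agg2 <- aggregateProfiles(list(a = p1, b = p1), c(a = "Z", b = "Z"))
  expect_true(all(agg2$sd == 0))
})

test_that("simulated per-window rates are recovered within binomial error", {
  layout <- genomeLayout("chr1", 1000000)
  withr::local_seed(99)
  rate <- 0.3
  n <- 1000
  inState <- runif(n) < rate
  # state block [1, 500000]; centers planted inside or outside it
  ctr <- ifelse(inState, sample.int(499000, n, replace = TRUE),
                500000 + sample.int(499000, n, replace = TRUE))
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ctr - 10, ctr + 10),
                               negLog10P = runif(n, 2, 30))
  GenomeInfoDb::seqinfo(gr) <- layout
  seg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 500000),
                                state = "Enhancers")
  GenomeInfoDb::seqinfo(seg) <- layout
  prof <- annotationProfile(rankPeaks(gr), seg, window = 1000, nWindows = 1)
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(prof$fraction - rate), 3 * se + 1e-9)
})
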
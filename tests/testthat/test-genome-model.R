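test_that("narrowPeak import converts BED coordinates to 1-based inclusive", {
  layout <- genomeLayout("chr1", 100000)
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t99\t200\t.\t0\t.\t5.0\t8.19\t6.0\t50", f)
  p <- readNarrowPeak(f, layout)
  expect_equal(GenomicRanges::start(p), 100)
  expect_equal(GenomicRanges::end(p), 200)
  expect_equal(p$negLog10P, 8.19)
})

test_that("narrowPeak import handles empty files and rejects bad input", {
  layout <- genomeLayout("chr1", 1000)
  empty <- withr::local_tempfile(fileext = ".narrowPeak")
  file.create(empty)
  expect_length(readNarrowPeak(empty, layout), 0)

  bad <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t200\t200\t.\t0\t.\t5.0\t8.19\t6.0\t50", bad)
  expect_error(readNarrowPeak(bad, layout), "end <= start|parse")

  wrongChrom <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chrX\t10\t20\t.\t0\t.\t5.0\t8.19\t6.0\t5", wrongChrom)
  expect_error(readNarrowPeak(wrongChrom, layout), "absent from layout")

  outOfBounds <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines("chr1\t10\t2000\t.\t0\t.\t5.0\t8.19\t6.0\t5", outOfBounds)
  expect_error(readNarrowPeak(outOfBounds, layout), "bounds")
})

test_that("peak write/read round trip preserves coordinates and scores", {
  layout <- genomeLayout(c("chr1", "chr2"), c(10000, 10000))
  gr <- GenomicRanges::GRanges(
    c("chr1", "chr2", "chr1"),
    IRanges::IRanges(c(1, 500, 9000), c(100, 700, 10000)),
    negLog10P = c(12.5, 3.25, 300.125))
  GenomeInfoDb::seqinfo(gr) <- layout
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeNarrowPeak(gr, f)
  back <- readNarrowPeak(f, layout)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$negLog10P, gr$negLog10P)
})

test_that("peak width is end minus start, not covered length", {
  p <- GenomicRanges::GRanges(
    c("chr3", "chr3", "chr1"),
    IRanges::IRanges(c(188271079, 188286401, 7), c(188271985, 188287077, 7)))
  expect_equal(peakWidth(p), c(906, 676, 0))
})

test_that("genome layout validates labels and lengths", {
  expect_error(genomeLayout(c("chr1", "chr1"), c(10, 20)), "unique")
  expect_error(genomeLayout("chr1", 0), "positive")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t150000", "chr2\t99"), f)
  lay <- readChromLengths(f)
  expect_equal(unname(GenomeInfoDb::seqlengths(lay)), c(150000L, 99L))
})

test_that("MACS2 command uses the fixed flags and a plain -p value", {
  cmd <- macs2Command("s1.bed", 1e-2, "out")
  expect_equal(cmd[1:2], c("macs2", "callpeak"))
  expect_true(all(c("--nomodel", "--nolambda", "--keep-dup") %in% cmd))
  expect_equal(cmd[which(cmd == "--keep-dup") + 1], "all")
  expect_equal(cmd[which(cmd == "-p") + 1], "0.01")
  cmd4 <- macs2Command("s1.bed", 1e-4, "out")
  expect_equal(cmd4[which(cmd4 == "-p") + 1], "0.0001")
  expect_error(macs2Command("s1.bed", 1.5, "out"), "in \\(0, 1\\)")
})

test_that("a missing external caller is an environment error", {
  skip_if(Sys.which("macs2") != "", "macs2 present; error path not testable")
  layout <- genomeLayout("chr1", 1000)
  wd <- withr::local_tempdir()
  expect_error(callPeaksMACS2("reads.bed", 1e-2, wd, layout),
               "not found on PATH")
  expect_length(list.files(wd), 0)
})

test_that("ChromHMM segmentation import converts, aliases and validates", {
  layout <- genomeLayout("chr1", 100000)
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t10000\t1_TssA",
               "chr1\t10000\t12000\t7_Enh",
               "chr1\t12000\t13000\t7_Enh"), f)
  seg <- readChromHMM(f, layout)
  expect_equal(GenomicRanges::start(seg)[1], 1)
  expect_equal(GenomicRanges::end(seg)[1], 10000)
  expect_equal(seg$state[1], "ActiveTSS")
  # adjacent same-state intervals are stored as given, no auto-merge
  expect_equal(sum(seg$state == "Enhancers"), 2)

  overlap <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\t1_TssA", "chr1\t500\t2000\t1_TssA"), overlap)
  expect_error(readChromHMM(overlap, layout), "overlapping")
})

test_that("label tables read into a named type vector", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("HSC1\tHSC", "B1\tB"), f)
  lab <- readLabels(f)
  expect_equal(lab, c(HSC1 = "HSC", B1 = "B"))
  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tX", "a\tY"), dup)
  expect_error(readLabels(dup), "duplicate")
})
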
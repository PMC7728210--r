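test_that("UPGMA set distance is the mean pairwise distance", {
  v <- matrix(c(0, 7, 2, 7, 0, 4, 2, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(setDistanceUPGMA("a", "b", v), 7)
  v2 <- matrix(0, 3, 3, dimnames = dimnames(v))
  v2["a", "b"] <- v2["b", "a"] <- 2
  v2["a", "c"] <- v2["c", "a"] <- 4
  expect_equal(setDistanceUPGMA("a", c("b", "c"), v2), 3)
  expect_equal(setDistanceUPGMA(character(0), "a", v), 0)
  expect_error(setDistanceUPGMA(c("a", "b"), "b", v), "disjoint")
})

test_that("Ward set distance matches the quadratic formula with sqrt heights", {
  v <- matrix(10, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  diag(v) <- 0
  expect_equal(setDistanceWard("a", "b", v), 10 / sqrt(2), tolerance = 1e-12)

  v3 <- matrix(2, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(v3) <- 0
  # D1 = 4, D2 = 0, D12 = 8, Q = 8/3 - 4/6 = 2
  expect_equal(setDistanceWard(c("a", "b"), "c", v3), sqrt(2),
               tolerance = 1e-12)
  expect_equal(setDistanceWard("a", character(0), v3), 0)
})

test_that("agglomeration follows the minimum-pair rule (hand trace)", {
  v <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  d <- agglomerate(v, "upgma")
  m <- mergeTable(d)
  expect_equal(m$tau1, c(1, 3))
  expect_equal(m$tau2, c(2, 4))
  expect_equal(m$height, c(1, 5))
  expect_equal(offspring(d, 4), c("s1", "s2"))
})

test_that("ties are broken lexicographically, deterministically", {
  v <- matrix(3, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  diag(v) <- 0
  for (method in c("ward", "upgma", "wpgma")) {
    m1 <- mergeTable(agglomerate(v, method))
    m2 <- mergeTable(agglomerate(v, method))
    expect_identical(m1, m2)
    expect_equal(m1$tau1[1], 1)
    expect_equal(m1$tau2[1], 2)
    expect_equal(m1$tau1[2], 3)  # next smallest pair (3,4)
    expect_equal(m1$tau2[2], 4)
  }
})

test_that("Lance-Williams fast path agrees with the direct set formulas", {
  withr::local_seed(123)
  for (trial in 1:25) {
    n <- sample(3:8, 1)
    v <- randomDistMatrix(n)
    for (method in c("ward", "upgma")) {
      fast <- mergeTable(agglomerate(v, method))
      slow <- directAgglomerate(v, method)
      expect_equal(fast$tau1, slow$tau1)
      expect_equal(fast$tau2, slow$tau2)
      expect_equal(fast$height, slow$height, tolerance = 1e-10)
    }
  }
})

test_that("merge heights are monotone for ward and upgma", {
  withr::local_seed(77)
  for (trial in 1:10) {
    v <- randomDistMatrix(7)
    for (method in c("ward", "upgma")) {
      h <- mergeTable(agglomerate(v, method))$height
      expect_true(all(diff(h) >= -1e-9))
    }
  }
})

test_that("sample order only relabels, never changes the tree", {
  withr::local_seed(31)
  v <- randomDistMatrix(6)
  d1 <- agglomerate(v, "ward")
  perm <- sample(6)
  vp <- v[perm, perm]
  d2 <- agglomerate(vp, "ward")
  sets1 <- lapply(seq_len(11), function(t) sort(offspring(d1, t)))
  sets2 <- lapply(seq_len(11), function(t) sort(offspring(d2, t)))
  # leaves may renumber, but the merged cluster sets and heights coincide
  expect_setequal(sets1[7:11], sets2[7:11])
  expect_equal(sort(mergeTable(d1)$height), sort(mergeTable(d2)$height),
               tolerance = 1e-10)
})

test_that("all five linkage variants run and differ where they should", {
  withr::local_seed(8)
  v <- randomDistMatrix(6)
  hs <- sapply(c("ward", "upgma", "wpgma", "upgmc", "wpgmc"),
               function(m) mergeTable(agglomerate(v, m))$height[5])
  expect_true(all(is.finite(hs)))
  expect_gt(length(unique(round(hs, 6))), 1)
})

test_that("node coordinates put leaves at y=0 and mothers at child midpoints", {
  v <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3,
              dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  d <- agglomerate(v, "upgma")
  co <- nodeCoordinates(d)
  expect_equal(co$y[1:3], rep(0, 3))
  expect_equal(co$x[4], (co$x[1] + co$x[2]) / 2)
  expect_equal(co$x[5], (co$x[4] + co$x[3]) / 2)
  # mother nodes at least as high as children (ward/upgma)
  withr::local_seed(4)
  v6 <- randomDistMatrix(6)
  for (method in c("ward", "upgma")) {
    dd <- agglomerate(v6, method)
    cc <- nodeCoordinates(dd)
    m <- mergeTable(dd)
    for (t in seq_len(5)) {
      expect_gte(cc$y[6 + t] + 1e-9, cc$y[m$tau1[t]])
      expect_gte(cc$y[6 + t] + 1e-9, cc$y[m$tau2[t]])
    }
  }
})

test_that("offspring sets follow the historical cluster list", {
  d <- hscExampleDendrogram()
  expect_equal(offspring(d, 1), "HSC1")
  expect_setequal(offspring(d, 10), c("HSC1", "HSC2", "HSC3", "MPP"))
  expect_setequal(offspring(d, 11),
                  c("HSC1", "HSC2", "HSC3", "MPP", "Mono1", "Mono2"))
  expect_error(offspring(d, 12), "1\\.\\.11")
})

test_that("hclust conversion and merge-table round trips are faithful", {
  withr::local_seed(19)
  v <- randomDistMatrix(5)
  d <- agglomerate(v, "upgma")
  hc <- stats::as.hclust(d)
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height, mergeTable(d)$height)
  expect_length(unique(stats::cutree(hc, k = 5)), 5)

  f <- withr::local_tempfile(fileext = ".tsv")
  writeMergeTable(d, f)
  back <- readMergeTable(f, sampleIds(d))
  expect_equal(mergeTable(back)$tau1, mergeTable(d)$tau1)
  expect_equal(mergeTable(back)$height, mergeTable(d)$height)

  nwk <- withr::local_tempfile(fileext = ".nwk")
  exportNewick(d, nwk)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, sampleIds(d))
})
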
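test_that("tile grids enumerate the documented layouts", {
  gA <- computeTileGrid(2000, 2000, 1000, 100, "A")
  expect_equal(length(gA), 4L)
  expect_setequal(paste(tiles(gA)$r0, tiles(gA)$c0),
                  c("0 0", "0 1000", "1000 0", "1000 1000"))
  gB <- computeTileGrid(2000, 2000, 1000, 100, "B")
  expect_equal(length(gB), 12L)
  expect_equal(gB@shift, 50L)
  expect_equal(sum(tiles(gB)$kind == "base"), 4L)
  gC <- computeTileGrid(1000, 1000, 1000, 100, "C")
  expect_equal(length(gC), 5L)
  expect_equal(sum(tiles(gC)$kind == "base"), 1L)
  expect_error(computeTileGrid(100, 100, 0, 10), "positive")
})

test_that("base tiles cover every pixel and schemes are nested", {
  for (dims in list(c(1500, 1500), c(1000, 700))) {
    cover <- matrix(0L, dims[1], dims[2])
    g <- computeTileGrid(dims[1], dims[2], 600, 51, "A")
    tl <- tiles(g)
    for (i in seq_len(nrow(tl)))
      cover[(tl$r0[i] + 1):tl$r1[i], (tl$c0[i] + 1):tl$c1[i]] <-
        cover[(tl$r0[i] + 1):tl$r1[i], (tl$c0[i] + 1):tl$c1[i]] + 1L
    expect_true(all(cover >= 1L))
    key <- function(s) { t <- tiles(computeTileGrid(dims[1], dims[2], 600, 51, s))
      paste(t$r0 - t$padTop, t$c0 - t$padLeft) }
    expect_true(all(key("A") %in% key("B")))
    expect_true(all(key("B") %in% key("C")))
  }
})

test_that("under scheme B interior base seams are covered by several tiles", {
  g <- computeTileGrid(1000, 1000, 500, 51, "B")
  tl <- tiles(g)
  cover <- matrix(0L, 1000, 1000)
  for (i in seq_len(nrow(tl)))
    cover[(tl$r0[i] + 1):tl$r1[i], (tl$c0[i] + 1):tl$c1[i]] <-
      cover[(tl$r0[i] + 1):tl$r1[i], (tl$c0[i] + 1):tl$c1[i]] + 1L
  # pixels straddling the interior seam at row 500 / col 500
  expect_true(all(cover[500:501, 100] >= 2L))
  expect_true(all(cover[100, 500:501] >= 2L))
})

test_that("tile extraction is exact inside and edge-replicated outside", {
  set.seed(21)
  img <- array(sample(0:255, 300 * 300 * 3, TRUE), c(300, 300, 3))
  g <- computeTileGrid(300, 300, 100, 31, "B")
  tl <- tiles(g)
  inner <- tl[tl$kind == "base" & tl$r0 == 100 & tl$c0 == 100, ][1, ]
  expect_identical(extractTile(img, inner), img[101:200, 101:200, , drop = FALSE])
  # shifted tile at the far edge carries padding, replicating the last column
  far <- tl[tl$padRight > 0, ][1, ]
  patch <- extractTile(img, far)
  expect_equal(dim(patch), c(100L, 100L, 3L))
  lastReal <- 100L - far$padRight
  expect_identical(patch[, lastReal + 1L, ], patch[, lastReal, ])
  # patch centres agree across schemes for the same base anchor
  gA <- computeTileGrid(300, 300, 100, 31, "A")
  baseA <- tiles(gA)[1, ]; baseB <- tl[tl$kind == "base", ][1, ]
  expect_identical(extractTile(img, baseA), extractTile(img, baseB))
})

test_that("two-circle ROI corners land on the stated circles, reproducibly", {
  s <- sampleRoisTwoCircle(center = c(3000, 2500), roiSize = 1000, n = 40, seed = 9)
  d <- sqrt((s$c0 - 3000)^2 + (s$r0 - 2500)^2)
  expect_true(all(abs(d - s$circle) < 1))
  expect_setequal(unique(s$circle), c(500, 2000))
  expect_identical(s, sampleRoisTwoCircle(center = c(3000, 2500),
                                          roiSize = 1000, n = 40, seed = 9))
  empty <- sampleRoisTwoCircle(center = c(0, 0), n = 0)
  expect_equal(nrow(empty), 0L)
})

test_that("patch QC separates tissue from blank and heavily blurred patches", {
  set.seed(50)
  keep <- lapply(1:30, function(s)
    sceneImage(generateScene(sceneSpec("wbcd", height = 128, width = 128,
                                       nNuclei = 6, clusterFraction = 0,
                                       seed = s))))
  blank <- lapply(1:15, function(i) degradePatch(keep[[i]], "blank"))
  blurred <- lapply(16:30, function(i) degradePatch(keep[[i]], "blur", 8))
  patches <- c(keep, blank, blurred)
  labels <- rep(c("keep", "skip"), c(30, 30))
  qc <- trainPatchQC(patches, labels, seed = 3, epochs = 300)
  expect_gte(qc@meta$testAccuracy, 0.9)
  expect_equal(qcPatch(blank[[1]], qc), "skip")
  expect_equal(qcPatch(blurred[[1]], qc), "skip")
  expect_equal(qcPatch(keep[[1]], qc), "keep")
  qc2 <- trainPatchQC(patches, labels, seed = 3, epochs = 300)
  expect_identical(qc@W1, qc2@W1)
  expect_error(trainPatchQC(patches, rep("keep", 60)), "both classes")
  expect_error(trainPatchQC(list(), character()), "empty")
})
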
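test_that("image round trips are exact for PNG and TIFF", {
  set.seed(61)
  img <- array(sample(0:255, 32 * 24 * 3, TRUE), c(32, 24, 3))
  for (ext in c("png", "tiff")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    writeRGBImage(img, f)
    back <- readRGBImage(f)
    expect_equal(unclass(back)[seq_along(img)], as.vector(img))
  }
})

test_that("degenerate image inputs follow the stated contracts", {
  f <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(1, 2, 2), f)          # all-white grayscale
  expect_warning(img <- readRGBImage(f), "grayscale")
  expect_equal(dim(img), c(2L, 2L, 3L))
  expect_true(all(img == 255))
  expect_error(readRGBImage("no/such/file.png"), "not found")
  bad <- withr::local_tempfile(fileext = ".png")
  writeLines("not an image", bad)
  expect_error(readRGBImage(bad), "decodable")
})

test_that("marker tables round-trip exactly and validate input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,class\n10,20,positive", f)
  mk <- readMarkers(f)
  expect_equal(nrow(mk), 1L)
  expect_equal(mk$x, 10); expect_equal(mk$y, 20)
  expect_equal(mk$class, "positive")
  writeLines("x,y,class", f)
  expect_equal(nrow(readMarkers(f)), 0L)
  set.seed(62)
  big <- data.frame(x = sample(0:999, 100, TRUE), y = sample(0:999, 100, TRUE),
                    class = sample(c("positive", "negative"), 100, TRUE))
  writeMarkers(big, f)
  expect_identical(readMarkers(f), big)
  writeLines("x,y\n-3,5", f)
  expect_error(readMarkers(f), "non-negative")
})

test_that("label masks survive the 16-bit round trip bit-exactly", {
  set.seed(63)
  lab <- matrix(sample(0:300, 40 * 30, TRUE), 40, 30)
  f <- withr::local_tempfile(fileext = ".tif")
  writeLabelMask(lab, f)
  expect_identical(readLabelMask(f), matrix(as.integer(lab), 40, 30))
})

test_that("a serialised model predicts identically after reloading", {
  set.seed(64)
  X <- rbind(matrix(rnorm(200), 20, 10), matrix(rnorm(200, 4), 20, 10))
  y <- rep(c("negative", "positive"), each = 20)
  m <- trainClassifier(X, y, seed = 2, epochs = 200, hidden = 5)
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(m, f)
  m2 <- loadModel(f)
  expect_equal(predict(m2, X), predict(m, X))
  expect_identical(m2@classes, m@classes)
})

test_that("a blank image produces zero objects and an empty table", {
  blank <- array(255, c(300, 300, 3))
  res <- runPipeline(blank, pipelineConfig(roiSize = 200, window = 31))
  expect_equal(max(res$labels), 0L)
  expect_equal(nucleusSummary(res$table)$nTotal, 0L)
})

test_that("well-separated nuclei are each detected exactly once", {
  sc <- generateScene(sceneSpec("wbcd", height = 600, width = 600,
                                nNuclei = 30, clusterFraction = 0, seed = 7))
  res <- runPipeline(sceneImage(sc), pipelineConfig(roiSize = 300))
  expect_equal(max(res$labels), 30L)
  counts <- matchObjects(res$labels, gtMarkers(sc))
  expect_equal(counts$TP, 30L)
  expect_equal(counts$FP, 0L)
  expect_equal(counts$FN, 0L)
})

test_that("the pipeline is deterministic and labels objects consecutively", {
  sc <- generateScene(sceneSpec("wbcd", height = 300, width = 300,
                                nNuclei = 10, clusterFraction = 0.2, seed = 3))
  cfg <- pipelineConfig(roiSize = 200, window = 31)
  r1 <- runPipeline(sceneImage(sc), cfg)
  r2 <- runPipeline(sceneImage(sc), cfg)
  expect_identical(r1$labels, r2$labels)
  expect_identical(nucleusRecords(r1$table), nucleusRecords(r2$table))
  n <- max(r1$labels)
  expect_setequal(unique(as.vector(r1$labels)), 0:n)
  expect_true(all(nucleusRecords(r1$table)$area >= 50))
})

test_that("an image smaller than the window is rejected with a hint", {
  expect_error(runPipeline(array(255, c(40, 40, 3)), pipelineConfig()),
               "reduce")
})

test_that("summary bookkeeping ties totals to the class split", {
  rec <- data.frame(label = 1:3, x = 1:3, y = 1:3, area = rep(60, 3),
                    perimeter = rep(30, 3),
                    class = c("positive", "negative", "positive"),
                    probability = c(0.9, 0.8, 0.99))
  tab <- ihcseg:::.makeNucleusTable(rec)
  s <- nucleusSummary(tab)
  expect_equal(s$nTotal, 3L)
  expect_equal(s$nPositive + s$nNegative, s$nTotal)
  expect_equal(s$positiveRatio, 2 / 3)
})
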
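test_that("marker-object matching follows the one-to-one containment rule", {
  lab <- matrix(0L, 20, 20)
  lab[5:8, 5:8] <- 1L
  one <- matchObjects(lab, data.frame(x = 5, y = 5))
  expect_equal(c(one$TP, one$FP, one$FN), c(1L, 0L, 0L))
  two <- matchObjects(lab, data.frame(x = c(5, 6), y = c(5, 6)))
  expect_equal(c(two$TP, two$FP, two$FN), c(1L, 0L, 1L))   # surplus marker
  off <- matchObjects(lab, data.frame(x = 15, y = 15))
  expect_equal(c(off$TP, off$FP, off$FN), c(0L, 1L, 1L))
  expect_error(matchObjects(lab, data.frame(x = 100, y = 2)), "extent")
})

test_that("matching invariants hold on random scenes", {
  set.seed(81)
  for (rep in 1:5) {
    lab <- matrix(0L, 50, 50)
    k <- 0L
    for (i in 1:4) {
      r <- sample(5:40, 1); cc <- sample(5:40, 1); k <- k + 1L
      lab[r:(r + 4), cc:(cc + 4)] <- k
    }
    lab <- removeSmall(lab, 1)
    mk <- data.frame(x = sample(0:49, 8, TRUE), y = sample(0:49, 8, TRUE))
    cts <- matchObjects(lab, mk)
    expect_equal(cts$TP + cts$FN, nrow(mk))
    expect_equal(cts$TP + cts$FP, max(lab))
  }
})

test_that("precision/recall formulas are exact, including the 0/0 rule", {
  expect_equal(unname(detectionMetrics(list(TP = 8, FP = 2, FN = 2))),
               c(0.8, 0.8, 0.8))
  expect_equal(unname(detectionMetrics(list(TP = 0, FP = 0, FN = 5))),
               c(0, 0, 0))
  expect_equal(unname(detectionMetrics(list(TP = 0, FP = 0, FN = 0))),
               c(0, 0, 0))
  # pooled harmonic mean of the benchmark detection row
  f1 <- 2 * 0.707 * 0.816 / (0.707 + 0.816)
  expect_equal(round(f1, 4), 0.7576)
})

test_that("harmonic-mean bounds hold for any counts", {
  set.seed(82)
  for (rep in 1:20) {
    cts <- list(TP = sample(0:20, 1), FP = sample(0:10, 1), FN = sample(0:10, 1))
    m <- detectionMetrics(cts)
    expect_lte(m["F1"], max(m["PPV"], m["TPR"]) + 1e-12)
    expect_gte(min(m["PPV"], m["TPR"]), m["F1"] / 2 - 1e-12)
  }
})

test_that("class-aware matching books mismatches as FP plus FN", {
  lab <- matrix(0L, 20, 20); lab[2:6, 2:6] <- 1L
  rec <- data.frame(label = 1L, class = "positive")
  agree <- classwiseMetrics(lab, rec, data.frame(x = 3, y = 3, class = "positive"))
  expect_equal(agree$TP[agree$class == "positive"], 1L)
  expect_equal(sum(agree$FP), 0L); expect_equal(sum(agree$FN), 0L)
  mism <- classwiseMetrics(lab, rec, data.frame(x = 3, y = 3, class = "negative"))
  expect_equal(mism$FP[mism$class == "positive"], 1L)
  expect_equal(mism$FN[mism$class == "negative"], 1L)
  expect_equal(sum(mism$TP), 0L)
  none <- classwiseMetrics(matrix(0L, 20, 20),
                           rec[0, ],
                           data.frame(x = c(3, 8), y = c(3, 8),
                                      class = c("positive", "negative")))
  expect_true(all(none$TPR == 0))
  expect_error(classwiseMetrics(lab, rec, data.frame(x = 3, y = 3)),
               "class")
})

test_that("pixel-wise metrics respect the evaluation region", {
  gt <- matrix(FALSE, 10, 10); gt[3:6, 3:6] <- TRUE
  expect_equal(unname(pixelMetrics(gt, gt)), c(1, 1, 1))
  pred <- matrix(FALSE, 10, 10); pred[8:9, 8:9] <- TRUE
  expect_equal(unname(pixelMetrics(pred, gt)), c(0, 0, 0))
  half <- gt; half[5:6, ] <- FALSE
  expect_equal(unname(pixelMetrics(half, gt)), c(1, 0.5, 2 / 3))
  # region restriction: disagreement outside the region is invisible
  region <- matrix(FALSE, 10, 10); region[3:6, 3:6] <- TRUE
  expect_equal(unname(pixelMetrics(half, gt, region)), c(1, 0.5, 2 / 3))
  expect_error(pixelMetrics(gt, gt[1:5, ]), "shape")
})

test_that("a parameter sweep scores each value and finds an interior optimum", {
  scenes <- lapply(c(301, 302), function(s)
    generateScene(sceneSpec("wbcd", height = 300, width = 300, nNuclei = 12,
                            clusterFraction = 0.2, seed = s)))
  imgs <- lapply(scenes, sceneImage)
  mks <- lapply(scenes, gtMarkers)
  cfg <- pipelineConfig(roiSize = 200, window = 31, acIterations = 15)
  single <- sweepParameter(imgs, mks, "splitT", values = 3, cfg = cfg)
  expect_equal(nrow(single@points), 1L)
  crv <- sweepParameter(imgs, mks, "splitT", values = c(2, 3, 12), cfg = cfg,
                        cv = TRUE, seed = 4)
  expect_equal(nrow(crv@points), 3L)
  expect_true(all(crv@points$F1 >= 0) && all(crv@points$F1 <= 1))
  expect_true(crv@best %in% c(2, 3, 12))
  # an absurdly high start level cannot beat a sensible one
  expect_lt(crv@points$F1[crv@points$value == 12],
            max(crv@points$F1[crv@points$value %in% c(2, 3)]) + 1e-12)
  expect_equal(nrow(crv@cv), 2L)
  crv2 <- sweepParameter(imgs, mks, "splitT", values = c(2, 3, 12), cfg = cfg,
                         cv = TRUE, seed = 4)
  expect_identical(crv@points, crv2@points)
  expect_error(sweepParameter(imgs, mks, "splitT", numeric(), cfg), "empty")
})
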
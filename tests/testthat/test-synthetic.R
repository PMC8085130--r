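test_that("scenes carry exact, consistent ground truth", {
  sc <- generateScene(sceneSpec("iispv", height = 600, width = 600,
                                nNuclei = 50, clusterFraction = 0.3, seed = 3))
  lab <- gtLabels(sc); mk <- gtMarkers(sc)
  expect_equal(nrow(mk), 50L)
  expect_equal(max(lab), 50L)
  # every marker inside exactly its own label; labels pairwise disjoint by
  # construction (one integer per pixel)
  expect_identical(lab[cbind(mk$y + 1L, mk$x + 1L)], 1:50)
  expect_true(all(tabulate(lab[lab > 0L], nbins = 50) > 0L))
  # reproducibility
  sc2 <- generateScene(sceneSpec("iispv", height = 600, width = 600,
                                 nNuclei = 50, clusterFraction = 0.3, seed = 3))
  expect_identical(sceneImage(sc2), sceneImage(sc))
  expect_identical(gtLabels(sc2), lab)
})

test_that("presets reproduce the benchmark shape statistics", {
  measure <- function(preset, side) {
    sc <- generateScene(sceneSpec(preset, height = side, width = side,
                                  nNuclei = 200, clusterFraction = 0, seed = 11))
    lab <- gtLabels(sc)
    h <- nrow(lab); idx <- which(lab > 0L)
    rows <- (idx - 1L) %% h + 1L; cols <- (idx - 1L) %/% h + 1L
    circ <- vapply(seq_len(max(lab)), function(id) {
      s <- lab[idx] == id
      ihcseg:::.geometricFeatures(rows[s], cols[s])[["circularity"]]
    }, numeric(1))
    c(area = mean(tabulate(lab[lab > 0L])), circ = mean(circ))
  }
  iispv <- measure("iispv", 1400)
  expect_gte(iispv["area"], 311 - 35); expect_lte(iispv["area"], 311 + 35)
  expect_gte(iispv["circ"], 0.50 - 0.07); expect_lte(iispv["circ"], 0.50 + 0.07)
  wbcd <- measure("wbcd", 900)
  expect_gte(wbcd["area"], 144 - 11); expect_lte(wbcd["area"], 144 + 11)
  expect_gte(wbcd["circ"], 0.70 - 0.08); expect_lte(wbcd["circ"], 0.70 + 0.08)
})

test_that("nuclei are darker than background with a clear margin", {
  for (preset in c("iispv", "wbcd")) {
    sc <- generateScene(sceneSpec(preset, height = 500, width = 500,
                                  nNuclei = 30, clusterFraction = 0.3, seed = 9))
    v <- valueChannel(sceneImage(sc))
    nuc <- v[gtLabels(sc) > 0L]; bg <- v[gtLabels(sc) == 0L]
    expect_lt(quantile(nuc, 0.99), quantile(bg, 0.01))
  }
})

test_that("infeasible packing is refused", {
  expect_error(generateScene(sceneSpec("iispv", height = 100, width = 100,
                                       nNuclei = 100, seed = 1)),
               "packing")
})

test_that("patch degradation behaves as documented", {
  sc <- generateScene(sceneSpec("wbcd", height = 128, width = 128,
                                nNuclei = 6, clusterFraction = 0, seed = 21))
  patch <- sceneImage(sc)
  expect_identical(degradePatch(patch, "blur", 0), patch)
  set.seed(1)
  blank <- degradePatch(patch, "blank")
  v <- valueChannel(blank)
  expect_equal(sum(bradleyThreshold(v, 51, 15)), 0)   # nothing to segment
  lapEnergy <- function(p) {
    v <- valueChannel(p)
    lap <- 4 * v[2:127, 2:127] - v[1:126, 2:127] - v[3:128, 2:127] -
      v[2:127, 1:126] - v[2:127, 3:128]
    mean(lap^2)
  }
  blurred <- degradePatch(patch, "blur", 8)
  expect_lt(lapEnergy(blurred), lapEnergy(patch))
  expect_error(degradePatch(patch, "wobble"), "arg")
})
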
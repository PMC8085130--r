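test_that("the descriptor has the documented layout and finite values", {
  sc <- generateScene(sceneSpec("wbcd", height = 200, width = 200,
                                nNuclei = 5, clusterFraction = 0, seed = 2))
  fv <- extractFeatures(sceneImage(sc), gtLabels(sc), 1L)
  expect_length(fv, 309L)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), featureNames(FALSE))
  # per-channel blocks: 11 geometric + 9 HOG + 44 GLRLM + 5 AR + 20 Haar +
  # 5 gradient + 9 histogram = 103
  expect_equal(sum(startsWith(names(fv), "R_")), 103L)
  fvD <- extractFeatures(sceneImage(sc), gtLabels(sc), 1L, dedupGeometric = TRUE)
  expect_length(fvD, 287L)
  expect_error(extractFeatures(sceneImage(sc), gtLabels(sc), 99L), "does not exist")
})

test_that("geometric features are channel-independent and near-analytic for a disk", {
  img <- array(128, c(60, 60, 3))
  lab <- matrix(0L, 60, 60)
  lab[diskMask(60, 30, 30, 12)] <- 1L
  fv <- extractFeatures(img, lab, 1L)
  circ <- fv[["R_geom_circularity"]]
  expect_gte(circ, 0.85); expect_lte(circ, 1.1)
  expect_equal(fv[["R_geom_area"]], sum(lab))
  for (nm in featureNames(TRUE)[1:11]) {
    base <- sub("geom_", "", nm)
    expect_equal(fv[[paste0("R_geom_", base)]], fv[[paste0("G_geom_", base)]])
    expect_equal(fv[[paste0("R_geom_", base)]], fv[[paste0("B_geom_", base)]])
  }
})

test_that("the descriptor is deterministic and translation invariant", {
  sc <- generateScene(sceneSpec("wbcd", height = 200, width = 200,
                                nNuclei = 4, clusterFraction = 0, seed = 5))
  img <- sceneImage(sc); lab <- gtLabels(sc)
  expect_identical(extractFeatures(img, lab, 2L), extractFeatures(img, lab, 2L))
  # translate the whole scene by (7, 11): everything except nothing changes
  img2 <- array(200, c(200, 200, 3)); lab2 <- matrix(0L, 200, 200)
  img2[8:200, 12:200, ] <- img[1:193, 1:189, ]
  lab2[8:200, 12:200] <- lab[1:193, 1:189]
  # pick an object whose 64 px texture window stays strictly interior in
  # both layouts, so no border clamping or fill pixels differ
  keep <- which(tabulate(lab2[lab2 > 0L], nbins = max(lab)) ==
                  tabulate(lab[lab > 0L], nbins = max(lab)))
  cent <- t(vapply(keep, function(id) {
    w <- which(lab == id, arr.ind = TRUE); colMeans(w)
  }, numeric(2)))
  id <- keep[which(cent[, 1] > 40 & cent[, 1] < 150 &
                     cent[, 2] > 40 & cent[, 2] < 150)][1]
  f1 <- extractFeatures(img, lab, id)
  f2 <- extractFeatures(img2, lab2, id)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-12)
})

test_that("training on separable features reaches near-perfect held-out accuracy", {
  set.seed(71)
  n <- 1000
  X <- rbind(matrix(rnorm(n / 2 * 20, 0), n / 2, 20),
             matrix(rnorm(n / 2 * 20, 5), n / 2, 20))
  y <- rep(c("negative", "positive"), each = n / 2)
  m <- trainClassifier(X, y, seed = 4, epochs = 1000)
  expect_gte(m@meta$testAccuracy, 0.99)
  m2 <- trainClassifier(X, y, seed = 4, epochs = 1000)
  expect_identical(m@W1, m2@W1)
  expect_identical(m@W2, m2@W2)
  expect_error(trainClassifier(X, rep("positive", n)), "both classes")
  few <- c(1:5, (n / 2 + 1):(n / 2 + 5))
  expect_error(trainClassifier(X[few, ], y[few]), "at least 20")
})

test_that("an established optimiser agrees on the same separable problem", {
  set.seed(72)
  X <- rbind(matrix(rnorm(600, 0), 100, 6), matrix(rnorm(600, 4), 100, 6))
  y <- factor(rep(c("negative", "positive"), each = 100))
  ours <- trainClassifier(X, y, seed = 3, epochs = 500, hidden = 10)
  ref <- nnet::nnet(X, class.ind <- diag(2)[as.integer(y), ], size = 10,
                    softmax = TRUE, trace = FALSE, maxit = 300)
  refAcc <- mean(levels(y)[max.col(predict(ref, X))] == as.character(y))
  ourAcc <- mean(predict(ours, X)$class == as.character(y))
  expect_gte(ourAcc, 0.99)
  expect_gte(refAcc, 0.99)
  expect_lte(abs(ourAcc - refAcc), 0.02)
})

test_that("prediction is the softmax argmax with its probability", {
  m <- new("MLPModel",
           W1 = matrix(0, 2, 3), b1 = rep(0, 3),
           W2 = matrix(c(1, 0, 0, 0, 0, 0), 3, 2), b2 = c(log(4), 0),
           center = c(0, 0), scale = c(1, 1),
           classes = c("positive", "negative"), featureNames = character(),
           meta = list())
  p <- predict(m, c(0, 0))
  # hidden activations 0.5 each; logits (log4 + 0.5, 0) -> known softmax
  expect_equal(p$class, "positive")
  expect_equal(p$probability, exp(log(4) + 0.5) / (exp(log(4) + 0.5) + 1))
  # symmetric weights give an exact tie, broken to the first class
  mSym <- m; mSym@W2 <- matrix(0, 3, 2); mSym@b2 <- c(0, 0)
  pSym <- predict(mSym, c(1, 1))
  expect_equal(pSym$probability, 0.5)
  expect_equal(pSym$class, "positive")
  # batch prediction equals the map of single predictions
  X <- matrix(rnorm(10), 5, 2)
  batch <- predict(m, X)
  singles <- do.call(rbind, lapply(1:5, function(i) predict(m, X[i, ])))
  expect_equal(batch, singles, ignore_attr = TRUE)
  expect_error(predict(m, c(1, 2, 3)), "does not match")
})

test_that("softmax outputs are normalised", {
  set.seed(73)
  X <- rbind(matrix(rnorm(100), 10, 10), matrix(rnorm(100, 3), 10, 10))
  m <- trainClassifier(X, rep(c("a", "b"), each = 10), seed = 1, epochs = 50,
                       hidden = 4)
  P <- ihcseg:::mlpForward(m, X)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("nucleus colour classes are recovered on held-out synthetic objects", {
  model <- trainedClassifier()
  expect_gte(model@meta$testAccuracy, 0.95)
})
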
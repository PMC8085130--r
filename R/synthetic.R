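# Synthetic DAB&H scene generation with exact ground truth. Nuclei are
# randomly oriented ellipses; their area and circularity follow normal laws
# matching the measured shape statistics of the two benchmark stains, and a
# configurable share is placed overlapping a neighbour to exercise cluster
# splitting. Scenes carry per-nucleus labels and centroid markers, so every
# pipeline stage can be scored without external data.

# Analytic circularity of an ellipse with axis ratio q = b/a (Ramanujan
# perimeter approximation); monotone increasing from 0 to 1.
.ellipseCircularity <- function(q) {
  a <- 1; b <- q
  hh <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * hh / (10 + sqrt(4 - 3 * hh)))
  4 * pi * (pi * a * b) / P^2
}

.axisRatioForCircularity <- function(circ) {
  circ <- min(max(circ, 0.05), 0.999)
  uniroot(function(q) .ellipseCircularity(q) - circ,
          lower = 1e-3, upper = 1, tol = 1e-6)$root
}

# Digitisation bias of the measured circularity at a given nucleus size:
# rasterising a small ellipse perturbs the digital perimeter, so the measured
# circularity differs from the analytic target. The offset is estimated once
# per scene by rasterising reference ellipses of the mean area/circularity at
# evenly spread orientations, and the sampled targets are shifted by it.
.circularityBias <- function(areaMean, circMean) {
  q <- .axisRatioForCircularity(circMean)
  a <- sqrt(areaMean / (pi * q)); b <- a * q
  side <- ceiling(2 * a + 8)
  meas <- vapply(seq(0, pi, length.out = 9L)[-9L], function(th) {
    idx <- .ellipsePixels(side / 2, side / 2, a, b, th, side, side)
    rows <- (idx - 1L) %% side + 1L; cols <- (idx - 1L) %/% side + 1L
    .geometricFeatures(rows, cols)[["circularity"]]
  }, numeric(1))
  mean(meas) - circMean
}

#' Describe a synthetic DAB&H scene
#'
#' Builds a \code{\link{SceneSpec}}. The presets pin the nucleus shape laws
#' to the measured statistics of the two benchmark stains — "iispv"
#' (breast-cancer FOXP3, area 311 +/- 35 px, circularity 0.50 +/- 0.07) and
#' "wbcd" (pancreas beta cells, area 144 +/- 11 px, circularity
#' 0.70 +/- 0.08) — and leave everything else at the defaults.
#'
#' @param preset "custom", "iispv" or "wbcd".
#' @param height,width scene size in px.
#' @param nNuclei nucleus count.
#' @param positiveFraction fraction of DAB-brown (immunopositive) nuclei.
#' @param clusterFraction share of nuclei placed overlapping a neighbour
#'   (by 20-40 percent of its equivalent radius).
#' @param areaMean,areaSd,circMean,circSd shape laws (preset values are
#'   used unless preset = "custom").
#' @param backgroundV background Value level.
#' @param positiveHSV,negativeHSV class colours (h, s, v).
#' @param noiseSd Gaussian pixel noise sd on [0,1] channels.
#' @param blurSigma Gaussian blur sd in px.
#' @param seed integer seed.
#' @return a \code{SceneSpec}.
#' @export
sceneSpec <- function(preset = c("custom", "iispv", "wbcd"),
                      height = 1000L, width = 1000L, nNuclei = 100L,
                      positiveFraction = 0.5, clusterFraction = 0.3,
                      areaMean = 311, areaSd = 35, circMean = 0.50,
                      circSd = 0.07, backgroundV = 0.92,
                      positiveHSV = c(0.07, 0.75, 0.45),
                      negativeHSV = c(0.60, 0.55, 0.38),
                      noiseSd = 0.02, blurSigma = 0.5, seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "iispv") { areaMean <- 311; areaSd <- 35; circMean <- 0.50; circSd <- 0.07 }
  if (preset == "wbcd") { areaMean <- 144; areaSd <- 11; circMean <- 0.70; circSd <- 0.08 }
  new("SceneSpec", height = as.integer(height), width = as.integer(width),
      nNuclei = as.integer(nNuclei), positiveFraction = positiveFraction,
      areaMean = areaMean, areaSd = areaSd, circMean = circMean,
      circSd = circSd, clusterFraction = clusterFraction,
      backgroundV = backgroundV, positiveHSV = positiveHSV,
      negativeHSV = negativeHSV, noiseSd = noiseSd, blurSigma = blurSigma,
      seed = as.integer(seed), preset = preset)
}

# Distance from an ellipse's centre to its boundary along direction phi.
.ellipseSupport <- function(a, b, theta, phi) {
  a * b / sqrt((b * cos(phi - theta))^2 + (a * sin(phi - theta))^2)
}

# Rasterise one ellipse; returns linear indices of its pixels.
.ellipsePixels <- function(cy, cx, a, b, theta, h, w) {
  rr <- max(1L, floor(cy - a - 1)):min(h, ceiling(cy + a + 1))
  cc <- max(1L, floor(cx - a - 1)):min(w, ceiling(cx + a + 1))
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  sel <- (u / a)^2 + (v / b)^2 <= 1
  ri <- matrix(rr, length(rr), length(cc))[sel]
  ci <- matrix(cc, length(rr), length(cc), byrow = TRUE)[sel]
  (ci - 1L) * h + ri
}

.hsv2rgbRow <- function(hsvRow) as.vector(grDevices::col2rgb(
  grDevices::hsv(hsvRow[1L], hsvRow[2L], hsvRow[3L]))) / 255

#' Generate a synthetic DAB&H scene with exact ground truth
#'
#' Draws nucleus areas from Normal(areaMean, areaSd) (truncated positive)
#' and circularities from Normal(circMean, circSd); each nucleus becomes a
#' randomly oriented ellipse whose axis ratio reproduces its sampled
#' circularity. A \code{clusterFraction} share is placed to overlap a
#' previously placed nucleus by 20-40 percent of its equivalent radius;
#' the remainder are placed disjoint. Later nuclei are rendered on top
#' (z-order), and ground-truth labels follow the same order, so labels are
#' pairwise disjoint even where rendered nuclei touch. Each class is
#' coloured in HSV (DAB brown for positive, hematoxylin blue for negative,
#' both strictly darker than the background in Value), then Gaussian pixel
#' noise and Gaussian blur are applied. Reproducible given the spec seed.
#'
#' @param spec a \code{\link{SceneSpec}}.
#' @return a \code{\link{SyntheticScene}}: image (0..255 RGB array),
#'   gtLabels, gtMarkers (0-based centroids with classes) and the spec.
#' @examples
#' sc <- generateScene(sceneSpec("wbcd", height = 256, width = 256,
#'                               nNuclei = 10, seed = 3))
#' nrow(gtMarkers(sc))  # 10
#' @export
generateScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  h <- spec@height; w <- spec@width; n <- spec@nNuclei
  if (n * spec@areaMean > 0.4 * h * w)
    stop("infeasible packing: requested nuclei exceed 40% of the scene area",
         call. = FALSE)
  set.seed(spec@seed)
  circBias <- .circularityBias(spec@areaMean, spec@circMean)
  for (attempt in 1:25) {
    areas <- numeric(n); circs <- numeric(n)
    for (i in seq_len(n)) {
      repeat { areas[i] <- rnorm(1, spec@areaMean, spec@areaSd); if (areas[i] > 60) break }
      circs[i] <- min(max(rnorm(1, spec@circMean, spec@circSd) - circBias,
                          0.15), 0.95)
    }
    q <- vapply(circs, .axisRatioForCircularity, numeric(1))
    aAx <- sqrt(areas / (pi * q)); bAx <- aAx * q
    theta <- runif(n, 0, pi)
    nPos <- round(spec@positiveFraction * n)
    cls <- sample(c(rep("positive", nPos), rep("negative", n - nPos)))
    nClu <- round(spec@clusterFraction * n)
    clustered <- c(rep(FALSE, n - nClu), rep(TRUE, nClu))
    cy <- numeric(n); cx <- numeric(n)
    rEq <- sqrt(areas / pi)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:400) {
        if (!clustered[i]) {
          yi <- runif(1, aAx[i] + 2, h - aAx[i] - 1)
          xi <- runif(1, aAx[i] + 2, w - aAx[i] - 1)
          if (i > 1L) {
            prev <- seq_len(i - 1L)
            if (any(sqrt((cy[prev] - yi)^2 + (cx[prev] - xi)^2) <
                    aAx[prev] + aAx[i] + 2)) next
          }
        } else {
          host <- sample(which(!clustered[seq_len(i - 1L)]), 1L)
          ov <- runif(1, 0.2, 0.4)
          phi <- runif(1, 0, 2 * pi)
          # the centre distance uses each ellipse's support radius along the
          # contact direction, so the 20-40% overlap is a shallow lens at the
          # touching boundaries rather than a non-physical interpenetration
          # of the two bodies (for circular nuclei this reduces to the
          # equivalent-radius rule)
          rH <- .ellipseSupport(aAx[host], bAx[host], theta[host], phi)
          rG <- .ellipseSupport(aAx[i], bAx[i], theta[i], phi)
          d <- rH + rG - ov * min(rG, rH)
          yi <- cy[host] + d * sin(phi); xi <- cx[host] + d * cos(phi)
          if (yi < aAx[i] + 2 || yi > h - aAx[i] - 1 ||
              xi < aAx[i] + 2 || xi > w - aAx[i] - 1) next
        }
        cy[i] <- yi; cx[i] <- xi; placed <- TRUE; break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (!ok) next
    gtLabels <- matrix(0L, h, w)
    pixList <- vector("list", n)
    for (i in seq_len(n)) {
      pixList[[i]] <- .ellipsePixels(cy[i], cx[i], aAx[i], bAx[i], theta[i], h, w)
      gtLabels[pixList[[i]]] <- i  # z-order: later nuclei on top
    }
    if (any(tabulate(gtLabels[gtLabels > 0L], nbins = n) == 0L)) next
    # markers: visible pixel of each label closest to its visible centroid
    mx <- numeric(n); my <- numeric(n)
    for (i in seq_len(n)) {
      idx <- which(gtLabels == i)
      ri <- (idx - 1L) %% h + 1L; ci <- (idx - 1L) %/% h + 1L
      j <- which.min((ri - mean(ri))^2 + (ci - mean(ci))^2)
      my[i] <- ri[j] - 1L; mx[i] <- ci[j] - 1L
    }
    # render
    bgRGB <- .hsv2rgbRow(c(0.08, 0.04, spec@backgroundV))
    planes <- lapply(bgRGB, function(x) matrix(x, h, w))
    for (i in seq_len(n)) {
      base <- if (cls[i] == "positive") spec@positiveHSV else spec@negativeHSV
      vJit <- min(max(base[3L] + rnorm(1, 0, 0.02), 0.05),
                  spec@backgroundV - 0.25)
      rgb <- .hsv2rgbRow(c(base[1L], base[2L], vJit))
      for (ch in 1:3) planes[[ch]][pixList[[i]]] <- rgb[ch]
    }
    for (ch in 1:3) {
      if (spec@noiseSd > 0)
        planes[[ch]] <- planes[[ch]] + matrix(rnorm(h * w, 0, spec@noiseSd), h, w)
      if (spec@blurSigma > 0)
        planes[[ch]] <- EBImage::gblur(planes[[ch]], spec@blurSigma)
    }
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- planes[[ch]]
    img <- round(pmin(pmax(img, 0), 1) * 255)
    markers <- data.frame(x = mx, y = my, class = cls, stringsAsFactors = FALSE)
    return(new("SyntheticScene", image = img, gtLabels = gtLabels,
               gtMarkers = markers, spec = spec))
  }
  stop("could not place all nuclei; reduce nNuclei or clusterFraction",
       call. = FALSE)
}

#' Degrade a patch for quality-control training
#'
#' \code{mode = "blank"} replaces the patch with background colour plus
#' Gaussian noise (an empty, tissue-free patch); \code{mode = "blur"}
#' applies a Gaussian blur of sd \code{magnitude} px (a heavily defocused
#' patch when magnitude is large; magnitude 0 returns the patch unchanged).
#'
#' @param patch RGB array (0..255).
#' @param mode "blank" or "blur".
#' @param magnitude blur sd in px, or noise sd (on [0,1]) for blank mode
#'   (default 0.02).
#' @return degraded RGB array (0..255).
#' @export
degradePatch <- function(patch, mode = c("blank", "blur"), magnitude = NULL) {
  .assertRGB(patch)
  mode <- match.arg(mode)
  h <- dim(patch)[1L]; w <- dim(patch)[2L]
  if (mode == "blank") {
    if (is.null(magnitude)) magnitude <- 0.02
    bgRGB <- .hsv2rgbRow(c(0.08, 0.04, 0.92))
    img <- array(rep(bgRGB, each = h * w), c(h, w, 3L))
    img <- img + array(rnorm(length(img), 0, magnitude), dim(img))
    return(round(pmin(pmax(img, 0), 1) * 255))
  }
  if (is.null(magnitude)) stop("blur mode needs a magnitude", call. = FALSE)
  if (magnitude == 0) return(patch)
  out <- patch / 255
  for (ch in 1:3) out[, , ch] <- EBImage::gblur(out[, , ch], magnitude)
  round(pmin(pmax(out, 0), 1) * 255)
}
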
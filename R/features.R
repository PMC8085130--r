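# The per-object descriptor: 103 features per RGB channel (11 geometric,
# 9 HOG, 44 GLRLM, 5 autoregression, 20 Haar wavelet, 5 gradient,
# 9 histogram), 309 in total. Geometric features derive from the label
# geometry and are therefore identical across channels; texture blocks are
# computed on a 64x64 window centred at the object centroid with non-object
# pixels masked to the window's background mean.

.momentStats <- function(x) {
  m <- mean(x); v <- mean((x - m)^2)
  if (v < 1e-24) return(c(mean = m, variance = v, skewness = 0, kurtosis = 0))
  c(mean = m, variance = v,
    skewness = mean((x - m)^3) / v^1.5,
    kurtosis = mean((x - m)^4) / v^2)
}

# -- geometric (11): area, perimeter, circularity, eccentricity, major/minor
#    axis, equivalent diameter, solidity, extent, convex area, orientation.
.geometricFeatures <- function(rows, cols) {
  area <- length(rows)
  r0 <- min(rows); c0 <- min(cols)
  crop <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
  crop[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
  per <- maskPerimeter(crop)
  circ <- if (per > 0) 4 * pi * area / per^2 else 0
  mu20 <- mean((rows - mean(rows))^2); mu02 <- mean((cols - mean(cols))^2)
  mu11 <- mean((rows - mean(rows)) * (cols - mean(cols)))
  tr <- mu20 + mu02
  disc <- sqrt(max(0, (mu20 - mu02)^2 + 4 * mu11^2))
  l1 <- (tr + disc) / 2; l2 <- (tr - disc) / 2
  major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
  ecc <- if (l1 > 1e-12) sqrt(max(0, 1 - l2 / l1)) else 0
  orient <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  pts <- unique(cbind(rows, cols))
  convexArea <- if (nrow(pts) >= 3L) {
    hull <- grDevices::chull(pts[, 2L], pts[, 1L])
    hx <- pts[hull, 2L]; hy <- pts[hull, 1L]
    a <- abs(sum(hx * c(hy[-1L], hy[1L]) - c(hx[-1L], hx[1L]) * hy)) / 2
    hp <- sum(sqrt(diff(c(hx, hx[1L]))^2 + diff(c(hy, hy[1L]))^2))
    a + hp / 2 + 1  # pixel-count estimate of the filled hull
  } else area
  c(area = area, perimeter = per, circularity = circ, eccentricity = ecc,
    majorAxis = major, minorAxis = minor,
    equivDiameter = 2 * sqrt(area / pi),
    solidity = area / max(convexArea, area),
    extent = area / (nrow(crop) * ncol(crop)),
    convexArea = convexArea, orientation = orient)
}

.gradients <- function(I) {
  gx <- (shiftMatrix(I, 0L, -1L, NA) - shiftMatrix(I, 0L, 1L, NA)) / 2
  gy <- (shiftMatrix(I, -1L, 0L, NA) - shiftMatrix(I, 1L, 0L, NA)) / 2
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# -- HOG (9): signed-orientation 9-bin histogram of gradient directions,
#    magnitude-weighted, L2-normalised.
.hogFeatures <- function(g) {
  ang <- atan2(g$gy, g$gx) %% (2 * pi)
  bin <- pmin(8L, as.integer(ang / (2 * pi / 9)))
  h <- vapply(0:8, function(b) sum(g$mag[bin == b]), numeric(1))
  h <- h / sqrt(sum(h^2) + 1e-12)
  names(h) <- paste0("hog", 1:9)
  h
}

# -- gradient (5): magnitude moments + nonzero fraction.
.gradientFeatures <- function(g) {
  s <- .momentStats(as.vector(g$mag))
  c(gradMean = unname(s["mean"]), gradVariance = unname(s["variance"]),
    gradSkewness = unname(s["skewness"]), gradKurtosis = unname(s["kurtosis"]),
    gradNonzero = mean(g$mag > 1e-12))
}

# -- histogram (9): moments + percentiles 1/10/50/90/99.
.histogramFeatures <- function(I) {
  s <- .momentStats(as.vector(I))
  q <- quantile(I, c(0.01, 0.1, 0.5, 0.9, 0.99), names = FALSE, type = 7)
  out <- c(s, q)
  names(out) <- c("histMean", "histVariance", "histSkewness", "histKurtosis",
                  paste0("histP", c(1, 10, 50, 90, 99)))
  out
}

# Run-length list (gray level, run length) for one direction given a list of
# scan lines (integer vectors of quantised levels).
.runs <- function(lines) {
  gl <- lapply(lines, function(v) {
    r <- rle(v)
    cbind(r$values, r$lengths)
  })
  do.call(rbind, gl)
}

# -- GLRLM (44): 11 classic run-length statistics for each of the four
#    principal directions (0, 45, 90, 135 degrees), 16 gray levels.
.glrlmFeatures <- function(I, nLevels = 16L) {
  q <- matrix(pmin(nLevels - 1L, as.integer(I * nLevels)) + 1L, nrow(I), ncol(I))
  h <- nrow(q); w <- ncol(q)
  ri <- matrix(seq_len(h), h, w); ci <- matrix(seq_len(w), h, w, byrow = TRUE)
  dirs <- list(
    d0   = split(as.vector(t(q)), rep(seq_len(h), each = w)),   # along rows
    d90  = split(as.vector(q), rep(seq_len(w), each = h)),      # along columns
    d45  = split(as.vector(q), as.vector(ri + ci)),             # anti-diagonal
    d135 = split(as.vector(q), as.vector(ri - ci)))             # main diagonal
  np <- length(q)
  out <- numeric(0)
  for (dn in names(dirs)) {
    rl <- .runs(dirs[[dn]])
    g <- rl[, 1L]; l <- rl[, 2L]; nr <- nrow(rl)
    stats <- c(
      SRE = sum(1 / l^2), LRE = sum(l^2),
      GLN = sum(tapply(rep(1, nr), g, sum)^2),
      RLN = sum(tapply(rep(1, nr), l, sum)^2),
      RP = nr / np * nr,  # placeholder scale fixed below
      LGRE = sum(1 / g^2), HGRE = sum(g^2),
      SRLGE = sum(1 / (g^2 * l^2)), SRHGE = sum(g^2 / l^2),
      LRLGE = sum(l^2 / g^2), LRHGE = sum(g^2 * l^2))
    stats <- stats / nr
    stats["RP"] <- nr / np
    names(stats) <- paste(dn, names(stats), sep = "_")
    out <- c(out, stats)
  }
  out
}

# -- autoregression (5): least-squares causal AR parameters for the four
#    causal neighbours (W, NW, N, NE) plus the residual standard deviation.
.arFeatures <- function(I) {
  h <- nrow(I); w <- ncol(I)
  y <- as.vector(I[2:h, 2:(w - 1)])
  X <- cbind(W = as.vector(I[2:h, 1:(w - 2)]),
             NW = as.vector(I[1:(h - 1), 1:(w - 2)]),
             N = as.vector(I[1:(h - 1), 2:(w - 1)]),
             NE = as.vector(I[1:(h - 1), 3:w]))
  theta <- tryCatch(solve(crossprod(X) + diag(1e-9, 4L), crossprod(X, y)),
                    error = function(e) matrix(0, 4L, 1L))
  res <- y - X %*% theta
  c(arW = theta[1L], arNW = theta[2L], arN = theta[3L], arNE = theta[4L],
    arResidSd = sd(as.vector(res)))
}

.haarStep <- function(M) {
  ro <- seq(1L, nrow(M), by = 2L); re <- ro + 1L
  co <- seq(1L, ncol(M), by = 2L); ce <- co + 1L
  L <- (M[ro, , drop = FALSE] + M[re, , drop = FALSE]) / sqrt(2)
  H <- (M[ro, , drop = FALSE] - M[re, , drop = FALSE]) / sqrt(2)
  list(LL = (L[, co, drop = FALSE] + L[, ce, drop = FALSE]) / sqrt(2),
       LH = (L[, co, drop = FALSE] - L[, ce, drop = FALSE]) / sqrt(2),
       HL = (H[, co, drop = FALSE] + H[, ce, drop = FALSE]) / sqrt(2),
       HH = (H[, co, drop = FALSE] - H[, ce, drop = FALSE]) / sqrt(2))
}

# -- Haar (20): subband energies (mean squared coefficient) of LL/LH/HL/HH
#    over a 5-level Haar decomposition of the 64x64 window.
.haarFeatures <- function(I, levels = 5L) {
  out <- numeric(0)
  M <- I
  for (lev in seq_len(levels)) {
    sb <- .haarStep(M)
    e <- vapply(sb, function(x) mean(x^2), numeric(1))
    names(e) <- paste0("haarL", lev, "_", names(sb))
    out <- c(out, e)
    M <- sb$LL
  }
  out
}

.channelTextureFeatures <- function(I) {
  g <- .gradients(I)
  c(.hogFeatures(g), .glrlmFeatures(I), .arFeatures(I), .haarFeatures(I),
    .gradientFeatures(g), .histogramFeatures(I))
}

#' Names of the object descriptor features
#'
#' @param dedupGeometric if TRUE the 11 geometric features (identical
#'   across channels by construction) appear once, giving 11 + 92 x 3 = 287
#'   names; the default FALSE keeps the full 103-feature block per channel
#'   (309 names).
#' @return character vector of feature names.
#' @export
featureNames <- function(dedupGeometric = FALSE) {
  geom <- c("area", "perimeter", "circularity", "eccentricity", "majorAxis",
            "minorAxis", "equivDiameter", "solidity", "extent", "convexArea",
            "orientation")
  tex <- names(.channelTextureFeatures(matrix(runif(64 * 64), 64L, 64L)))
  if (dedupGeometric)
    c(paste0("geom_", geom),
      unlist(lapply(c("R", "G", "B"), function(ch) paste0(ch, "_", tex))))
  else
    unlist(lapply(c("R", "G", "B"), function(ch)
      paste0(ch, "_", c(paste0("geom_", geom), tex))))
}

#' Extract the shape/texture descriptor of one detected object
#'
#' Computes the 103-feature block for each RGB channel of the object:
#' 11 geometric features from the label geometry (hence identical across
#' channels), then 9 HOG, 44 gray-level run-length, 5 autoregression,
#' 20 Haar-wavelet, 5 gradient and 9 histogram features from a 64x64
#' window centred at the object centroid in which non-object pixels are
#' replaced by the window's background mean. The extraction is
#' deterministic and translation-invariant (the window moves with the
#' object).
#'
#' @param image RGB array (0..255) the labels refer to.
#' @param labels integer label matrix.
#' @param labelId id of the object to describe.
#' @param dedupGeometric drop the redundant per-channel copies of the
#'   geometric block (287 values instead of 309).
#' @param windowSize texture window side, px (default 64; must be a
#'   multiple of 32 for the 5-level wavelet).
#' @return named numeric feature vector.
#' @export
extractFeatures <- function(image, labels, labelId, dedupGeometric = FALSE,
                            windowSize = 64L) {
  .assertRGB(image)
  stopifnot(identical(dim(image)[1:2], dim(labels)))
  idx <- which(labels == labelId)
  if (length(idx) == 0L)
    stop("label ", labelId, " does not exist in the mask", call. = FALSE)
  h <- nrow(labels); w <- ncol(labels)
  rows <- (idx - 1L) %% h + 1L; cols <- (idx - 1L) %/% h + 1L
  geom <- .geometricFeatures(rows, cols)
  half <- windowSize %/% 2L
  # floor(x + 0.5) keeps the window equivariant under integer translation
  # (round() half-to-even would depend on centroid parity)
  rc <- floor(mean(rows) + 0.5); cc <- floor(mean(cols) + 0.5)
  wr <- pmin(pmax((rc - half + 1L):(rc + half), 1L), h)
  wc <- pmin(pmax((cc - half + 1L):(cc + half), 1L), w)
  inObj <- labels[wr, wc, drop = FALSE] == labelId
  out <- numeric(0)
  for (ch in 1:3) {
    I <- image[wr, wc, ch, drop = TRUE] / 255
    bg <- if (all(inObj)) 0.5 else mean(I[!inObj])
    I[!inObj] <- bg
    tex <- .channelTextureFeatures(I)
    out <- if (dedupGeometric) c(out, tex) else c(out, geom, tex)
  }
  if (dedupGeometric) out <- c(geom, out)
  names(out) <- featureNames(dedupGeometric)
  out
}

#' Descriptor matrix for every object of a label mask
#'
#' Applies \code{\link{extractFeatures}} to each label 1..N and stacks the
#' results (rows in label order, columns named by \code{featureNames}).
#'
#' @inheritParams extractFeatures
#' @return numeric matrix, one row per object.
#' @export
extractAllFeatures <- function(image, labels, dedupGeometric = FALSE,
                               windowSize = 64L) {
  n <- max(labels)
  nm <- featureNames(dedupGeometric)
  X <- matrix(NA_real_, n, length(nm), dimnames = list(NULL, nm))
  for (id in seq_len(n))
    X[id, ] <- extractFeatures(image, labels, id, dedupGeometric, windowSize)
  X
}
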
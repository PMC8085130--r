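#' @importFrom methods new validObject show is slot setValidity
NULL

# ---------------------------------------------------------------- PipelineConfig

#' Pipeline configuration
#'
#' Holds every tunable parameter of the detection pipeline. The two
#' parameters that dominate detection performance are \code{thresholdT}
#' (the relative cut-off of the adaptive threshold, in percent below the
#' local window mean) and \code{splitT} (the starting level of the
#' distance-transform cluster-splitting recursion, in pixels); both are
#' the usual subjects of a precision-recall sweep
#' (\code{\link{sweepParameter}}).
#'
#' @slot roiSize side of the square processing tiles, px.
#' @slot scheme tiling scheme: "A" (non-overlapping cover), "B" (adds
#'   right/down shifted tiles), "C" (shifted in all four directions).
#' @slot thresholdT adaptive-threshold sensitivity, percent in (0, 100).
#' @slot window adaptive-threshold window side, px (odd).
#' @slot splitT starting distance-transform threshold for cluster
#'   splitting, px.
#' @slot splitDT increment added at each recurrence, px.
#' @slot maxRecurrences cap on probes per branch of the splitting recursion.
#' @slot minArea objects below this area (px) are discarded as artifacts.
#' @slot acIterations boundary-refinement (active contour) iteration count.
#' @slot pixelSizeUm physical pixel size, um (only used for um^2 reporting).
#' @slot seed integer seed echoed into results for provenance.
#' @export
setClass("PipelineConfig", representation(
  roiSize = "integer", scheme = "character", thresholdT = "numeric",
  window = "integer", splitT = "numeric", splitDT = "numeric",
  maxRecurrences = "integer", minArea = "integer", acIterations = "integer",
  pixelSizeUm = "numeric", seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (!object@scheme %in% c("A", "B", "C")) msg <- c(msg, "scheme must be A, B or C")
  if (object@window <= 0L) msg <- c(msg, "window must be positive")
  if (object@roiSize <= object@window) msg <- c(msg, "roiSize must exceed window")
  if (object@minArea < 0L) msg <- c(msg, "minArea must be >= 0")
  if (object@thresholdT <= 0 || object@thresholdT >= 100)
    msg <- c(msg, "thresholdT must lie in (0, 100)")
  if (object@splitT <= 0) msg <- c(msg, "splitT must be positive")
  if (object@splitDT <= 0) msg <- c(msg, "splitDT must be positive")
  if (object@maxRecurrences < 1L) msg <- c(msg, "maxRecurrences must be >= 1")
  if (object@acIterations < 0L) msg <- c(msg, "acIterations must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param roiSize tile side in px (default 1000).
#' @param scheme tiling scheme "A", "B" or "C" (default "B").
#' @param thresholdT adaptive-threshold sensitivity in percent (default 15).
#' @param window adaptive-threshold window side in px (default 51).
#' @param splitT starting split threshold in px (default 3).
#' @param splitDT split threshold increment in px (default 2).
#' @param maxRecurrences recursion cap (default 10).
#' @param minArea minimum object area in px (default 50).
#' @param acIterations active-contour iterations (default 50).
#' @param pixelSizeUm physical pixel size in um (default 0.5).
#' @param seed integer seed (default 1).
#' @return a \code{PipelineConfig} object.
#' @examples
#' cfg <- pipelineConfig(roiSize = 500, thresholdT = 15)
#' @export
pipelineConfig <- function(roiSize = 1000L, scheme = "B", thresholdT = 15,
                           window = 51L, splitT = 3, splitDT = 2,
                           maxRecurrences = 10L, minArea = 50L,
                           acIterations = 50L, pixelSizeUm = 0.5, seed = 1L) {
  new("PipelineConfig", roiSize = as.integer(roiSize), scheme = scheme,
      thresholdT = thresholdT, window = as.integer(window), splitT = splitT,
      splitDT = splitDT, maxRecurrences = as.integer(maxRecurrences),
      minArea = as.integer(minArea), acIterations = as.integer(acIterations),
      pixelSizeUm = pixelSizeUm, seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: roi", object@roiSize, "px, scheme", object@scheme,
      "| window", object@window, "px, t", object@thresholdT, "%",
      "| split T", object@splitT, "+", object@splitDT,
      "(max", object@maxRecurrences, ")",
      "| minArea", object@minArea, "px | AC", object@acIterations, "iter\n")
})

# --------------------------------------------------------------------- TileGrid

#' Precomputed tile grid for large-image processing
#'
#' Base tiles form a non-overlapping cover of the image on a regular grid
#' with stride \code{roiSize}; the last row/column tile is anchored so its
#' far edge coincides with the image edge. Schemes "B"/"C" append per base
#' tile copies shifted by \code{shift = floor(window/2)} pixels right/down
#' ("B") or in all four main directions ("C"), so every base-tile seam is
#' also covered by tile interiors. Rectangles are half-open 0-based
#' \code{[r0, r1) x [c0, c1)}; parts extending past the border carry
#' per-side padding annotations.
#'
#' @slot tiles data.frame with one row per tile: r0, r1, c0, c1 (half-open,
#'   0-based), kind, padTop, padBottom, padLeft, padRight.
#' @slot roiSize tile side, px.
#' @slot shift scheme shift, px.
#' @slot scheme "A", "B" or "C".
#' @slot imageDim integer c(height, width) of the gridded image.
#' @export
setClass("TileGrid", representation(
  tiles = "data.frame", roiSize = "integer", shift = "integer",
  scheme = "character", imageDim = "integer"))

setValidity("TileGrid", function(object) {
  need <- c("r0", "r1", "c0", "c1", "kind", "padTop", "padBottom",
            "padLeft", "padRight")
  if (!all(need %in% names(object@tiles))) return("tiles is missing columns")
  t <- object@tiles
  if (any(t$r1 - t$r0 + t$padTop + t$padBottom != object@roiSize) ||
      any(t$c1 - t$c0 + t$padLeft + t$padRight != object@roiSize))
    return("every padded patch must measure roiSize x roiSize")
  TRUE
})

#' @describeIn TileGrid number of tiles.
#' @param x,object a TileGrid.
#' @export
setMethod("length", "TileGrid", function(x) nrow(x@tiles))

#' Accessors for TileGrid
#' @param x a \code{TileGrid}.
#' @return \code{tiles()} the tile table; \code{roiSize()} the tile side.
#' @export
tiles <- function(x) x@tiles

#' @rdname tiles
#' @export
roiSize <- function(x) x@roiSize

setMethod("show", "TileGrid", function(object) {
  k <- table(object@tiles$kind)
  cat("TileGrid:", nrow(object@tiles), "tiles (",
      paste(names(k), k, sep = "=", collapse = ", "), ") roi",
      object@roiSize, "px, shift", object@shift, "px, scheme",
      object@scheme, "over", object@imageDim[1], "x", object@imageDim[2], "\n")
})

# ---------------------------------------------------------------------- VoteMap

#' Per-pixel vote accumulator for overlapped-tile fusion
#'
#' \code{votes(p)} counts the tiles whose processed mask marks pixel p as
#' nucleus; \code{coverage(p)} counts the tiles whose unpadded extent
#' contains p. Skipped tiles and padded tile margins contribute to neither.
#'
#' @slot votes integer matrix of object votes.
#' @slot coverage integer matrix of tile coverage.
#' @export
setClass("VoteMap", representation(votes = "matrix", coverage = "matrix"))

setValidity("VoteMap", function(object) {
  if (!identical(dim(object@votes), dim(object@coverage)))
    return("votes and coverage must share a shape")
  if (any(object@votes > object@coverage)) return("votes must not exceed coverage")
  if (any(object@votes < 0) || any(object@coverage < 0)) return("counts must be >= 0")
  TRUE
})

#' Accessors for VoteMap
#' @param x a \code{VoteMap}.
#' @return integer matrix of votes / coverage counts.
#' @export
votes <- function(x) x@votes

#' @rdname votes
#' @export
coverage <- function(x) x@coverage

setMethod("show", "VoteMap", function(object) {
  cat("VoteMap", nrow(object@votes), "x", ncol(object@votes),
      "| coverage", min(object@coverage), "-", max(object@coverage),
      "| max votes", max(object@votes), "\n")
})

# --------------------------------------------------------------------- MLPModel

#' Single-hidden-layer neural network model
#'
#' Fully connected network with sigmoid hidden units and a softmax output
#' layer, trained by scaled conjugate gradient on the cross-entropy loss
#' (see \code{\link{trainClassifier}} and \code{\link{trainPatchQC}}).
#' Inputs are z-scored with the training-split statistics stored in
#' \code{center}/\code{scale}.
#'
#' @slot W1,b1 hidden-layer weights (inputs x hidden) and biases.
#' @slot W2,b2 output-layer weights (hidden x classes) and biases.
#' @slot center,scale feature standardisation fitted on the training split.
#' @slot classes class labels, in output-unit order.
#' @slot featureNames expected input feature names (may be empty).
#' @slot meta list: seed, epochs, split sizes, held-out accuracy.
#' @export
setClass("MLPModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  center = "numeric", scale = "numeric", classes = "character",
  featureNames = "character", meta = "list"))

setValidity("MLPModel", function(object) {
  if (ncol(object@W1) != nrow(object@W2)) return("layer shapes disagree")
  if (length(object@b1) != ncol(object@W1)) return("b1 length mismatch")
  if (length(object@b2) != ncol(object@W2)) return("b2 length mismatch")
  if (length(object@classes) != ncol(object@W2)) return("one output unit per class")
  if (length(object@center) != nrow(object@W1) ||
      length(object@scale) != nrow(object@W1)) return("standardisation length mismatch")
  TRUE
})

setMethod("show", "MLPModel", function(object) {
  cat("MLPModel", nrow(object@W1), "->", ncol(object@W1), "->",
      ncol(object@W2), "(sigmoid / softmax); classes:",
      paste(object@classes, collapse = ", "))
  if (!is.null(object@meta$testAccuracy))
    cat(sprintf("; held-out accuracy %.3f", object@meta$testAccuracy))
  cat("\n")
})

# -------------------------------------------------------- SceneSpec & SyntheticScene

#' Specification of a synthetic DAB&H scene
#'
#' Describes the appearance statistics of a generated scene: nuclei are
#' randomly oriented ellipses whose areas and circularities follow the
#' normal laws given here, rendered darker than the background in the HSV
#' Value channel with class-specific hue (DAB brown for immunopositive,
#' hematoxylin blue for immunonegative), then degraded with Gaussian pixel
#' noise and blur. The built-in presets reproduce the shape statistics of
#' the two benchmark stains: \code{"iispv"} (area 311 +/- 35 px,
#' circularity 0.50 +/- 0.07) and \code{"wbcd"} (area 144 +/- 11 px,
#' circularity 0.70 +/- 0.08).
#'
#' @slot height,width scene size, px.
#' @slot nNuclei number of nuclei.
#' @slot positiveFraction fraction of immunopositive nuclei.
#' @slot areaMean,areaSd nucleus area law, px.
#' @slot circMean,circSd nucleus circularity law (4*pi*A/P^2).
#' @slot clusterFraction share of nuclei placed overlapping a neighbour.
#' @slot backgroundV background HSV Value level.
#' @slot positiveHSV,negativeHSV class colours as (h, s, v) in [0,1].
#' @slot noiseSd Gaussian pixel-noise sd (on [0,1] channels).
#' @slot blurSigma Gaussian blur sd, px.
#' @slot seed integer seed.
#' @slot preset preset name ("iispv", "wbcd" or "custom").
#' @export
setClass("SceneSpec", representation(
  height = "integer", width = "integer", nNuclei = "integer",
  positiveFraction = "numeric", areaMean = "numeric", areaSd = "numeric",
  circMean = "numeric", circSd = "numeric", clusterFraction = "numeric",
  backgroundV = "numeric", positiveHSV = "numeric", negativeHSV = "numeric",
  noiseSd = "numeric", blurSigma = "numeric", seed = "integer",
  preset = "character"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@areaMean <= 50) msg <- c(msg, "areaMean must exceed the 50 px artifact floor")
  if (object@positiveHSV[3] >= object@backgroundV ||
      object@negativeHSV[3] >= object@backgroundV)
    msg <- c(msg, "class Value levels must lie strictly below the background Value")
  if (object@positiveFraction < 0 || object@positiveFraction > 1)
    msg <- c(msg, "positiveFraction must lie in [0,1]")
  if (object@clusterFraction < 0 || object@clusterFraction > 1)
    msg <- c(msg, "clusterFraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec '%s': %d x %d px, %d nuclei (area %.0f+/-%.0f px, circ %.2f+/-%.2f, %d%% clustered), seed %d\n",
              object@preset, object@height, object@width, object@nNuclei,
              object@areaMean, object@areaSd, object@circMean, object@circSd,
              round(100 * object@clusterFraction), object@seed))
})

#' A generated scene with exact ground truth
#'
#' @slot image RGB array (height x width x 3, 0..255).
#' @slot gtLabels integer label mask; overlap between rendered nuclei is
#'   resolved by z-order, so ground-truth labels are pairwise disjoint.
#' @slot gtMarkers data.frame x, y, class (0-based centroids, one per
#'   nucleus, each inside its own label).
#' @slot spec the \code{SceneSpec} the scene was drawn from.
#' @export
setClass("SyntheticScene", representation(
  image = "array", gtLabels = "matrix", gtMarkers = "data.frame",
  spec = "SceneSpec"))

setValidity("SyntheticScene", function(object) {
  if (nrow(object@gtMarkers) != max(0L, max(object@gtLabels)))
    return("one marker per ground-truth label is required")
  TRUE
})

#' Accessors for SyntheticScene
#' @param x a \code{SyntheticScene}.
#' @return the RGB image array / label matrix / marker data.frame.
#' @export
sceneImage <- function(x) x@image

#' @rdname sceneImage
#' @export
gtLabels <- function(x) x@gtLabels

#' @rdname sceneImage
#' @export
gtMarkers <- function(x) x@gtMarkers

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene:", dim(object@image)[1], "x", dim(object@image)[2],
      "px,", nrow(object@gtMarkers), "nuclei (",
      sum(object@gtMarkers$class == "positive"), "positive )\n")
})

# ----------------------------------------------------------------- NucleusTable

#' Detected-nucleus result table
#'
#' One row per detected object (label id, centroid, area, perimeter,
#' predicted class and its softmax probability) plus the summary counts a
#' pathologist reads off first: total nuclei and the immunopositive /
#' immunonegative split, whose ratio is the diagnostic quantity the
#' pipeline exists to estimate.
#'
#' @slot records data.frame: label, x, y (0-based centroid), area,
#'   perimeter, class, probability.
#' @slot summary list: nTotal, nPositive, nNegative, positiveRatio.
#' @export
setClass("NucleusTable", representation(records = "data.frame", summary = "list"))

setValidity("NucleusTable", function(object) {
  s <- object@summary
  if (s$nTotal != nrow(object@records)) return("nTotal must equal the row count")
  if (!is.na(s$nPositive) && s$nTotal != s$nPositive + s$nNegative)
    return("nTotal must equal nPositive + nNegative")
  TRUE
})

#' Accessors for NucleusTable
#' @param x a \code{NucleusTable}.
#' @return \code{nucleusRecords()} the per-object data.frame;
#'   \code{nucleusSummary()} the summary count list.
#' @export
nucleusRecords <- function(x) x@records

#' @rdname nucleusRecords
#' @export
nucleusSummary <- function(x) x@summary

setMethod("show", "NucleusTable", function(object) {
  s <- object@summary
  cat("NucleusTable:", s$nTotal, "nuclei")
  if (!is.na(s$nPositive))
    cat(" |", s$nPositive, "positive,", s$nNegative, "negative",
        sprintf("(positive ratio %.3f)", s$positiveRatio))
  cat("\n")
})

.makeNucleusTable <- function(records) {
  classified <- nrow(records) > 0 && !all(is.na(records$class))
  npos <- if (classified) sum(records$class == "positive") else NA_integer_
  nneg <- if (classified) sum(records$class == "negative") else NA_integer_
  ratio <- if (classified && nrow(records) > 0) npos / nrow(records) else NA_real_
  new("NucleusTable", records = records,
      summary = list(nTotal = nrow(records), nPositive = npos,
                     nNegative = nneg, positiveRatio = ratio))
}
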
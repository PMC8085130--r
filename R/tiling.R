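# ROI precalculation for images too large to process at once, the overlapped
# tiling schemes, border padding, the patch quality-control network, and the
# two-circle random ROI sampler used to draw evaluation patches from a
# tissue core.

.tileRow <- function(r0raw, c0raw, roi, h, w, kind) {
  r1raw <- r0raw + roi; c1raw <- c0raw + roi
  r0 <- max(0L, r0raw); r1 <- min(h, r1raw)
  c0 <- max(0L, c0raw); c1 <- min(w, c1raw)
  if (r1 <= r0 || c1 <= c0) return(NULL)  # fully outside: grid construction forbids
  data.frame(r0 = r0, r1 = r1, c0 = c0, c1 = c1, kind = kind,
             padTop = r0 - r0raw, padBottom = r1raw - r1,
             padLeft = c0 - c0raw, padRight = c1raw - c1,
             stringsAsFactors = FALSE)
}

#' Precalculate the ROI grid for an image
#'
#' Base tiles are laid on a regular grid with stride \code{roiSize}; when
#' the image side is not a multiple, the last tile is anchored so its far
#' edge coincides with the image edge (fewer padded pixels than appending a
#' padded extra tile). Scheme "B" appends, per base tile, copies shifted by
#' \code{floor(window/2)} px right and down; scheme "C" shifts in all four
#' main directions. Shifted tiles (and base tiles of images smaller than
#' \code{roiSize}) that extend past the border carry per-side padding
#' annotations so every padded patch measures exactly
#' \code{roiSize x roiSize}.
#'
#' @param height,width image size, px.
#' @param roiSize tile side, px (> 0).
#' @param window adaptive-threshold window side, px (> 0); only its half
#'   determines the scheme shift.
#' @param scheme "A", "B" or "C".
#' @return a \code{\link{TileGrid}}.
#' @examples
#' length(computeTileGrid(2000, 2000, 1000, 100, "A"))  # 4
#' length(computeTileGrid(2000, 2000, 1000, 100, "B"))  # 12
#' @export
computeTileGrid <- function(height, width, roiSize, window, scheme = "B") {
  height <- as.integer(height); width <- as.integer(width)
  roiSize <- as.integer(roiSize); window <- as.integer(window)
  if (roiSize <= 0L || window <= 0L)
    stop("roiSize and window must be positive", call. = FALSE)
  if (!scheme %in% c("A", "B", "C")) stop("scheme must be A, B or C", call. = FALSE)
  anchors <- function(side) {
    if (side <= roiSize) return(0L)
    a <- seq.int(0L, side - roiSize, by = roiSize)
    sort(unique(c(a, side - roiSize)))
  }
  shift <- if (scheme == "A") 0L else window %/% 2L
  rows <- list()
  for (r in anchors(height)) for (cc in anchors(width)) {
    rows[[length(rows) + 1L]] <- .tileRow(r, cc, roiSize, height, width, "base")
    if (scheme %in% c("B", "C")) {
      rows[[length(rows) + 1L]] <- .tileRow(r, cc + shift, roiSize, height, width, "shifted-right")
      rows[[length(rows) + 1L]] <- .tileRow(r + shift, cc, roiSize, height, width, "shifted-down")
    }
    if (scheme == "C") {
      rows[[length(rows) + 1L]] <- .tileRow(r, cc - shift, roiSize, height, width, "shifted-left")
      rows[[length(rows) + 1L]] <- .tileRow(r - shift, cc, roiSize, height, width, "shifted-up")
    }
  }
  tl <- do.call(rbind, rows)
  new("TileGrid", tiles = tl, roiSize = roiSize, shift = shift,
      scheme = scheme, imageDim = c(height, width))
}

#' Crop one padded ROI out of an image
#'
#' Returns the \code{roiSize x roiSize} patch for a tile of a grid computed
#' for this image. Interior pixels equal the source pixels exactly;
#' out-of-image area (padding) is filled by edge replication, which avoids
#' introducing artificial dark borders that the adaptive threshold would
#' pick up as objects.
#'
#' @param image RGB array (height x width x 3).
#' @param tile one row of \code{tiles(grid)} (data.frame or list).
#' @return RGB array of the padded patch.
#' @export
extractTile <- function(image, tile) {
  .assertRGB(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  rows <- seq.int(tile$r0 - tile$padTop, tile$r1 + tile$padBottom - 1L) + 1L
  cols <- seq.int(tile$c0 - tile$padLeft, tile$c1 + tile$padRight - 1L) + 1L
  image[pmin(pmax(rows, 1L), h), pmin(pmax(cols, 1L), w), , drop = FALSE]
}

#' Sample evaluation ROIs from two circles around a tissue-core centre
#'
#' Draws \code{n} square ROIs whose upper-left corners lie on the
#' circumference of one of two virtual circles centred on the tissue core
#' (radii \code{r1} and \code{r2}; circle and angle both uniform). Sampling
#' near the core guarantees non-empty tissue patches while keeping the draw
#' random. Corners are rounded to integer pixels; ROIs may extend past the
#' image and are clipped or padded by the caller.
#'
#' @param center core centre as c(x, y) in 0-based pixel coordinates.
#' @param r1,r2 circle radii, px (defaults 500 and 2000).
#' @param roiSize ROI side, px.
#' @param n number of ROIs (>= 0).
#' @param seed integer seed.
#' @return data.frame with r0, c0, r1, c1 (half-open, 0-based) and circle.
#' @export
sampleRoisTwoCircle <- function(center, r1 = 500, r2 = 2000, roiSize = 1000L,
                                n = 1L, seed = 1L) {
  stopifnot(length(center) == 2L, n >= 0)
  if (n == 0)
    return(data.frame(r0 = integer(), c0 = integer(), r1 = integer(),
                      c1 = integer(), circle = numeric()))
  set.seed(as.integer(seed))
  radius <- sample(c(r1, r2), n, replace = TRUE)
  angle <- runif(n, 0, 2 * pi)
  x0 <- round(center[1L] + radius * cos(angle))
  y0 <- round(center[2L] + radius * sin(angle))
  data.frame(r0 = as.integer(y0), c0 = as.integer(x0),
             r1 = as.integer(y0 + roiSize), c1 = as.integer(x0 + roiSize),
             circle = radius)
}

# ------------------------------------------------------------------ patch QC

# Otsu threshold on a [0,1] channel (256-bin histogram, maximal between-class
# variance; ties to the lower cut).
.otsuCut <- function(v) {
  counts <- tabulate(pmin(255L, as.integer(v * 256)) + 1L, nbins = 256L)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256L) - 1L))
  muT <- mu[256L]
  sigma <- (muT * omega - mu)^2 / (omega * (1 - omega))
  sigma[!is.finite(sigma)] <- 0
  (which.max(sigma) - 1L) / 255
}

# Summary features of a patch for the processability decision: 16-bin Value
# histogram (captures "empty": mass piled at white), Laplacian energy
# (captures "heavily blurred": low high-frequency content), and foreground
# fraction at the Otsu cut.
qcFeatures <- function(patch) {
  v <- valueChannel(patch)
  histo <- tabulate(pmin(15L, as.integer(v * 16)) + 1L, nbins = 16L) / length(v)
  lap <- 4 * v - shiftMatrix(v, 1L, 0L, fill = NA) - shiftMatrix(v, -1L, 0L, fill = NA) -
    shiftMatrix(v, 0L, 1L, fill = NA) - shiftMatrix(v, 0L, -1L, fill = NA)
  lapEnergy <- mean(lap^2, na.rm = TRUE)
  fgFrac <- mean(v < .otsuCut(v))
  out <- c(histo, log1p(lapEnergy * 1e4), fgFrac)
  names(out) <- c(paste0("vhist", seq_len(16L)), "lapEnergy", "fgFrac")
  out
}

#' Train the patch quality-control network
#'
#' Fits a small fully connected network (10 sigmoid hidden units, softmax
#' output) that discriminates processable tissue patches from empty and
#' heavily blurred ones, so that such patches can be skipped before the
#' expensive segmentation stages. Inputs are the \code{qcFeatures} patch
#' summaries (16-bin Value histogram, Laplacian energy, Otsu foreground
#' fraction).
#'
#' @param patches list of RGB patch arrays.
#' @param labels character/factor of "keep"/"skip", one per patch.
#' @param seed integer seed (initialisation and data split).
#' @param epochs training epochs (default 300).
#' @return an \code{\link{MLPModel}} with held-out accuracy in
#'   \code{meta$testAccuracy}.
#' @export
trainPatchQC <- function(patches, labels, seed = 1L, epochs = 300L) {
  if (length(patches) == 0L) stop("empty training set", call. = FALSE)
  labels <- factor(as.character(labels), levels = c("keep", "skip"))
  if (any(is.na(labels))) stop("labels must be 'keep' or 'skip'", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2L)
    stop("both classes must be present in the training set", call. = FALSE)
  X <- t(vapply(patches, qcFeatures, numeric(18L)))
  trainMLP(X, labels, hidden = 10L, seed = seed, epochs = epochs)
}

#' Decide whether a patch is worth processing
#'
#' Applies a trained \code{\link{trainPatchQC}} model; patches judged
#' unprocessable (empty or heavily blurred) are skipped and contribute an
#' all-background mask downstream. The decision is deterministic.
#'
#' @param patch RGB patch array.
#' @param model a QC \code{\link{MLPModel}}.
#' @param threshold keep-probability cut-off (default 0.5).
#' @return "keep" or "skip".
#' @export
qcPatch <- function(patch, model, threshold = 0.5) {
  if (!is(model, "MLPModel")) stop("model must be a trained MLPModel", call. = FALSE)
  p <- mlpForward(model, matrix(qcFeatures(patch), nrow = 1L))
  if (p[1L, match("keep", model@classes)] >= threshold) "keep" else "skip"
}
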
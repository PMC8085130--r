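# Initial nucleus segmentation: HSV Value extraction, Bradley integral-image
# adaptive threshold, and region-based boundary refinement. Hematoxylin-blue
# and DAB-brown nuclei are both darker than the unstained background in the
# Value channel, so foreground is "darker than a fixed percentage below the
# local mean".

#' Extract the HSV Value channel
#'
#' Converts an RGB image to the Value channel of the HSV colour model,
#' i.e. per-pixel \code{max(R, G, B) / 255}. Working on this single channel
#' keeps both stain colours (hematoxylin blue, DAB brown) dark against the
#' bright background while discarding chromatic information the threshold
#' does not need.
#'
#' @param image RGB array, height x width x 3, values 0..255.
#' @return matrix of values in [0, 1].
#' @examples
#' img <- array(255, c(2, 2, 3))
#' valueChannel(img)  # all 1
#' @export
valueChannel <- function(image) {
  .assertRGB(image)
  pmax(image[, , 1L], image[, , 2L], image[, , 3L]) / 255
}

#' Bradley integral-image adaptive threshold
#'
#' A pixel is foreground iff its value lies more than \code{thresholdT}
#' percent below the mean of the \code{window} x \code{window} neighbourhood
#' centred on it: \code{value < localMean * (1 - thresholdT/100)}. Local
#' means come from a summed-area (integral) table, so the cost is O(1) per
#' pixel regardless of window size; at image borders the window shrinks to
#' its valid part and the mean is taken over that region. The result is
#' byte-identical to the naive per-pixel double loop.
#'
#' @param channel numeric matrix in [0, 1] (typically \code{valueChannel}).
#' @param window odd window side in px, smaller than either image side.
#' @param thresholdT relative cut-off in percent, in (0, 100).
#' @return logical foreground mask of the same shape.
#' @examples
#' v <- matrix(0.9, 64, 64); v[30:34, 30:34] <- 0.2
#' sum(bradleyThreshold(v, 33, 15))  # the dark square
#' @export
bradleyThreshold <- function(channel, window = 51L, thresholdT = 15) {
  stopifnot(is.matrix(channel))
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be an odd integer >= 3", call. = FALSE)
  if (thresholdT <= 0 || thresholdT >= 100)
    stop("thresholdT must lie in (0, 100)", call. = FALSE)
  if (window >= min(dim(channel)))
    stop("window (", window, " px) must be smaller than the image sides; ",
         "reduce the window or supply a larger image", call. = FALSE)
  mu <- localMean(channel, window)
  channel < mu * (1 - thresholdT / 100)
}

# One morphological Chan-Vese iteration on a binary crop u for image crop I:
# pixels adjacent to the contour move to the region (inside/outside) whose
# mean intensity they are closer to, then the contour is smoothed with one
# opening/closing pair (smoothing weight 1).
.chanVeseStep <- function(u, I) {
  inA <- u > 0
  if (!any(inA) || all(inA)) return(u)
  c1 <- mean(I[inA]); c2 <- mean(I[!inA])
  band <- (dilateDiamond(u) - erodeDiamond(u)) > 0
  F <- (I - c1)^2 - (I - c2)^2
  u[band & F < 0] <- 1
  u[band & F > 0] <- 0
  u <- dilateDiamond(erodeDiamond(u))   # opening
  u <- erodeDiamond(dilateDiamond(u))   # closing
  u
}

#' Refine object boundaries with a region-based active contour
#'
#' Evolves the initial thresholded mask on the Value channel with a
#' morphological Chan-Vese (active contour without edges) scheme so that
#' boundaries settle on the intensity transition between nucleus and
#' background. Refinement is localised: each 8-connected component of the
#' initial mask evolves independently inside its padded bounding box, with
#' the region means computed there. Components can change shape, merge or
#' vanish, but no component is created from an empty region; zero
#' iterations return the initial mask unchanged.
#'
#' @param channel numeric matrix in [0, 1].
#' @param init logical initial mask of the same shape.
#' @param iterations non-negative iteration count (default 50). Evolution
#'   stops early at a fixed point, which leaves the result identical to
#'   running the full count.
#' @return refined logical mask.
#' @export
refineBoundaries <- function(channel, init, iterations = 50L) {
  stopifnot(is.matrix(channel), identical(dim(channel), dim(init)))
  iterations <- as.integer(iterations)
  if (iterations < 0L) stop("iterations must be >= 0", call. = FALSE)
  init <- init != 0
  if (iterations == 0L || !any(init)) return(init)
  lab <- labelComponents(init)
  out <- matrix(FALSE, nrow(init), ncol(init))
  pad <- 8L
  h <- nrow(init); w <- ncol(init)
  idx <- which(lab > 0L)
  rows <- (idx - 1L) %% h + 1L; cols <- (idx - 1L) %/% h + 1L
  for (id in seq_len(max(lab))) {
    sel <- lab[idx] == id
    r0 <- max(1L, min(rows[sel]) - pad); r1 <- min(h, max(rows[sel]) + pad)
    c0 <- max(1L, min(cols[sel]) - pad); c1 <- min(w, max(cols[sel]) + pad)
    u <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    u[cbind(rows[sel] - r0 + 1L, cols[sel] - c0 + 1L)] <- 1
    I <- channel[r0:r1, c0:c1, drop = FALSE]
    for (it in seq_len(iterations)) {
      u2 <- .chanVeseStep(u, I)
      if (identical(u2, u)) break
      u <- u2
    }
    out[r0:r1, c0:c1] <- out[r0:r1, c0:c1] | (u > 0)
  }
  out
}
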
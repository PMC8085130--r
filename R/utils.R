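# Low-level raster helpers shared across modules. Images are base R arrays:
# an RGB image is height x width x 3 with 8-bit values in [0, 255]; single
# channels and masks are height x width matrices indexed [row, col].

#' @import methods
#' @importFrom stats rnorm runif quantile sd uniroot predict
#' @importFrom utils head read.csv write.csv
NULL

.assertRGB <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("expected an RGB image: height x width x 3 array", call. = FALSE)
  invisible(TRUE)
}

# Summed-area table with a zero top row/left column so that the sum over the
# half-open window [r0,r1) x [c0,c1) is S[r1+1,c1+1]-S[r0,c1+1]-S[r1+1,c0]+S[r0,c0]
# in 1-based closed-window terms below.
integralImage <- function(m) {
  S <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  S[-1L, -1L] <- apply(apply(m, 2L, cumsum), 1L, cumsum)
  if (ncol(m) == 1L) S[-1L, -1L] <- cumsum(m) # apply() drops dims
  t0 <- t(S[-1L, -1L, drop = FALSE])
  S[-1L, -1L] <- t0
  S
}

# Per-pixel mean over a (2h+1)-sided window truncated at the borders.
localMean <- function(m, window) {
  h <- nrow(m); w <- ncol(m)
  half <- (window - 1L) %/% 2L
  S <- integralImage(m)
  r <- seq_len(h); cc <- seq_len(w)
  r0 <- pmax(r - half, 1L); r1 <- pmin(r + half, h)
  c0 <- pmax(cc - half, 1L); c1 <- pmin(cc + half, w)
  # closed windows [r0,r1] x [c0,c1]; index into the padded table
  R0 <- matrix(r0, h, w); R1 <- matrix(r1, h, w)
  C0 <- matrix(c0, h, w, byrow = TRUE); C1 <- matrix(c1, h, w, byrow = TRUE)
  sums <- S[cbind(as.vector(R1) + 1L, as.vector(C1) + 1L)] -
    S[cbind(as.vector(R0), as.vector(C1) + 1L)] -
    S[cbind(as.vector(R1) + 1L, as.vector(C0))] +
    S[cbind(as.vector(R0), as.vector(C0))]
  area <- (R1 - R0 + 1L) * (C1 - C0 + 1L)
  matrix(sums, h, w) / area
}

# Shift a matrix by (dr, dc), filling vacated cells with `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1L, 1L + dr):min(h, h + dr)
  cs <- max(1L, 1L + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

.N8 <- cbind(dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
             dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))

# 3x3 binary dilation/erosion with the 4-connected cross (diamond) element,
# implemented with shifts; cheap for the many small crops the refiner visits.
dilateDiamond <- function(u) {
  v <- u
  v <- pmax(v, shiftMatrix(u, 1L, 0L), shiftMatrix(u, -1L, 0L),
            shiftMatrix(u, 0L, 1L), shiftMatrix(u, 0L, -1L))
  v
}

erodeDiamond <- function(u) {
  v <- u
  v <- pmin(v, shiftMatrix(u, 1L, 0L, 1), shiftMatrix(u, -1L, 0L, 1),
            shiftMatrix(u, 0L, 1L, 1), shiftMatrix(u, 0L, -1L, 1))
  v
}

dilateSquare <- function(u) {
  v <- u
  for (k in seq_len(nrow(.N8)))
    v <- pmax(v, shiftMatrix(u, .N8[k, 1L], .N8[k, 2L]))
  v
}

# 8-connected component labeling. EBImage::bwlabel is 4-connected, so labels
# touching diagonally are merged afterwards with a union-find pass over the
# diagonal adjacency, then renumbered 1..N in raster (row-major) order of each
# component's first pixel.
labelComponents <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  n <- max(lab)
  if (n > 1L) {
    parent <- seq_len(n)
    findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; as.integer(i) }
    for (d in list(c(1L, 1L), c(1L, -1L))) {
      nb <- shiftMatrix(lab, d[1L], d[2L])
      sel <- lab > 0L & nb > 0L & lab != nb
      if (any(sel)) {
        pairs <- unique(cbind(lab[sel], nb[sel]))
        for (i in seq_len(nrow(pairs))) {
          a <- findRoot(pairs[i, 1L]); b <- findRoot(pairs[i, 2L])
          if (a != b) parent[max(a, b)] <- min(a, b)
        }
      }
    }
    root <- vapply(seq_len(n), findRoot, integer(1))
    lab[lab > 0L] <- root[lab[lab > 0L]]
  }
  renumberLabels(lab)
}

# Renumber positive labels to consecutive 1..N ordered by raster (row-major)
# position of each label's first pixel; 0 stays background.
renumberLabels <- function(lab) {
  ids <- sort(unique(as.integer(lab[lab > 0L])))
  if (length(ids) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  h <- nrow(lab)
  idx <- which(lab > 0L)
  rowi <- (idx - 1L) %% h + 1L
  coli <- (idx - 1L) %/% h + 1L
  raster <- (rowi - 1L) * ncol(lab) + coli
  first <- tapply(raster, lab[idx], min)
  ord <- ids[order(first[as.character(ids)])]
  map <- integer(max(ids)); map[ord] <- seq_along(ord)
  out <- lab
  out[idx] <- map[lab[idx]]
  matrix(as.integer(out), h, ncol(lab))
}

# Digital perimeter from the traced 8-connected contour, with the standard
# corner-corrected weights (0.948 per axial step, 1.340 per diagonal step)
# so that digitised disks measure close to 2*pi*r.
maskPerimeter <- function(mask) {
  if (!any(mask)) return(0)
  oc <- EBImage::ocontour(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  per <- 0
  for (ctr in oc) {
    if (nrow(ctr) == 1L) { per <- per + 0.948 * 4; next }
    d <- abs(ctr - ctr[c(2:nrow(ctr), 1L), , drop = FALSE])
    diag <- d[, 1L] > 0 & d[, 2L] > 0
    per <- per + 0.948 * sum(!diag) + 1.340 * sum(diag)
  }
  per
}

# Physical area of `px` pixels at a given sampling resolution.
#' Convert a pixel area to square micrometres
#'
#' Utility for reporting object sizes in physical units: a count of `px`
#' pixels at a sampling resolution of `pixelSizeUm` micrometres per pixel
#' covers `px * pixelSizeUm^2` square micrometres. At the two common scanner
#' settings (0.25 um/px at 40x, 0.5 um/px at 20x) the default 50-pixel
#' artifact filter corresponds to 3.125 and 12.5 um^2 respectively, well
#' below the ~300-pixel area of real nuclei.
#'
#' @param px object area in pixels.
#' @param pixelSizeUm physical size of one pixel in micrometres (default 0.5,
#'   i.e. 20x magnification).
#' @return area in square micrometres.
#' @examples
#' pixelAreaUm2(50, 0.5)   # 12.5
#' pixelAreaUm2(50, 0.25)  # 3.125
#' @export
pixelAreaUm2 <- function(px, pixelSizeUm = 0.5) {
  stopifnot(is.numeric(px), px >= 0, pixelSizeUm > 0)
  px * pixelSizeUm^2
}
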
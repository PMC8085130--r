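# Seam-free fusion of overlapping processed ROIs: per-pixel vote
# accumulation followed by a strict-majority decision, then final object
# labeling. Merging overlapped results removes the ambiguity of objects cut
# by a single ROI's border.

#' Accumulate per-pixel object votes from processed tiles
#'
#' Adds the binary per-tile masks into an image-level vote map. For every
#' tile the unpadded part of its mask is pasted at the tile position:
#' \code{votes(p)} counts tiles voting "nucleus" at p and \code{coverage(p)}
#' counts tiles containing p. Padded tile margins are excluded from both
#' counts, and a skipped tile (quality control) contributes to neither —
#' pass \code{NULL} in its slot.
#'
#' @param grid the \code{\link{TileGrid}} the masks were processed under.
#' @param tileMasks list of logical \code{roiSize x roiSize} masks, one per
#'   tile (NULL for skipped tiles), in \code{tiles(grid)} order.
#' @return a \code{\link{VoteMap}}.
#' @export
accumulateVotes <- function(grid, tileMasks) {
  if (!is(grid, "TileGrid")) stop("grid must be a TileGrid", call. = FALSE)
  tl <- grid@tiles
  if (length(tileMasks) != nrow(tl))
    stop("need one mask (or NULL) per tile: got ", length(tileMasks),
         " for ", nrow(tl), " tiles", call. = FALSE)
  h <- grid@imageDim[1L]; w <- grid@imageDim[2L]
  votes <- matrix(0L, h, w); cover <- matrix(0L, h, w)
  roi <- grid@roiSize
  for (i in seq_len(nrow(tl))) {
    m <- tileMasks[[i]]
    if (is.null(m)) next
    if (!identical(dim(m), c(roi, roi)))
      stop("tile mask ", i, " is not roiSize x roiSize", call. = FALSE)
    t <- tl[i, ]
    rs <- (t$r0 + 1L):t$r1; cs <- (t$c0 + 1L):t$c1
    mr <- (t$padTop + 1L):(t$padTop + length(rs))
    mc <- (t$padLeft + 1L):(t$padLeft + length(cs))
    cover[rs, cs] <- cover[rs, cs] + 1L
    votes[rs, cs] <- votes[rs, cs] + (m[mr, mc] != 0)
  }
  new("VoteMap", votes = votes, coverage = cover)
}

#' Strict-majority fused mask
#'
#' A pixel of the merged image is an object pixel iff more than half of the
#' tiles covering it voted "nucleus" (\code{votes > coverage / 2}). Ties at
#' even coverage fail the strict majority and become background, as do
#' pixels no tile covered.
#'
#' @param vm a \code{\link{VoteMap}}.
#' @return logical fused mask.
#' @export
majorityMask <- function(vm) {
  if (!is(vm, "VoteMap")) stop("vm must be a VoteMap", call. = FALSE)
  vm@votes > vm@coverage / 2
}

#' Label connected foreground objects
#'
#' 8-connected components of the mask are labeled 1..N in raster (row-major)
#' order of each component's first pixel; background stays 0.
#'
#' @param mask logical mask.
#' @return integer label matrix.
#' @export
labelObjects <- function(mask) {
  stopifnot(is.matrix(mask))
  labelComponents(mask != 0)
}
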
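# Cluster splitting by recursive local processing: probe the Euclidean
# distance transform of each component at a recurrently increasing threshold
# until the thresholded core disconnects, then partition the component among
# the cores and recurse on each part. Only shape drives the split; colour is
# never consulted.

# Partition the TRUE pixels of `set` among the positive labels of `seeds` by
# geodesic (within-set, 8-connected) breadth-first growth. Ties in arrival
# round go to the lower seed id. Both matrices share a shape.
.geodesicPartition <- function(set, seeds) {
  owner <- seeds
  owner[!set] <- 0L
  repeat {
    free <- set & owner == 0L
    if (!any(free)) break
    best <- matrix(0L, nrow(owner), ncol(owner))
    for (k in seq_len(nrow(.N8))) {
      cand <- shiftMatrix(owner, .N8[k, 1L], .N8[k, 2L])
      take <- free & cand > 0L & (best == 0L | cand < best)
      best[take] <- cand[take]
    }
    if (!any(best > 0L)) break   # unreachable pixels (cannot happen in one component)
    owner[best > 0L] <- best[best > 0L]
  }
  owner
}

# Distance transform of a logical crop, with everything outside treated as
# background; a one-pixel border guard keeps the EBImage transform exact.
.edt <- function(m) {
  g <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  g[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- as.numeric(m)
  d <- EBImage::distmap(g, metric = "euclidean")
  matrix(d, nrow(g), ncol(g))[2:(nrow(m) + 1L), 2:(ncol(m) + 1L), drop = FALSE]
}

#' Split clustered nuclei by recursive distance-transform thresholding
#'
#' Touching nuclei thresholded into one blob are separated using only the
#' blob's shape. Per 8-connected component the Euclidean distance transform
#' is computed and probed at level \code{splitT}: pixels with distance
#' \code{>= splitT} form candidate seed cores (8-connected, cores below
#' \code{minSeedArea} px are ignored as speckle). If no core survives the
#' component is final; with a single core the probe is repeated at
#' \code{splitT + splitDT}; with two or more cores every component pixel is
#' assigned to its geodesically nearest core (breadth-first growth inside
#' the component, ties to the lower core id) and the recursion continues on
#' each part at the incremented level. Each branch performs at most
#' \code{maxRecurrences} probes. Lower starting levels resolve heavily
#' packed clusters better because a split can only be seen while the
#' probe level lies between a neck's width and its flanking cores' depths.
#'
#' Pixels are conserved exactly: the union of output labels equals the
#' input foreground, and parts never exchange pixels across components.
#'
#' @param mask logical foreground mask.
#' @param splitT starting distance threshold, px (> 0).
#' @param splitDT increment per recurrence, px (> 0).
#' @param maxRecurrences cap on probes per branch (>= 1).
#' @param minSeedArea minimum seed-core area, px.
#' @return integer label matrix, labels 1..N consecutive, 0 background.
#' @examples
#' m <- matrix(FALSE, 40, 64)
#' for (cx in c(20, 44)) {
#'   d <- outer((1:40) - 20, (1:64) - cx, function(r, c) sqrt(r^2 + c^2))
#'   m <- m | d <= 15
#' }
#' max(recursiveSplit(m))  # 2: the dumbbell is split at the neck
#' @export
recursiveSplit <- function(mask, splitT = 3, splitDT = 2,
                           maxRecurrences = 10L, minSeedArea = 10L) {
  stopifnot(is.matrix(mask))
  if (splitT <= 0 || splitDT <= 0) stop("splitT and splitDT must be positive", call. = FALSE)
  maxRecurrences <- as.integer(maxRecurrences)
  if (maxRecurrences < 1L) stop("maxRecurrences must be >= 1", call. = FALSE)
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  if (!any(mask)) return(out)
  lab <- labelComponents(mask)
  nextLabel <- 0L
  idxAll <- which(lab > 0L)
  rowsAll <- (idxAll - 1L) %% h + 1L
  colsAll <- (idxAll - 1L) %/% h + 1L
  for (id in seq_len(max(lab))) {
    sel <- lab[idxAll] == id
    rows <- rowsAll[sel]; cols <- colsAll[sel]
    r0 <- min(rows); c0 <- min(cols)
    ch <- max(rows) - r0 + 1L; cw <- max(cols) - c0 + 1L
    comp <- matrix(FALSE, ch, cw)
    comp[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    # iterative recursion over parts of this component
    stack <- list(list(set = comp, T = splitT, depth = 1L))
    while (length(stack)) {
      item <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      set <- item$set
      finalize <- FALSE
      if (item$depth > maxRecurrences) {
        finalize <- TRUE
      } else {
        d <- .edt(set)
        cores <- labelComponents(d >= item$T)
        if (max(cores) > 0L) {
          areas <- tabulate(cores[cores > 0L], nbins = max(cores))
          keep <- which(areas >= minSeedArea)
          cores[!(cores %in% keep)] <- 0L
          cores <- renumberLabels(cores)
        }
        n <- max(cores)
        if (n == 0L) {
          finalize <- TRUE
        } else if (n == 1L) {
          stack[[length(stack) + 1L]] <-
            list(set = set, T = item$T + splitDT, depth = item$depth + 1L)
        } else {
          part <- .geodesicPartition(set, cores)
          for (p in seq_len(n)) {
            stack[[length(stack) + 1L]] <-
              list(set = part == p, T = item$T + splitDT, depth = item$depth + 1L)
          }
        }
      }
      if (finalize) {
        nextLabel <- nextLabel + 1L
        sub <- out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L), drop = FALSE]
        sub[set] <- nextLabel
        out[r0:(r0 + ch - 1L), c0:(c0 + cw - 1L)] <- sub
      }
    }
  }
  renumberLabels(out)
}

#' Remove sub-threshold artifacts from a label mask
#'
#' Objects with an area strictly below \code{minArea} pixels are erased to
#' background; surviving labels are renumbered consecutively preserving
#' their order. At the usual scanner resolutions the default 50 px floor
#' corresponds to 3.125 um^2 (0.25 um/px) or 12.5 um^2 (0.5 um/px) —
#' an order of magnitude below real nuclei — so everything removed is
#' treated as staining or thresholding debris.
#'
#' @param labels integer label matrix.
#' @param minArea minimum surviving area in px (default 50); an object of
#'   exactly \code{minArea} pixels is kept.
#' @return filtered, renumbered label matrix.
#' @export
removeSmall <- function(labels, minArea = 50L) {
  stopifnot(is.matrix(labels))
  if (minArea < 0) stop("minArea must be >= 0", call. = FALSE)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  n <- max(labels)
  if (n == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L], nbins = n)
  drop <- which(areas < minArea)
  if (length(drop)) labels[labels %in% drop] <- 0L
  renumberLabels(labels)
}
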
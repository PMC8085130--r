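# The end-to-end pipeline driver: tile, quality-control, segment, refine,
# split, filter per tile; fuse tiles by majority vote; re-split at image
# level; then featurise and classify every surviving object.

.logStage <- function(verbose, stage, t0, ...) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("[ihcseg] %-12s %6.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, paste0(..., collapse = " ")))
}

# Segment one padded patch down to a binary per-tile mask.
.processPatch <- function(patch, cfg) {
  v <- valueChannel(patch)
  m <- bradleyThreshold(v, cfg@window, cfg@thresholdT)
  m <- refineBoundaries(v, m, cfg@acIterations)
  lm <- recursiveSplit(m, cfg@splitT, cfg@splitDT, cfg@maxRecurrences)
  removeSmall(lm, cfg@minArea) > 0L
}

#' Run the full nucleus detection and classification pipeline
#'
#' Executes tile -> (optional patch QC) -> Value-channel adaptive
#' threshold -> active-contour refinement -> recursive cluster splitting ->
#' small-object removal per tile, fuses the per-tile masks with a
#' per-pixel strict majority vote, re-splits the fused mask once at image
#' level (per-tile label identities do not survive fusion), applies the
#' area filter, and finally extracts the object descriptors and classifies
#' each nucleus when a classifier is supplied. The run is deterministic
#' for a given configuration.
#'
#' @param image RGB array (0..255).
#' @param cfg a \code{\link{PipelineConfig}}.
#' @param model optional nucleus classifier (\code{\link{MLPModel}}); its
#'   input size selects the descriptor layout (309 or 287 features).
#' @param qcModel optional patch quality-control model; skipped patches
#'   contribute an all-background mask.
#' @param qcThreshold keep-probability cut-off for QC (default 0.5).
#' @param verbose log one structured line per stage.
#' @return list with \code{labels} (integer label matrix, labels 1..N,
#'   background 0), \code{table} (a \code{\link{NucleusTable}}) and
#'   \code{votes} (the \code{\link{VoteMap}}).
#' @export
runPipeline <- function(image, cfg = pipelineConfig(), model = NULL,
                        qcModel = NULL, qcThreshold = 0.5, verbose = FALSE) {
  .assertRGB(image)
  h <- dim(image)[1L]; w <- dim(image)[2L]
  if (min(h, w) <= cfg@window)
    stop("image (", h, "x", w, ") is not larger than the threshold window (",
         cfg@window, " px); reduce `window` or supply a larger image",
         call. = FALSE)
  t0 <- as.numeric(Sys.time())
  grid <- computeTileGrid(h, w, min(cfg@roiSize, max(h, w)), cfg@window,
                          cfg@scheme)
  .logStage(verbose, "tiling", t0, length(grid), "tiles")
  tl <- grid@tiles
  masks <- vector("list", nrow(tl))
  nSkipped <- 0L
  for (i in seq_len(nrow(tl))) {
    patch <- extractTile(image, tl[i, ])
    if (!is.null(qcModel) && qcPatch(patch, qcModel, qcThreshold) == "skip") {
      nSkipped <- nSkipped + 1L
      next
    }
    masks[[i]] <- .processPatch(patch, cfg)
  }
  .logStage(verbose, "segmentation", t0, nrow(tl) - nSkipped, "tiles processed,",
            nSkipped, "skipped")
  vm <- accumulateVotes(grid, masks)
  fused <- majorityMask(vm)
  .logStage(verbose, "fusion", t0, sum(fused), "foreground px")
  labels <- recursiveSplit(fused, cfg@splitT, cfg@splitDT, cfg@maxRecurrences)
  labels <- removeSmall(labels, cfg@minArea)
  n <- max(labels)
  .logStage(verbose, "labeling", t0, n, "objects")
  if (n > 0L) {
    idx <- which(labels > 0L)
    rows <- (idx - 1L) %% h + 1L; cols <- (idx - 1L) %/% h + 1L
    lab <- labels[idx]
    area <- tabulate(lab, nbins = n)
    cy <- tapply(rows, lab, mean) - 1; cx <- tapply(cols, lab, mean) - 1
    per <- vapply(seq_len(n), function(id) {
      sel <- lab == id
      r0 <- min(rows[sel]); c0 <- min(cols[sel])
      crop <- matrix(FALSE, max(rows[sel]) - r0 + 1L, max(cols[sel]) - c0 + 1L)
      crop[cbind(rows[sel] - r0 + 1L, cols[sel] - c0 + 1L)] <- TRUE
      maskPerimeter(crop)
    }, numeric(1))
    records <- data.frame(label = seq_len(n), x = as.numeric(cx),
                          y = as.numeric(cy), area = area, perimeter = per,
                          class = NA_character_, probability = NA_real_,
                          stringsAsFactors = FALSE)
    if (!is.null(model)) {
      dedup <- nrow(model@W1) == length(featureNames(dedupGeometric = TRUE))
      pred <- classifyObjects(image, labels, model, dedupGeometric = dedup)
      records$class <- pred$class
      records$probability <- pred$probability
      .logStage(verbose, "classify", t0, sum(pred$class == "positive"),
                "positive /", sum(pred$class == "negative"), "negative")
    }
  } else {
    records <- data.frame(label = integer(), x = numeric(), y = numeric(),
                          area = integer(), perimeter = numeric(),
                          class = character(), probability = numeric(),
                          stringsAsFactors = FALSE)
  }
  list(labels = labels, table = .makeNucleusTable(records), votes = vm)
}
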
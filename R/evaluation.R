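# Object-wise and pixel-wise scoring against ground truth, and
# precision-recall sweeps of the two primary detection parameters.

.checkMarkers <- function(markers, dim = NULL) {
  if (!all(c("x", "y") %in% names(markers)))
    stop("markers need x and y columns", call. = FALSE)
  if (!is.numeric(markers$x) || !is.numeric(markers$y) ||
      any(!is.finite(markers$x)) || any(!is.finite(markers$y)) ||
      any(markers$x < 0) || any(markers$y < 0))
    stop("marker coordinates must be non-negative numbers", call. = FALSE)
  if (!is.null(dim) && nrow(markers) > 0 &&
      (any(markers$y >= dim[1L]) || any(markers$x >= dim[2L])))
    stop("marker outside the image extent", call. = FALSE)
  invisible(TRUE)
}

#' Match point markers to detected objects
#'
#' Containment-based one-to-one matching for object-wise evaluation: a
#' marker matches the object whose pixels contain it. Each object
#' containing at least one marker yields exactly one true positive; its
#' surplus markers each count one false negative; an object containing no
#' marker is one false positive; a marker inside no object is one false
#' negative.
#'
#' @param labels integer label matrix of detected objects.
#' @param markers data.frame with 0-based x (column) and y (row)
#'   coordinates inside the image extent.
#' @return list with integer TP, FP, FN and scope = "detection".
#' @export
matchObjects <- function(labels, markers) {
  stopifnot(is.matrix(labels))
  .checkMarkers(markers, dim(labels))
  n <- max(labels)
  if (nrow(markers) == 0L)
    return(list(TP = 0L, FP = n, FN = 0L, scope = "detection"))
  hit <- labels[cbind(round(markers$y) + 1L, round(markers$x) + 1L)]
  markersPerObject <- tabulate(hit[hit > 0L], nbins = max(n, 1L))
  TP <- sum(markersPerObject > 0L)
  list(TP = as.integer(TP),
       FP = as.integer(n - TP),
       FN = as.integer(sum(hit == 0L) + sum(pmax(markersPerObject - 1L, 0L))),
       scope = "detection")
}

#' Precision, recall and F1 from match counts
#'
#' \code{PPV = TP / (TP + FP)}, \code{TPR = TP / (TP + FN)}, and F1 is
#' their harmonic mean; any 0/0 is 0 by convention.
#'
#' @param counts list or vector with TP, FP, FN.
#' @return named numeric c(PPV, TPR, F1).
#' @examples
#' detectionMetrics(list(TP = 8, FP = 2, FN = 2))  # all 0.8
#' @export
detectionMetrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
  tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (ppv + tpr > 0) 2 * ppv * tpr / (ppv + tpr) else 0
  c(PPV = ppv, TPR = tpr, F1 = f1)
}

#' Per-class detection + classification metrics
#'
#' Repeats the containment matching of \code{\link{matchObjects}} with
#' class agreement required for a true positive: an object matched to a
#' marker of another class counts a false positive for the predicted class
#' and a false negative for the marker class; unmatched objects are false
#' positives of their predicted class; unmatched markers (including
#' surplus markers of a multi-marker object) are false negatives of their
#' own class.
#'
#' @param labels integer label matrix.
#' @param records per-object table (a \code{\link{NucleusTable}} or its
#'   records data.frame) with columns label and class.
#' @param markers data.frame x, y, class with class in
#'   "positive"/"negative".
#' @return data.frame, one row per class: class, TP, FP, FN, PPV, TPR, F1.
#' @export
classwiseMetrics <- function(labels, records, markers) {
  if (is(records, "NucleusTable")) records <- nucleusRecords(records)
  .checkMarkers(markers, dim(labels))
  if (!"class" %in% names(markers) ||
      any(!markers$class %in% c("positive", "negative")))
    stop("markers must carry a class of 'positive' or 'negative'", call. = FALSE)
  classes <- c("positive", "negative")
  predClass <- rep(NA_character_, max(labels))
  predClass[records$label] <- as.character(records$class)
  hit <- if (nrow(markers)) labels[cbind(round(markers$y) + 1L, round(markers$x) + 1L)] else integer()
  cnt <- matrix(0L, 2L, 3L, dimnames = list(classes, c("TP", "FP", "FN")))
  matchedObjects <- integer()
  for (obj in unique(hit[hit > 0L])) {
    mk <- which(hit == obj)
    mClass <- as.character(markers$class[mk[1L]])
    pClass <- predClass[obj]
    if (!is.na(pClass) && pClass == mClass) {
      cnt[mClass, "TP"] <- cnt[mClass, "TP"] + 1L
    } else {
      if (!is.na(pClass)) cnt[pClass, "FP"] <- cnt[pClass, "FP"] + 1L
      cnt[mClass, "FN"] <- cnt[mClass, "FN"] + 1L
    }
    for (s in mk[-1L]) {  # surplus markers
      sc <- as.character(markers$class[s])
      cnt[sc, "FN"] <- cnt[sc, "FN"] + 1L
    }
    matchedObjects <- c(matchedObjects, obj)
  }
  if (nrow(markers)) for (i in which(hit == 0L)) {
    sc <- as.character(markers$class[i])
    cnt[sc, "FN"] <- cnt[sc, "FN"] + 1L
  }
  for (obj in setdiff(seq_len(max(labels)), matchedObjects)) {
    pClass <- predClass[obj]
    if (!is.na(pClass)) cnt[pClass, "FP"] <- cnt[pClass, "FP"] + 1L
  }
  out <- do.call(rbind, lapply(classes, function(cl) {
    m <- detectionMetrics(list(TP = cnt[cl, "TP"], FP = cnt[cl, "FP"],
                               FN = cnt[cl, "FN"]))
    data.frame(class = cl, TP = cnt[cl, "TP"], FP = cnt[cl, "FP"],
               FN = cnt[cl, "FN"], PPV = m["PPV"], TPR = m["TPR"],
               F1 = m["F1"], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pixel-wise segmentation metrics over an evaluation region
#'
#' Confusion counts are taken only over pixels where \code{region} is TRUE
#' (e.g. the area whose boundary ground truth both experts agreed on);
#' PPV/TPR/F1 follow the same formulas and 0/0 convention as
#' \code{\link{detectionMetrics}}.
#'
#' @param pred,gt logical predicted and ground-truth masks.
#' @param region logical evaluation region (default: everywhere).
#' @return named numeric c(PPV, TPR, F1).
#' @export
pixelMetrics <- function(pred, gt, region = NULL) {
  if (is.null(region)) region <- matrix(TRUE, nrow(pred), ncol(pred))
  if (!identical(dim(pred), dim(gt)) || !identical(dim(pred), dim(region)))
    stop("pred, gt and region must share a shape", call. = FALSE)
  p <- pred[region]; g <- gt[region]
  detectionMetrics(list(TP = sum(p & g), FP = sum(p & !g), FN = sum(!p & g)))
}

#' Precision-recall curve from a parameter sweep
#'
#' @slot parameter swept parameter name.
#' @slot points data.frame: value, PPV, TPR, F1 (macro-averaged across
#'   images).
#' @slot best F1-maximising parameter value (ties to the first).
#' @slot cv per-fold twofold cross-validation results (may be empty).
#' @export
setClass("PRCurve", representation(parameter = "character",
                                   points = "data.frame", best = "numeric",
                                   cv = "data.frame"))

setMethod("show", "PRCurve", function(object) {
  cat("PRCurve over", object@parameter, "(", nrow(object@points), "values );",
      "best =", object@best, sprintf("(F1 %.3f)\n",
      max(object@points$F1)))
})

#' Sweep a detection parameter and score each value
#'
#' Runs the detection pipeline (no classifier) on every image for every
#' candidate value of \code{thresholdT} (adaptive-threshold cut-off) or
#' \code{splitT} (cluster-splitting start level), matches detections to the
#' markers, and reports macro-averaged (per-image mean) PPV/TPR/F1 together
#' with the F1-maximising value. With \code{cv = TRUE} images are split
#' into two seeded folds and the value selected on each fold is scored on
#' the other (twofold cross-validation).
#'
#' @param images list of RGB arrays.
#' @param markersList list of marker data.frames, parallel to images.
#' @param parameter "thresholdT" or "splitT".
#' @param values numeric candidate values (>= 1; >= 2 for a useful curve).
#' @param cfg base \code{\link{PipelineConfig}}.
#' @param cv run twofold cross-validation (needs >= 2 images).
#' @param seed seed for the CV fold split.
#' @return a \code{\link{PRCurve}}.
#' @export
sweepParameter <- function(images, markersList, parameter = c("thresholdT", "splitT"),
                           values, cfg = pipelineConfig(), cv = FALSE, seed = 1L) {
  parameter <- match.arg(parameter)
  if (length(values) == 0L) stop("values must not be empty", call. = FALSE)
  if (length(images) == 0L || length(images) != length(markersList))
    stop("need one marker set per image", call. = FALSE)
  perImageF1 <- matrix(NA_real_, length(values), length(images))
  pts <- data.frame(value = values, PPV = NA_real_, TPR = NA_real_, F1 = NA_real_)
  for (vi in seq_along(values)) {
    cfgV <- cfg
    slot(cfgV, parameter) <- values[vi]
    mm <- vapply(seq_along(images), function(ii) {
      res <- runPipeline(images[[ii]], cfgV)
      m <- detectionMetrics(matchObjects(res$labels, markersList[[ii]]))
      perImageF1[vi, ii] <<- m["F1"]
      m
    }, numeric(3L))
    pts$PPV[vi] <- mean(mm[1L, ]); pts$TPR[vi] <- mean(mm[2L, ])
    pts$F1[vi] <- mean(mm[3L, ])
  }
  best <- values[which.max(pts$F1)]
  cvDf <- data.frame(fold = integer(), bestValue = numeric(), f1Held = numeric())
  if (cv && length(images) >= 2L) {
    set.seed(as.integer(seed))
    fold <- sample(rep(1:2, length.out = length(images)))
    for (f in 1:2) {
      inF <- fold == f
      bestF <- values[which.max(rowMeans(perImageF1[, inF, drop = FALSE]))]
      held <- mean(perImageF1[match(bestF, values), !inF])
      cvDf <- rbind(cvDf, data.frame(fold = f, bestValue = bestF, f1Held = held))
    }
  }
  new("PRCurve", parameter = parameter, points = pts, best = best, cv = cvDf)
}
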
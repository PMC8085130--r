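# Independent oracles used to validate the package's core algorithms, plus a
# lazy fixture cache so expensive scenes and models are built once per run.

# Naive per-pixel Bradley threshold: explicit double loop, window truncated at
# the borders, mean over the valid region. Deliberately independent of the
# integral-image implementation.
naiveBradley <- function(channel, window, thresholdT) {
  h <- nrow(channel); w <- ncol(channel); half <- (window - 1L) %/% 2L
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (cc in seq_len(w)) {
    rs <- max(1L, r - half):min(h, r + half)
    cs <- max(1L, cc - half):min(w, cc + half)
    out[r, cc] <- channel[r, cc] < mean(channel[rs, cs]) * (1 - thresholdT / 100)
  }
  out
}

# Brute-force Euclidean distance transform: per foreground pixel, the minimum
# distance to any background pixel (image border counts as background).
bruteDT <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L); pad[2:(h + 1L), 2:(w + 1L)] <- mask
  fg <- which(pad); bg <- which(!pad)
  fr <- (fg - 1L) %% (h + 2L) + 1L; fc <- (fg - 1L) %/% (h + 2L) + 1L
  br <- (bg - 1L) %% (h + 2L) + 1L; bc <- (bg - 1L) %/% (h + 2L) + 1L
  d <- matrix(0, h + 2L, w + 2L)
  for (i in seq_along(fg))
    d[fg[i]] <- sqrt(min((br - fr[i])^2 + (bc - fc[i])^2))
  d[2:(h + 1L), 2:(w + 1L), drop = FALSE]
}

# Queue-based 8-connected component labeling (flood fill), independent of the
# package's union-find path.
bruteLabel <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w); nxt <- 0L
  for (cc in seq_len(w)) for (r in seq_len(h)) {
    if (!mask[r, cc] || lab[r, cc] > 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r, cc)); lab[r, cc] <- nxt
    while (length(queue)) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1L] + dr; ccv <- p[2L] + dc
        if (rr >= 1L && rr <= h && ccv >= 1L && ccv <= w &&
            mask[rr, ccv] && lab[rr, ccv] == 0L) {
          lab[rr, ccv] <- nxt
          queue[[length(queue) + 1L]] <- c(rr, ccv)
        }
      }
    }
  }
  lab
}

# Brute-force rendition of the splitting recursion: probe the DT of a pixel
# set at T; no surviving core -> final label; one core -> retry at T + dT;
# several -> partition by breadth-first growth from the cores (ties to the
# lower core id) and recurse at T + dT. Written with queues and loops, not
# the package's vectorised shifts.
bruteSplit <- function(mask, splitT = 3, splitDT = 2, maxRec = 10L,
                       minSeed = 10L) {
  out <- matrix(0L, nrow(mask), ncol(mask)); cnt <- 0L
  comps <- bruteLabel(mask)
  growParts <- function(set, seeds) {
    owner <- seeds; owner[!set] <- 0L
    repeat {
      changed <- FALSE
      snapshot <- owner
      idx <- which(set & owner == 0L, arr.ind = TRUE)
      if (nrow(idx) == 0L) break
      for (i in seq_len(nrow(idx))) {
        r <- idx[i, 1L]; cc <- idx[i, 2L]; best <- 0L
        for (dr in -1:1) for (dc in -1:1) {
          rr <- r + dr; ccv <- cc + dc
          if (rr >= 1L && rr <= nrow(set) && ccv >= 1L && ccv <= ncol(set)) {
            o <- snapshot[rr, ccv]
            if (o > 0L && (best == 0L || o < best)) best <- o
          }
        }
        if (best > 0L) { owner[r, cc] <- best; changed <- TRUE }
      }
      if (!changed) break
    }
    owner
  }
  splitRec <- function(set, T, depth) {
    if (depth <= maxRec) {
      d <- bruteDT(set)
      cores <- bruteLabel(d >= T)
      keep <- which(tabulate(cores[cores > 0L]) >= minSeed)
      cores[!(cores %in% keep)] <- 0L
      ids <- sort(unique(cores[cores > 0L]))
      if (length(ids) == 0L) { cnt <<- cnt + 1L; out[set] <<- cnt; return(invisible()) }
      if (length(ids) == 1L) return(splitRec(set, T + splitDT, depth + 1L))
      seeds <- matrix(0L, nrow(set), ncol(set))
      for (j in seq_along(ids)) seeds[cores == ids[j]] <- j
      parts <- growParts(set, seeds)
      for (j in seq_along(ids)) splitRec(parts == j, T + splitDT, depth + 1L)
      return(invisible())
    }
    cnt <<- cnt + 1L; out[set] <<- cnt
  }
  for (id in seq_len(max(comps))) splitRec(comps == id, splitT, 1L)
  out
}

# Pixels whose four axial neighbours are all foreground (mask interior).
interior4 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(FALSE, h + 2L, w + 2L); p[2:(h + 1L), 2:(w + 1L)] <- m
  (p[1:h, 2:(w + 1L)] & p[3:(h + 2L), 2:(w + 1L)] &
     p[2:(h + 1L), 1:w] & p[2:(h + 1L), 3:(w + 2L)])
}

# Disk / dumbbell / triple-blob fixtures.
diskMask <- function(side, cy, cx, r) {
  outer(seq_len(side) - cy, seq_len(side) - cx,
        function(a, b) sqrt(a^2 + b^2)) <= r
}

dumbbellMask <- function() {
  m <- matrix(FALSE, 40, 64)
  for (cx in c(20, 44)) m <- m | diskMask(64, 20, cx, 15)[1:40, ]
  m
}

tripleBlobMask <- function() {
  m <- matrix(FALSE, 48, 80)
  for (cx in c(18, 40, 62)) m <- m | diskMask(80, 24, cx, 13)[1:48, ]
  m
}

# ---- lazy fixtures (built once per test run) --------------------------------

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# the acceptance workhorse scene: "iispv" preset, 100 nuclei, 30% clustered
evalScene <- function() fixture("evalScene", function()
  generateScene(sceneSpec("iispv", height = 1000, width = 1000, nNuclei = 100,
                          clusterFraction = 0.3, seed = 7)))

# training scenes (distinct seeds from the evaluation scene)
trainScenes <- function() fixture("trainScenes", function()
  lapply(c(101, 102), function(s)
    generateScene(sceneSpec("iispv", height = 800, width = 800, nNuclei = 80,
                            clusterFraction = 0.1, seed = s))))

trainedClassifier <- function() fixture("trainedClassifier", function() {
  sc <- trainScenes()
  X <- do.call(rbind, lapply(sc, function(s)
    extractAllFeatures(sceneImage(s), gtLabels(s))))
  y <- unlist(lapply(sc, function(s) gtMarkers(s)$class))
  trainClassifier(X, y, seed = 5, epochs = 1000)
})

evalPipeline <- function() fixture("evalPipeline", function()
  runPipeline(sceneImage(evalScene()), pipelineConfig(), trainedClassifier()))

# matched (object, marker) pairs: each object containing a marker, paired
# with its first contained marker (the one-to-one matching rule)
matchedPairs <- function(labels, markers) {
  hit <- labels[cbind(markers$y + 1L, markers$x + 1L)]
  first <- tapply(seq_len(nrow(markers))[hit > 0L], hit[hit > 0L], min)
  data.frame(object = as.integer(names(first)), marker = as.integer(first))
}
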
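# Single-hidden-layer network machinery shared by the nucleus classifier and
# the patch quality-control model: Nguyen-Widrow layer initialisation,
# sigmoid/softmax forward pass, cross-entropy backpropagation, and the
# scaled conjugate gradient (SCG) optimiser. One epoch is one full-batch SCG
# step (a single presentation of all input vectors).

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Nguyen-Widrow initialisation: random directions rescaled so hidden-unit
# active regions tile the input space; magnitude beta = 0.7 * H^(1/n) for n
# inputs and H hidden units, biases spread linearly across [-beta, beta].
.nguyenWidrow <- function(nIn, nHidden) {
  W <- matrix(runif(nIn * nHidden, -0.5, 0.5), nIn, nHidden)
  beta <- 0.7 * nHidden^(1 / nIn)
  norms <- sqrt(colSums(W^2))
  W <- sweep(W, 2L, ifelse(norms > 0, beta / norms, 1), "*")
  b <- if (nHidden == 1L) 0 else beta * seq(-1, 1, length.out = nHidden) * sign(W[1L, ])
  list(W = W, b = b)
}

.packParams <- function(W1, b1, W2, b2) c(W1, b1, W2, b2)

.unpackParams <- function(theta, nIn, nH, nOut) {
  i <- 0L
  W1 <- matrix(theta[i + seq_len(nIn * nH)], nIn, nH); i <- i + nIn * nH
  b1 <- theta[i + seq_len(nH)]; i <- i + nH
  W2 <- matrix(theta[i + seq_len(nH * nOut)], nH, nOut); i <- i + nH * nOut
  b2 <- theta[i + seq_len(nOut)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# Mean cross-entropy and its gradient for one-hot targets Y.
.mlpLossGrad <- function(theta, X, Y, nH) {
  n <- nrow(X); nIn <- ncol(X); nOut <- ncol(Y)
  p <- .unpackParams(theta, nIn, nH, nOut)
  A1 <- .sigmoid(sweep(X %*% p$W1, 2L, p$b1, "+"))
  P <- .softmax(sweep(A1 %*% p$W2, 2L, p$b2, "+"))
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
  D2 <- (P - Y) / n
  gW2 <- crossprod(A1, D2)
  gb2 <- colSums(D2)
  D1 <- (D2 %*% t(p$W2)) * A1 * (1 - A1)
  gW1 <- crossprod(X, D1)
  gb1 <- colSums(D1)
  list(loss = loss, grad = .packParams(gW1, gb1, gW2, gb2))
}

# Scaled conjugate gradient (Moller 1993). `fg(theta)` returns list(loss,
# grad); runs `epochs` iterations or stops when the gradient vanishes.
.scg <- function(theta, fg, epochs) {
  sigma0 <- 5e-5
  lambda <- 5e-7; lambdaBar <- 0
  cur <- fg(theta)
  r <- -cur$grad
  p <- r
  success <- TRUE
  delta <- 0; sk <- NULL
  for (k in seq_len(epochs)) {
    p2 <- sum(p * p)
    if (p2 < 1e-30) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      g2 <- fg(theta + sigma * p)$grad
      sk <- (g2 - cur$grad) / sigma
      delta <- sum(p * sk)
    }
    delta <- delta + (lambda - lambdaBar) * p2
    if (delta <= 0) {
      lambdaBar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdaBar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    nxt <- fg(theta + alpha * p)
    Delta <- 2 * delta * (cur$loss - nxt$loss) / mu^2
    if (Delta >= 0) {
      theta <- theta + alpha * p
      rNew <- -nxt$grad
      lambdaBar <- 0
      success <- TRUE
      beta <- (sum(rNew * rNew) - sum(rNew * r)) / mu
      p <- rNew + beta * p
      r <- rNew
      cur <- nxt
      if (Delta >= 0.75) lambda <- lambda / 4
      if (sqrt(sum(r * r)) < 1e-8) break
    } else {
      lambdaBar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta * (1 - Delta) / p2
    if (lambda > 1e12) break
  }
  theta
}

# Stratified assignment of indices to train/validation/test in the given
# proportions (default 70/15/15), per class, deterministically from the
# current RNG state.
.stratifiedSplit <- function(y, fractions = c(0.70, 0.15, 0.15)) {
  part <- character(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    nTr <- max(1L, round(fractions[1L] * length(idx)))
    nVa <- max(1L, round(fractions[2L] * length(idx)))
    nTr <- min(nTr, length(idx) - 2L)
    nVa <- min(nVa, length(idx) - nTr - 1L)
    part[idx[seq_len(nTr)]] <- "train"
    part[idx[nTr + seq_len(nVa)]] <- "validation"
    part[idx[(nTr + nVa + 1L):length(idx)]] <- "test"
  }
  part
}

# Shared trainer: standardise on the training split, Nguyen-Widrow init,
# full-batch SCG on the cross-entropy, then held-out accuracies.
trainMLP <- function(X, y, hidden, seed, epochs,
                     fractions = c(0.70, 0.15, 0.15)) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L)
    stop("training requires at least two classes", call. = FALSE)
  set.seed(as.integer(seed))
  part <- .stratifiedSplit(y, fractions)
  tr <- part == "train"
  center <- colMeans(X[tr, , drop = FALSE])
  scl <- apply(X[tr, , drop = FALSE], 2L, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")
  Y <- diag(nlevels(y))[as.integer(y), , drop = FALSE]
  nIn <- ncol(X); nH <- as.integer(hidden); nOut <- nlevels(y)
  l1 <- .nguyenWidrow(nIn, nH)
  l2 <- .nguyenWidrow(nH, nOut)
  theta0 <- .packParams(l1$W, l1$b, l2$W, l2$b)
  fg <- function(th) .mlpLossGrad(th, Xs[tr, , drop = FALSE],
                                  Y[tr, , drop = FALSE], nH)
  theta <- .scg(theta0, fg, as.integer(epochs))
  p <- .unpackParams(theta, nIn, nH, nOut)
  model <- new("MLPModel", W1 = p$W1, b1 = p$b1, W2 = p$W2, b2 = p$b2,
               center = center, scale = scl, classes = levels(y),
               featureNames = if (is.null(colnames(X))) character() else colnames(X),
               meta = list(seed = as.integer(seed), epochs = as.integer(epochs),
                           nTrain = sum(tr), nValidation = sum(part == "validation"),
                           nTest = sum(part == "test")))
  acc <- function(sel) {
    if (!any(sel)) return(NA_real_)
    pred <- model@classes[max.col(mlpForward(model, X[sel, , drop = FALSE],
                                             standardised = FALSE), "first")]
    mean(pred == as.character(y[sel]))
  }
  model@meta$validationAccuracy <- acc(part == "validation")
  model@meta$testAccuracy <- acc(part == "test")
  model
}

# Softmax class probabilities for a raw (unstandardised) feature matrix.
mlpForward <- function(model, X, standardised = FALSE) {
  if (!standardised)
    X <- sweep(sweep(X, 2L, model@center, "-"), 2L, model@scale, "/")
  A1 <- .sigmoid(sweep(X %*% model@W1, 2L, model@b1, "+"))
  .softmax(sweep(A1 %*% model@W2, 2L, model@b2, "+"))
}

#' Predict classes with a trained network
#'
#' Runs the forward pass and returns the argmax class with its softmax
#' probability (ties break deterministically to the first class in
#' \code{model@classes}).
#'
#' @param object a trained \code{\link{MLPModel}}.
#' @param newdata numeric feature vector, or matrix with one row per
#'   example; length/columns must match the model input size.
#' @param ... unused.
#' @return data.frame with columns \code{class} and \code{probability},
#'   one row per example.
#' @export
setMethod("predict", "MLPModel", function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != nrow(object@W1))
    stop("feature length ", ncol(newdata), " does not match the model input size ",
         nrow(object@W1), call. = FALSE)
  P <- mlpForward(object, newdata)
  j <- max.col(P, "first")
  data.frame(class = object@classes[j],
             probability = P[cbind(seq_len(nrow(P)), j)],
             stringsAsFactors = FALSE)
})
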
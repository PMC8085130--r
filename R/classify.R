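# Immunopositive / immunonegative nucleus classification: the object
# descriptor feeds a fully connected network with one hidden layer of 20
# sigmoid units and a two-class softmax output, trained with scaled
# conjugate gradient backpropagation on the cross-entropy loss.

#' Train the nucleus classifier
#'
#' Standardises the features with training-split statistics, initialises
#' both layers with the Nguyen-Widrow rule, performs a stratified 70/15/15
#' train/validation/test split, and minimises the cross-entropy with
#' full-batch scaled conjugate gradient for \code{epochs} epochs (one epoch
#' is one presentation of all input vectors). Training is reproducible
#' given \code{seed}; held-out accuracies are stored in the model metadata.
#'
#' @param features numeric matrix (objects x features) or list of equal
#'   length feature vectors from \code{\link{extractFeatures}}.
#' @param labels class per object, e.g. "positive"/"negative"; both classes
#'   must be present.
#' @param seed integer seed.
#' @param epochs training epochs (default 1000).
#' @param hidden hidden-layer width (default 20).
#' @return a trained \code{\link{MLPModel}}.
#' @export
trainClassifier <- function(features, labels, seed = 1L, epochs = 1000L,
                            hidden = 20L) {
  if (is.list(features)) features <- do.call(rbind, features)
  stopifnot(is.matrix(features))
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L)
    stop("both classes must be present to train a classifier", call. = FALSE)
  if (nrow(features) < 20L)
    stop("at least 20 examples are required", call. = FALSE)
  trainMLP(features, labels, hidden = hidden, seed = seed, epochs = epochs)
}

# Classify every object of a label mask; returns records data.frame rows.
classifyObjects <- function(image, labels, model, dedupGeometric = FALSE) {
  n <- max(labels)
  if (n == 0L) return(NULL)
  X <- extractAllFeatures(image, labels, dedupGeometric)
  predict(model, X)
}
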
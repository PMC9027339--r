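## R-side interface to the compiled compact depthwise-separable CNN.

#' Training configuration for the gait-matrix classifier
#'
#' Defaults follow the training protocol used for the correlation-matrix
#' images: 160 x 160 x 3 inputs, learning rate 0.05, binary cross-entropy
#' over a 2-class softmax, Adam optimizer, stratified 70/10/20
#' train/validation/test split. The epoch default is desk-scale (30); the
#' full protocol value is 150.
#'
#' @param imageDim input image dimensions.
#' @param learningRate optimizer step size.
#' @param epochs training epochs.
#' @param batchSize minibatch size (32, 64 or 128).
#' @param optimizer `"adam"` or `"sgd"` (momentum 0.9).
#' @param split train/validation/test fractions, summing to 1.
#' @param seed RNG seed for initialization, shuffling and splitting.
#' @param augmentFactor dataset enlargement factor (1 = off).
#' @param subjectDisjoint keep all frames of one subject in one partition
#'   (avoids leakage between frames of the same subject).
#' @param channels pointwise channel widths of the four
#'   depthwise-separable blocks.
#' @param architecture only `"compact_dw_sep"` is available; the
#'   external-backbone transfer-learning setting requires downloaded
#'   pretrained weights and is not part of this package.
#' @param clipNorm global gradient-norm clip (numerical safeguard at the
#'   protocol's large learning rate); 0 disables.
#' @return A list of class `"TrainConfig"`.
#' @export
trainConfig <- function(imageDim = c(160L, 160L, 3L), learningRate = 0.05,
                        epochs = 30L, batchSize = 32L,
                        optimizer = c("adam", "sgd"),
                        split = c(train = 0.7, val = 0.1, test = 0.2),
                        seed = 1L, augmentFactor = 1L,
                        subjectDisjoint = TRUE,
                        channels = c(8L, 16L, 32L, 32L),
                        architecture = "compact_dw_sep", clipNorm = 5) {
  optimizer <- match.arg(optimizer)
  if (abs(sum(split) - 1) > 1e-9) stop("split fractions must sum to 1")
  if (learningRate <= 0) stop("learning rate must be positive")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (!batchSize %in% c(32L, 64L, 128L) && batchSize < 1L)
    stop("invalid batch size")
  if (architecture != "compact_dw_sep")
    stop("unsupported architecture: ", architecture,
         " (only compact_dw_sep is available)")
  structure(list(imageDim = as.integer(imageDim),
                 learningRate = learningRate, epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize), optimizer = optimizer,
                 split = split, seed = as.integer(seed),
                 augmentFactor = as.integer(augmentFactor),
                 subjectDisjoint = isTRUE(subjectDisjoint),
                 channels = as.integer(channels),
                 architecture = architecture, clipNorm = clipNorm),
            class = "TrainConfig")
}

.CLASS_LEVELS <- c("physiological", "pd")  # pd is the positive class

#' Train the gait-matrix classifier
#'
#' Trains the compact depthwise-separable CNN (four blocks of 3x3
#' depthwise + 1x1 pointwise convolution, ReLU and 2x2 max pooling,
#' global average pooling, 2-unit softmax head) on labeled matrix images.
#' Training is deterministic given `cfg$seed`.
#'
#' @param train,val datasets from [makeDataset()]/[splitDataset()] (`val`
#'   may be `NULL`).
#' @param cfg a [trainConfig()].
#' @return An object of class `"gaitCNN"` holding the weights, per-epoch
#'   history (loss/accuracy, validation loss/accuracy) and the config.
#' @export
trainClassifier <- function(train, val = NULL, cfg = trainConfig()) {
  stopifnot(inherits(train, "gaitDataset"), nrow(train$manifest) > 0L)
  y <- as.integer(factor(train$manifest$label, levels = .CLASS_LEVELS)) - 1L
  if (anyNA(y)) stop("unlabeled images in the training set")
  vx <- NULL; vy <- NULL
  if (!is.null(val) && nrow(val$manifest) > 0L) {
    vx <- val$images
    vy <- as.integer(factor(val$manifest$label, levels = .CLASS_LEVELS)) - 1L
  }
  fit <- .cnnTrain(train$images, y, cfg$channels, cfg$epochs, cfg$batchSize,
                   cfg$learningRate, cfg$seed, cfg$optimizer, cfg$clipNorm,
                   vx, vy, FALSE)
  if (isTRUE(fit$diverged))
    stop("training diverged (non-finite loss); try a lower learning rate")
  structure(list(weights = fit$weights, history = fit$history, config = cfg),
            class = "gaitCNN")
}

#' @export
print.gaitCNN <- function(x, ...) {
  h <- x$history
  done <- which(is.finite(h$loss))
  last <- if (length(done)) max(done) else 0L
  cat("Compact depthwise-separable gait CNN\n")
  cat("  blocks:", paste(x$config$channels, collapse = "-"),
      "| optimizer:", x$config$optimizer,
      "| lr:", x$config$learningRate, "\n")
  if (last > 0L)
    cat(sprintf("  trained %d epochs; final loss %.4f, accuracy %.3f\n",
                last, h$loss[last], h$acc[last]))
  invisible(x)
}

#' Classify gait-matrix images
#'
#' @param model a trained `"gaitCNN"`.
#' @param images a dataset from [makeDataset()] or an `H x W x 3 x N`
#'   image array matching the model's input dimension.
#' @return A data.frame with per-image class probabilities
#'   (`p_physiological`, `p_pd`, summing to 1) and the argmax `label`.
#'   Inference is deterministic.
#' @export
predictClassifier <- function(model, images) {
  stopifnot(inherits(model, "gaitCNN"))
  x <- if (inherits(images, "gaitDataset")) images$images else images
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (!all(dim(x)[1:3] == model$config$imageDim))
    stop("image dimensions do not match the model input (",
         paste(model$config$imageDim, collapse = " x "), ")")
  p <- .cnnPredict(model$weights, x)
  colnames(p) <- paste0("p_", .CLASS_LEVELS)
  data.frame(p, label = .CLASS_LEVELS[max.col(p, ties.method = "first")])
}
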
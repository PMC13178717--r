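# Differentiable fixture classifiers written in plain matrix algebra, so the
# attack stage has exact input gradients and the RSA stage has penultimate
# features without any external deep-learning dependency.

asInputMatrix <- function(X) {
  if (is.matrix(X)) X
  else if (is.array(X) && length(dim(X)) %in% c(3L, 4L)) flattenImages(X)
  else if (is.numeric(X)) matrix(X, nrow = 1L)
  else stop("X must be an image array or a matrix of flattened images")
}

#' Create a small differentiable fixture classifier
#'
#' Builds an untrained one-hidden-layer ReLU network
#' (`logits = relu(x W1 + b1) W2 + b2`) on flattened `imageSize^2 * 3` pixel
#' inputs. He-style Gaussian initialization scaled by fan-in. With the default
#' 8 hidden units on 64 x 64 RGB inputs the model has ~98k parameters, trains
#' to high accuracy on separable band-coded data within seconds on one CPU,
#' and exposes penultimate features and exact input gradients — a desk-scale
#' stand-in for the deep backbone used in full-scale experiments.
#'
#' @param imageSize input side length in pixels (square RGB images), >= 16
#' @param nClasses number of classes
#' @param hidden hidden-layer width
#' @param seed integer seed for the weight initialization
#' @return an untrained [MLPClassifier-class]
#' @seealso [trainClassifier()], [pgdAttack()], [penultimateFeatures()]
#' @export
makeFixtureClassifier <- function(imageSize = 64L, nClasses = 4L,
                                  hidden = 8L, seed = 0L) {
  imageSize <- as.integer(imageSize)
  nClasses <- as.integer(nClasses)
  hidden <- as.integer(hidden)
  if (imageSize < 16L) stop("imageSize must be >= 16")
  D <- imageSize^2 * 3L
  withSeed(seed, {
    W1 <- matrix(rnorm(D * hidden, sd = sqrt(2 / D)), D, hidden)
    W2 <- matrix(rnorm(hidden * nClasses, sd = sqrt(2 / hidden)),
                 hidden, nClasses)
  })
  new("MLPClassifier", W1 = W1, b1 = numeric(hidden), W2 = W2,
      b2 = numeric(nClasses), imageSize = imageSize, nClasses = nClasses,
      trained = FALSE)
}

#' Create a linear softmax classifier
#'
#' `logits = x W + b`. The closed-form worst-case behavior of linear models
#' under norm-bounded attacks makes this the natural analytic target for
#' validating attack implementations; a zero weight matrix gives a
#' constant-logit model with identically zero input gradients.
#'
#' @param W weight matrix, inputs x classes
#' @param b bias vector, one per class (default zero)
#' @return a [LinearClassifier-class]
#' @export
linearClassifier <- function(W, b = numeric(ncol(W))) {
  new("LinearClassifier", W = W, b = b)
}

## --- MLPClassifier methods ---------------------------------------------

# Input normalization: zero-mean each color channel of each image (the
# analog of dataset normalization). Besides standardizing the input scale
# this makes the network invariant to uniform luminance shifts, so input
# gradients carry spatial structure rather than a DC offset. The map is
# linear and symmetric (a projection), so backprop through it is the same
# subtraction applied to the gradient.
centerChannels <- function(X, nPix) {
  for (c in 0:2) {
    cols <- (c * nPix + 1L):((c + 1L) * nPix)
    X[, cols] <- X[, cols, drop = FALSE] -
      rowMeans(X[, cols, drop = FALSE])
  }
  X
}

mlpForward <- function(model, X) {
  Xc <- centerChannels(X, as.integer(model@imageSize)^2)
  Z1 <- sweep(Xc %*% model@W1, 2L, model@b1, `+`)
  H <- pmax(Z1, 0)
  logits <- sweep(H %*% model@W2, 2L, model@b2, `+`)
  list(Xc = Xc, Z1 = Z1, H = H, logits = logits)
}

#' @rdname model-interface
#' @export
setMethod("predictLogits", "MLPClassifier", function(model, X) {
  mlpForward(model, asInputMatrix(X))$logits
})

#' @rdname model-interface
#' @export
setMethod("predictClasses", "MLPClassifier", function(model, X) {
  max.col(predictLogits(model, X), ties.method = "first")
})

#' @rdname model-interface
#' @export
setMethod("penultimateFeatures", "MLPClassifier", function(model, X) {
  mlpForward(model, asInputMatrix(X))$H
})

#' @rdname model-interface
#' @export
setMethod("inputGradient", "MLPClassifier", function(model, X, y) {
  X <- asInputMatrix(X)
  stopifnot(length(y) == nrow(X))
  fw <- mlpForward(model, X)
  P <- softmaxRows(fw$logits)
  T <- matrix(0, nrow(X), model@nClasses)
  T[cbind(seq_len(nrow(X)), y)] <- 1
  dZ2 <- P - T
  dZ1 <- (dZ2 %*% t(model@W2)) * (fw$Z1 > 0)
  centerChannels(dZ1 %*% t(model@W1), as.integer(model@imageSize)^2)
})

setMethod("show", "MLPClassifier", function(object) {
  D <- nrow(object@W1)
  h <- ncol(object@W1)
  nPar <- length(object@W1) + length(object@b1) +
    length(object@W2) + length(object@b2)
  cat("MLPClassifier: ", D, " -> ", h, " (ReLU) -> ", object@nClasses,
      " classes, ", format(nPar, big.mark = ","), " parameters",
      if (object@trained) " [trained]" else " [untrained]", "\n", sep = "")
})

## --- LinearClassifier methods ------------------------------------------

#' @rdname model-interface
#' @export
setMethod("predictLogits", "LinearClassifier", function(model, X) {
  sweep(asInputMatrix(X) %*% model@W, 2L, model@b, `+`)
})

#' @rdname model-interface
#' @export
setMethod("predictClasses", "LinearClassifier", function(model, X) {
  max.col(predictLogits(model, X), ties.method = "first")
})

#' @rdname model-interface
#' @export
setMethod("penultimateFeatures", "LinearClassifier", function(model, X) {
  asInputMatrix(X)  # the input itself feeds the final linear layer
})

#' @rdname model-interface
#' @export
setMethod("inputGradient", "LinearClassifier", function(model, X, y) {
  X <- asInputMatrix(X)
  stopifnot(length(y) == nrow(X))
  P <- softmaxRows(predictLogits(model, X))
  T <- matrix(0, nrow(X), ncol(model@W))
  T[cbind(seq_len(nrow(X)), y)] <- 1
  (P - T) %*% t(model@W)
})

## --- Training ----------------------------------------------------------

# Cross-entropy with optional label smoothing; logits n x K, y integer.
crossEntropy <- function(logits, y, smoothing = 0) {
  n <- nrow(logits); K <- ncol(logits)
  logZ <- log(rowSums(exp(logits - apply(logits, 1L, max)))) +
    apply(logits, 1L, max)
  logP <- logits - logZ
  T <- matrix(smoothing / K, n, K)
  T[cbind(seq_len(n), y)] <- T[cbind(seq_len(n), y)] + (1 - smoothing)
  -sum(T * logP) / n
}

#' Train a classifier with minibatch SGD
#'
#' Stochastic gradient descent with momentum, weight decay, a single step
#' learning-rate decay, and label smoothing — the optimization recipe used by
#' full-scale experiments (60 epochs, momentum 0.9, weight decay 1e-4, lr 0.1
#' decayed x0.1 at epoch 45, batch 1024, smoothing 0.1), with desk-scale
#' defaults suitable for the fixture network. An [AugmentationPolicy-class]
#' may be supplied; it is applied to each minibatch independently every epoch
#' (one fresh mask and phase field per replaced image per step) and never to
#' any evaluation data. A `NULL` policy or `replaceProb = 0` makes the
#' augmentation path a no-op.
#'
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model an [MLPClassifier-class]
#' @param images N x H x W x 3 array (or N x D matrix of flattened pixels)
#' @param labelsVec integer class labels in 1..nClasses
#' @param epochs training epochs
#' @param lr initial learning rate
#' @param momentum SGD momentum
#' @param weightDecay L2 penalty coefficient
#' @param batchSize minibatch size
#' @param labelSmoothing label-smoothing mass in `[0, 1)`
#' @param lrDecayEpoch epoch at which lr is multiplied by `lrDecayFactor`
#' @param lrDecayFactor learning-rate decay multiplier
#' @param policy optional [AugmentationPolicy-class] applied to minibatches
#' @param seed seed controlling shuffling, augmentation draws and their order
#' @return a list with `model` (trained [MLPClassifier-class]) and `log`
#'   (data.frame of per-epoch `epoch`, `loss`, `accuracy` on the training
#'   data as seen, i.e. post-augmentation)
#' @export
trainClassifier <- function(model, images, labelsVec,
                            epochs = 30L, lr = 0.1, momentum = 0.9,
                            weightDecay = 1e-4, batchSize = 64L,
                            labelSmoothing = 0.1, lrDecayEpoch = 20L,
                            lrDecayFactor = 0.1, policy = NULL, seed = 0L) {
  stopifnot(is(model, "MLPClassifier"))
  labelsVec <- as.integer(labelsVec)
  usePolicy <- !is.null(policy) && policy@replaceProb > 0
  size <- model@imageSize
  if (usePolicy && !(is.array(images) && length(dim(images)) == 4L))
    stop("augmentation policies require images as an N x H x W x 3 array")
  Xall <- if (is.matrix(images)) images else flattenImages(images)
  n <- nrow(Xall)
  stopifnot(length(labelsVec) == n, all(labelsVec >= 1L),
            all(labelsVec <= model@nClasses))
  vW1 <- matrix(0, nrow(model@W1), ncol(model@W1)); vb1 <- numeric(length(model@b1))
  vW2 <- matrix(0, nrow(model@W2), ncol(model@W2)); vb2 <- numeric(length(model@b2))
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  K <- model@nClasses
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      lrEp <- if (ep >= lrDecayEpoch) lr * lrDecayFactor else lr
      ord <- sample.int(n)
      epLoss <- 0; epCorrect <- 0L
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        if (usePolicy) {
          aug <- applyPolicy(images[idx, , , , drop = FALSE], policy)
          Xb <- flattenImages(aug)
        } else {
          Xb <- Xall[idx, , drop = FALSE]
        }
        yb <- labelsVec[idx]
        m <- length(idx)
        fw <- mlpForward(model, Xb)
        P <- softmaxRows(fw$logits)
        T <- matrix(labelSmoothing / K, m, K)
        T[cbind(seq_len(m), yb)] <- T[cbind(seq_len(m), yb)] +
          (1 - labelSmoothing)
        loss <- crossEntropy(fw$logits, yb, labelSmoothing)
        if (!is.finite(loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        epLoss <- epLoss + loss * m
        epCorrect <- epCorrect +
          sum(max.col(fw$logits, ties.method = "first") == yb)
        dZ2 <- (P - T) / m
        dW2 <- t(fw$H) %*% dZ2 + weightDecay * model@W2
        db2 <- colSums(dZ2)
        dZ1 <- (dZ2 %*% t(model@W2)) * (fw$Z1 > 0)
        dW1 <- t(fw$Xc) %*% dZ1 + weightDecay * model@W1
        db1 <- colSums(dZ1)
        vW1 <- momentum * vW1 - lrEp * dW1; model@W1 <- model@W1 + vW1
        vb1 <- momentum * vb1 - lrEp * db1; model@b1 <- model@b1 + vb1
        vW2 <- momentum * vW2 - lrEp * dW2; model@W2 <- model@W2 + vW2
        vb2 <- momentum * vb2 - lrEp * db2; model@b2 <- model@b2 + vb2
      }
      log <- rbind(log, data.frame(epoch = ep, loss = epLoss / n,
                                   accuracy = epCorrect / n))
    }
  })
  model@trained <- TRUE
  list(model = model, log = log)
}
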
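#' Construct a residual-network model configuration
#'
#' The default architecture follows the small residual-network pattern: a
#' stem convolution (7x7, stride 2, pad 3) with batch normalization and
#' ReLU, four stages each opened by one convolution residual block
#' (projection shortcut; stride 1 in stage 1, stride 2 afterwards) and
#' continued by identity residual blocks per `stagePlan` (default 1,2,2,1,
#' i.e. exactly 4 convolution + 6 identity blocks), global average pooling
#' and a fully connected classification layer.  Training defaults follow
#' common practice for this model family: SGD with learning rate 0.01,
#' weight decay 1e-4, momentum 0.9, 40 epochs.
#'
#' @param nClasses number of classes (>= 2)
#' @param inputSize input image side in pixels (default 224)
#' @param stagePlan identity blocks per stage, length 4
#' @param channels stage widths, length 4
#' @param stemChannels stem output channels (differs from `channels[1]` so
#'   that every stage opener genuinely changes dimensions)
#' @param stemFilter,stemStride,stemPad stem convolution geometry
#' @param learningRate,weightDecay,momentum SGD hyperparameters
#' @param lrSchedule `"step"` (default: learning rate divided by 10 at 50%
#'   and 75% of the epochs) or `"constant"`
#' @param epochs,batchSize training schedule
#' @param seed integer seed for initialization, shuffling and augmentation
#' @param augmentation subset of `c("crop", "transpose")`; random resized
#'   crop (0.9-1.0 scale) and transpose flip.  The transpose flip is only
#'   label-preserving for symmetric (synchronous) maps -- disable it when
#'   training on asynchronous or integrative images
#' @return a [ModelConfig]
#' @examples
#' modelConfig(7)
#' @export
modelConfig <- function(nClasses, inputSize = 224L,
                        stagePlan = c(1L, 2L, 2L, 1L),
                        channels = c(16L, 32L, 64L, 128L),
                        stemChannels = 8L, stemFilter = 7L, stemStride = 2L,
                        stemPad = 3L, learningRate = 0.01,
                        lrSchedule = c("step", "constant"),
                        weightDecay = 1e-4, momentum = 0.9, epochs = 40L,
                        batchSize = 16L, seed = 1L,
                        augmentation = c("crop", "transpose")) {
  methods::new("ModelConfig", inputSize = as.integer(inputSize),
               nClasses = as.integer(nClasses),
               stagePlan = as.integer(stagePlan),
               channels = as.integer(channels),
               stemChannels = as.integer(stemChannels),
               stemFilter = as.integer(stemFilter),
               stemStride = as.integer(stemStride),
               stemPad = as.integer(stemPad),
               learningRate = as.numeric(learningRate),
               lrSchedule = match.arg(lrSchedule),
               weightDecay = as.numeric(weightDecay),
               momentum = as.numeric(momentum), epochs = as.integer(epochs),
               batchSize = as.integer(batchSize), seed = as.integer(seed),
               augmentation = as.character(augmentation))
}

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: %dpx input, %d classes, stages [%s] identity blocks @ [%s] channels\n",
    object@inputSize, object@nClasses,
    paste(object@stagePlan, collapse = ","),
    paste(object@channels, collapse = ",")))
  cat(sprintf("  SGD lr=%g, weight decay=%g, momentum=%g, %d epochs, batch %d, seed %d\n",
              object@learningRate, object@weightDecay, object@momentum,
              object@epochs, object@batchSize, object@seed))
})

#' Build the residual network
#'
#' Instantiates the layer graph described by the configuration: stem
#' convolution -> batch normalization -> ReLU -> 4 stages (one convolution
#' residual block + identity residual blocks each) -> global average pooling
#' -> fully connected layer with `nClasses` outputs.  Every residual block
#' computes `output = F(x) + shortcut(x)`; identity blocks use the identity
#' shortcut (shapes preserved), convolution blocks a 1x1 projection.
#' Weights are He-initialized from the configuration seed.
#'
#' @param cfg a [ModelConfig]
#' @param inputChannels image channels (3 for RGB renderings)
#' @return model object (list of layer environments) of class `"resnetModel"`
#' @examples
#' m <- buildModel(modelConfig(7, inputSize = 32, channels = c(4L, 8L, 16L, 32L),
#'                             stemChannels = 2L))
#' countBlocks(m)
#' @export
buildModel <- function(cfg, inputChannels = 3L) {
  stopifnot(methods::is(cfg, "ModelConfig"))
  methods::validObject(cfg)
  rng <- .localRNG(cfg@seed)
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$inputChannels <- as.integer(inputChannels)
  model$stemConv <- .newConv(inputChannels, cfg@stemChannels, cfg@stemFilter,
                             cfg@stemStride, cfg@stemPad, rng)
  model$stemBn <- .newBN(cfg@stemChannels)
  cin <- cfg@stemChannels
  model$stages <- vector("list", 4L)
  for (s in 1:4) {
    stride <- if (s == 1L) 1L else 2L
    blocks <- list(.newBlock("convolution", cin, cfg@channels[s], stride, rng))
    cin <- cfg@channels[s]
    for (i in seq_len(cfg@stagePlan[s]))
      blocks <- c(blocks, list(.newBlock("identity", cin, cin, 1L, rng)))
    model$stages[[s]] <- blocks
  }
  model$fc <- .newFC(cin, cfg@nClasses, rng)
  model$classLevels <- NULL
  class(model) <- "resnetModel"
  model
}

#' @export
print.resnetModel <- function(x, ...) {
  nb <- countBlocks(x)
  cat(sprintf("resnetModel: %d convolution + %d identity residual blocks, %d classes\n",
              nb[["convolution"]], nb[["identity"]], x$cfg@nClasses))
  invisible(x)
}

#' Count residual blocks by kind
#'
#' @param model a model from [buildModel()]
#' @return named integer vector with entries `convolution` and `identity`
#' @export
countBlocks <- function(model) {
  kinds <- vapply(.modelBlocks(model), function(b) b$kind, character(1))
  c(convolution = sum(kinds == "convolution"),
    identity = sum(kinds == "identity"))
}

#' Audit convolution shapes against the output-size formula
#'
#' Runs one forward pass recording each convolution's observed input and
#' output spatial sides, and compares the observed outputs with
#' [convOutputSize()] applied to the layer's (pad, filter, stride).
#'
#' @param model a model from [buildModel()]
#' @return data.frame with columns nIn, pad, filt, stride, nOut, predicted
#' @export
auditShapes <- function(model) {
  cfg <- model$cfg
  x <- array(0, dim = c(cfg@inputSize, cfg@inputSize, model$inputChannels, 1L))
  .modelF(model, x, train = FALSE, audit = TRUE)
  convs <- Filter(function(l) l$type == "conv", .modelLayers(model))
  do.call(rbind, lapply(convs, function(l)
    data.frame(nIn = l$lastIn, pad = l$pad, filt = l$f, stride = l$stride,
               nOut = l$lastOut,
               predicted = convOutputSize(l$lastIn, l$pad, l$f, l$stride))))
}

# images: array (H, W, C, N); returns augmented copy (training only)
.augmentBatch <- function(x, augmentation, rng) {
  if (!length(augmentation)) return(x)
  d <- dim(x)
  H <- d[1]
  for (n in seq_len(d[4])) {
    img <- x[, , , n, drop = FALSE]
    dim(img) <- d[1:3]
    if ("crop" %in% augmentation) {
      scale <- rng$runif(1, 0.9, 1)
      side <- max(2L, as.integer(round(scale * H)))
      if (side < H) {
        off1 <- as.integer(rng$sample(seq_len(H - side + 1L), 1L))
        off2 <- as.integer(rng$sample(seq_len(H - side + 1L), 1L))
        crop <- img[off1:(off1 + side - 1L), off2:(off2 + side - 1L), ,
                    drop = FALSE]
        for (c in seq_len(d[3]))
          img[, , c] <- .resampleBilinear(crop[, , c], H)
      }
    }
    if ("transpose" %in% augmentation && rng$runif(1) < 0.5)
      img <- aperm(img, c(2, 1, 3))
    x[, , , n] <- img
  }
  x
}

#' Train the residual network
#'
#' Runs `cfg@epochs` epochs of stochastic gradient descent (momentum,
#' weight decay) minimizing cross-entropy on the training images, logging
#' per-epoch training accuracy/loss (computed on the fly from the training
#' forward passes) and test accuracy/loss (inference mode; batch
#' normalization statistics are re-estimated on the full training set after
#' every epoch, so evaluation always uses statistics consistent with the
#' current weights).  The optimal
#' model is selected over the run: parameters are checkpointed at the epoch
#' with the highest test accuracy (earliest on ties) and restored before the
#' final external validation, so `model` leaves this function in its
#' selected state; the history still records every epoch.  All randomness
#' (shuffling, augmentation) comes from the configuration seed, so repeated
#' runs on one device are identical.
#'
#' @param model a model from [buildModel()]
#' @param trainImages array H x W x C x N of training images
#' @param trainLabels factor (or character) of training labels; every model
#'   class must be present
#' @param testImages,testLabels test set (required, evaluated each epoch)
#' @param externalImages,externalLabels optional external-validation set,
#'   evaluated once after the final epoch
#' @return a [TrainReport]
#' @export
trainModel <- function(model, trainImages, trainLabels, testImages,
                       testLabels, externalImages = NULL,
                       externalLabels = NULL) {
  cfg <- model$cfg
  if (length(dim(trainImages)) != 4L || dim(trainImages)[4] < 1L)
    stop("training image set must be a non-empty H x W x C x N array")
  if (length(dim(testImages)) != 4L || dim(testImages)[4] < 1L)
    stop("test image set must be a non-empty H x W x C x N array")
  lvl <- model$classLevels
  if (is.null(lvl))
    lvl <- sort(unique(c(as.character(trainLabels), as.character(testLabels))))
  if (length(lvl) != cfg@nClasses)
    stop(sprintf("found %d classes but the model has %d outputs",
                 length(lvl), cfg@nClasses))
  missing <- setdiff(lvl, as.character(trainLabels))
  if (length(missing))
    stop("class missing from the training set: ", paste(missing, collapse = ", "))
  model$classLevels <- lvl
  yTrain <- match(as.character(trainLabels), lvl)
  yTest <- match(as.character(testLabels), lvl)
  if (anyNA(yTest)) stop("test labels outside the training classes")
  n <- dim(trainImages)[4]
  rng <- .localRNG(cfg@seed + 1L)
  hist <- vector("list", cfg@epochs)
  bestAcc <- -Inf; bestEpoch <- 0L; bestState <- NULL
  for (epoch in seq_len(cfg@epochs)) {
    lr <- cfg@learningRate
    if (cfg@lrSchedule == "step")
      lr <- lr * 0.1^sum(epoch > c(0.5, 0.75) * cfg@epochs)
    ord <- rng$sample(n, n)
    correct <- 0; lossSum <- 0; seen <- 0
    for (start in seq(1, n, by = cfg@batchSize)) {
      idx <- ord[start:min(start + cfg@batchSize - 1L, n)]
      xb <- trainImages[, , , idx, drop = FALSE]
      xb <- .augmentBatch(xb, cfg@augmentation, rng)
      logits <- .modelF(model, xb, train = TRUE)
      ce <- .ceLoss(logits, yTrain[idx])
      .modelB(model, ce$grad)
      .sgdStep(model, lr, cfg@momentum, cfg@weightDecay)
      pred <- max.col(t(logits), ties.method = "first")
      correct <- correct + sum(pred == yTrain[idx])
      lossSum <- lossSum + ce$loss * length(idx)
      seen <- seen + length(idx)
    }
    .refreshBNStats(model, trainImages)
    testEval <- evaluateModel(model, testImages, testLabels)
    hist[[epoch]] <- data.frame(epoch = epoch, trainAcc = correct / seen,
                                trainLoss = lossSum / seen,
                                testAcc = testEval$accuracy,
                                testLoss = testEval$loss)
    if (testEval$accuracy > bestAcc) {
      bestAcc <- testEval$accuracy
      bestEpoch <- epoch
      bestState <- .modelState(model)
    }
  }
  history <- do.call(rbind, hist)
  .restoreState(model, bestState)        # keep the selected optimal model
  extAcc <- NA_real_
  if (!is.null(externalImages)) {
    extEval <- evaluateModel(model, externalImages, externalLabels)
    extAcc <- extEval$accuracy
  }
  methods::new("TrainReport", history = history,
               finalTrainAcc = history$trainAcc[cfg@epochs],
               finalTestAcc = history$testAcc[cfg@epochs],
               externalAcc = extAcc, bestTestAcc = bestAcc,
               bestEpoch = bestEpoch,
               finalLoss = history$trainLoss[bestEpoch],
               config = .configSnapshot(cfg), seed = cfg@seed)
}

.configSnapshot <- function(cfg) {
  nm <- methods::slotNames(cfg)
  stats::setNames(lapply(nm, function(s) methods::slot(cfg, s)), nm)
}

#' Evaluate the model on an image set
#'
#' @param model a trained model
#' @param images array H x W x C x N (non-empty)
#' @param labels class labels, one per image
#' @param batchSize forward batch size
#' @return list with `accuracy`, `loss` (mean cross-entropy) and
#'   `confusion` (true x predicted counts)
#' @export
evaluateModel <- function(model, images, labels, batchSize = 32L) {
  if (length(dim(images)) != 4L || dim(images)[4] < 1L)
    stop("cannot evaluate an empty image set")
  lvl <- model$classLevels
  if (is.null(lvl)) lvl <- sort(unique(as.character(labels)))
  y <- match(as.character(labels), lvl)
  if (anyNA(y)) stop("labels outside the model's classes")
  n <- dim(images)[4]
  preds <- integer(n); lossSum <- 0
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, n)
    logits <- .modelF(model, images[, , , idx, drop = FALSE], train = FALSE)
    ce <- .ceLoss(logits, y[idx])
    lossSum <- lossSum + ce$loss * length(idx)
    preds[idx] <- max.col(t(logits), ties.method = "first")
  }
  confusion <- table(factor(lvl[y], levels = lvl),
                     factor(lvl[preds], levels = lvl))
  list(accuracy = mean(preds == y), loss = lossSum / n, confusion = confusion)
}

#' Class-probability predictions
#'
#' @param model a trained model
#' @param images one image (H x W x C) or a batch (H x W x C x N)
#' @return matrix nClasses x N of softmax probabilities (columns sum to 1),
#'   rows named by class
#' @export
predictModel <- function(model, images) {
  d <- dim(images)
  if (length(d) == 3L) images <- array(images, dim = c(d, 1L))
  p <- .softmax(.modelF(model, images, train = FALSE))
  if (!is.null(model$classLevels)) rownames(p) <- model$classLevels
  p
}
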
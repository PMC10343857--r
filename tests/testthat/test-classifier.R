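test_that("convOutputSize implements the padded-convolution formula", {
  expect_equal(convOutputSize(224, pad = 3, filt = 7, stride = 2), 112)
  expect_equal(convOutputSize(10, 0, 1, 1), 10)       # 1x1 identity geometry
  expect_equal(convOutputSize(5, 0, 3, 1), 3)
  expect_error(convOutputSize(3, 0, 7, 1), "filter exceeds")
})

test_that("the default model has 4 convolution and 6 identity residual blocks", {
  m <- buildModel(modelConfig(7))
  nb <- countBlocks(m)
  expect_equal(nb[["convolution"]], 4)
  expect_equal(nb[["identity"]], 6)
  m2 <- buildModel(modelConfig(2, stagePlan = c(2L, 1L, 2L, 1L)))
  expect_equal(countBlocks(m2)[["identity"]], 6)
  expect_error(modelConfig(7, stagePlan = c(1L, 2L, 2L)), "4 stages")
})

test_that("every convolution's observed output matches the size formula", {
  audit <- auditShapes(buildModel(tinyConfig()))
  expect_gt(nrow(audit), 10)
  expect_equal(audit$nOut, audit$predicted)
  audit224 <- auditShapes(buildModel(modelConfig(7)))
  expect_equal(audit224$nOut, audit224$predicted)
  expect_equal(audit224$nIn[1], 224)
})

test_that("identity blocks preserve shapes and reduce to the identity map when F is zeroed", {
  ns <- asNamespace("ir2dcos")
  m <- buildModel(tinyConfig())
  blk <- m$stages[[2]][[2]]                  # an identity block
  expect_equal(blk$kind, "identity")
  rng <- ns$.localRNG(3)
  x <- array(abs(rng$rnorm(8 * 8 * 8 * 2)), dim = c(8, 8, 8, 2))
  y <- ns$.blockF(blk, x, train = FALSE)
  expect_equal(dim(y), dim(x))               # shape-preserving contract
  # zero the residual branch's final scale/shift: H(x) = 0 + x, and the
  # trailing ReLU is transparent for non-negative input
  blk$bn2$gamma[] <- 0; blk$bn2$beta[] <- 0
  expect_identical(ns$.blockF(blk, x, train = FALSE), x)
})

test_that("the final layer emits one logit per class and softmax sums to 1", {
  m <- buildModel(tinyConfig(nClasses = 2L))
  x <- array(runif(16 * 16 * 3 * 3), dim = c(16, 16, 3, 3))
  p <- predictModel(m, x)
  expect_equal(dim(p), c(2, 3))
  expect_equal(colSums(p), rep(1, 3), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicate inputs give identical outputs
  xdup <- x[, , , c(1, 1), drop = FALSE]
  pd <- predictModel(m, xdup)
  expect_identical(pd[, 1], pd[, 2])
  # a single image is accepted as a 3-D array
  p1 <- predictModel(m, x[, , , 1])
  expect_equal(p1[, 1], p[, 1])
})

test_that("a zero learning rate leaves parameters untouched and the loss flat", {
  ns <- asNamespace("ir2dcos")
  toy <- toyImages(4, seed = 2)
  m <- buildModel(tinyConfig(epochs = 3L, learningRate = 0,
                             lrSchedule = "constant"))
  before <- ns$.modelState(m)
  rep <- trainModel(m, toy$x, toy$labels, toy$x, toy$labels)
  after <- ns$.modelState(m)
  for (i in seq_along(before)) {
    if (before[[i]]$type == "bn") {
      expect_identical(before[[i]]$gamma, after[[i]]$gamma)
      expect_identical(before[[i]]$beta, after[[i]]$beta)
    } else {
      expect_identical(before[[i]]$w, after[[i]]$w)
    }
  }
  expect_lt(diff(range(rep@history$trainLoss)), 1e-8)
})

test_that("training errors out before starting when a class is absent", {
  toy <- toyImages(4)
  m <- buildModel(tinyConfig())
  onlyOne <- toy$x[, , , 1:4, drop = FALSE]
  expect_error(trainModel(m, onlyOne, toy$labels[1:4], toy$x, toy$labels),
               "missing from the training set")
})

test_that("the model fits a small linearly separable image set perfectly", {
  toy <- toyImages(8, seed = 5)                # 16 images, 2 classes
  m <- buildModel(tinyConfig(epochs = 30L, seed = 4L))
  rep <- trainModel(m, toy$x, toy$labels, toy$x, toy$labels)
  expect_equal(rep@finalTrainAcc, 1)
  ev <- evaluateModel(m, toy$x, toy$labels)
  expect_equal(ev$accuracy, 1)
  expect_lt(min(rep@history$trainLoss), 0.01)  # capacity: loss driven near 0
  # argmax of predict agrees with evaluate's bookkeeping
  p <- predictModel(m, toy$x)
  expect_equal(mean(rownames(p)[apply(p, 2, which.max)] == toy$labels),
               ev$accuracy)
})

test_that("training is reproducible from the configuration seed", {
  toy <- toyImages(4, seed = 8)
  r1 <- trainModel(buildModel(tinyConfig(epochs = 4L, seed = 11L)),
                   toy$x, toy$labels, toy$x, toy$labels)
  r2 <- trainModel(buildModel(tinyConfig(epochs = 4L, seed = 11L)),
                   toy$x, toy$labels, toy$x, toy$labels)
  expect_identical(r1@history, r2@history)
  expect_identical(r1@finalLoss, r2@finalLoss)
})

test_that("evaluation reports chance accuracy for a constant predictor and rejects empty sets", {
  toy <- toyImages(7, seed = 3)
  m <- buildModel(tinyConfig())
  # force a constant prediction: zero features' weight, bias towards class 1
  m$fc$w[] <- 0
  m$fc$b <- c(10, -10)
  m$classLevels <- c("class1", "class2")
  ev <- evaluateModel(m, toy$x, toy$labels)
  expect_equal(ev$accuracy, 0.5)               # balanced two-class set
  expect_equal(unname(rowSums(ev$confusion)), c(7, 7))
  expect_equal(sum(ev$confusion), 14)
  expect_error(evaluateModel(m, array(0, dim = c(16, 16, 3, 0)),
                             character(0)), "empty")
})
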
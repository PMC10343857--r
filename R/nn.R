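# Minimal residual-network engine.  Layers are environments (parameters are
# updated in place during SGD); activations are 4-D arrays (H, W, C, N).
# Convolutions run through the compiled im2col+GEMM kernels in src/.

#' Convolutional layer output size
#'
#' `floor((nIn + 2*pad - filt) / stride) + 1`: the spatial side of a
#' convolution output given input side, padding, filter side and stride.
#'
#' @param nIn input side (pixels)
#' @param pad zero padding per side
#' @param filt filter side
#' @param stride stride
#' @return output side; errors when the result is non-positive
#' @examples
#' convOutputSize(224, pad = 3, filt = 7, stride = 2)  # 112
#' convOutputSize(5, 0, 3, 1)                          # 3
#' @export
convOutputSize <- function(nIn, pad, filt, stride) {
  stopifnot(nIn > 0, pad >= 0, filt > 0, stride > 0)
  if (filt > nIn + 2 * pad) stop("filter exceeds padded input")
  out <- (nIn + 2 * pad - filt) %/% stride + 1
  if (out <= 0) stop("non-positive convolution output size")
  as.integer(out)
}

.newConv <- function(cin, cout, f, stride, pad, rng) {
  l <- new.env(parent = emptyenv())
  l$type <- "conv"
  l$f <- as.integer(f); l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  sdw <- sqrt(2 / (f * f * cin))                       # He initialization
  l$w <- array(rng$rnorm(f * f * cin * cout, 0, sdw), dim = c(f, f, cin, cout))
  l$b <- numeric(cout)
  l$vw <- array(0, dim = dim(l$w)); l$vb <- numeric(cout)
  l
}

.newBN <- function(c) {
  l <- new.env(parent = emptyenv())
  l$type <- "bn"
  l$gamma <- rep(1, c); l$beta <- numeric(c)
  l$runMean <- numeric(c); l$runVar <- rep(1, c)
  l$eps <- 1e-5; l$bnMomentum <- 0.1
  l$vgamma <- numeric(c); l$vbeta <- numeric(c)
  l
}

.newFC <- function(cin, cout, rng) {
  l <- new.env(parent = emptyenv())
  l$type <- "fc"
  l$w <- matrix(rng$rnorm(cin * cout, 0, sqrt(2 / cin)), nrow = cin)
  l$b <- numeric(cout)
  l$vw <- matrix(0, cin, cout); l$vb <- numeric(cout)
  l
}

.convF <- function(l, x, audit = FALSE) {
  y <- .convForward(x, l$w, l$b, l$stride, l$pad)
  if (audit) { l$lastIn <- dim(x)[1]; l$lastOut <- dim(y)[1] }
  y
}

.convB <- function(l, x, dy) {
  g <- .convBackward(x, l$w, dy, l$stride, l$pad)
  l$gw <- g$dw; l$gb <- g$db
  g$dx
}

.bnF <- function(l, x, train) {
  d <- dim(x)
  C <- d[3]
  y <- x
  if (train) {
    mu <- numeric(C); va <- numeric(C); xhat <- x
    for (c in seq_len(C)) {
      xc <- x[, , c, , drop = FALSE]
      mu[c] <- mean(xc)
      va[c] <- mean((xc - mu[c])^2)
      xhat[, , c, ] <- (xc - mu[c]) / sqrt(va[c] + l$eps)
      y[, , c, ] <- l$gamma[c] * xhat[, , c, , drop = FALSE] + l$beta[c]
    }
    l$runMean <- (1 - l$bnMomentum) * l$runMean + l$bnMomentum * mu
    l$runVar <- (1 - l$bnMomentum) * l$runVar + l$bnMomentum * va
    l$cacheXhat <- xhat
    l$cacheInvStd <- 1 / sqrt(va + l$eps)
  } else {
    for (c in seq_len(C))
      y[, , c, ] <- l$gamma[c] *
        (x[, , c, , drop = FALSE] - l$runMean[c]) / sqrt(l$runVar[c] + l$eps) +
        l$beta[c]
  }
  y
}

.bnB <- function(l, dy) {
  d <- dim(dy)
  C <- d[3]
  xhat <- l$cacheXhat
  dx <- dy
  ggamma <- numeric(C); gbeta <- numeric(C)
  for (c in seq_len(C)) {
    dyc <- dy[, , c, , drop = FALSE]
    xc <- xhat[, , c, , drop = FALSE]
    gbeta[c] <- sum(dyc)
    ggamma[c] <- sum(dyc * xc)
    dxhat <- dyc * l$gamma[c]
    dx[, , c, ] <- l$cacheInvStd[c] *
      (dxhat - mean(dxhat) - xc * mean(dxhat * xc))
  }
  l$ggamma <- ggamma; l$gbeta <- gbeta
  l$cacheXhat <- NULL
  dx
}

.reluF <- function(x) { x[x < 0] <- 0; x }

# -- residual blocks -------------------------------------------------------

.newBlock <- function(kind, cin, cout, stride, rng) {
  b <- new.env(parent = emptyenv())
  b$kind <- kind
  b$conv1 <- .newConv(cin, cout, 3L, stride, 1L, rng)
  b$bn1 <- .newBN(cout)
  b$conv2 <- .newConv(cout, cout, 3L, 1L, 1L, rng)
  b$bn2 <- .newBN(cout)
  if (kind == "convolution") {
    b$proj <- .newConv(cin, cout, 1L, stride, 0L, rng)
    b$projBn <- .newBN(cout)
  } else if (cin != cout || stride != 1L) {
    stop("an identity block must preserve channels and spatial size")
  }
  b
}

.blockF <- function(b, x, train, audit = FALSE) {
  a1 <- .convF(b$conv1, x, audit)
  a2 <- .bnF(b$bn1, a1, train)
  a3 <- .reluF(a2)
  a4 <- .convF(b$conv2, a3, audit)
  f <- .bnF(b$bn2, a4, train)
  s <- if (b$kind == "convolution")
    .bnF(b$projBn, .convF(b$proj, x, audit), train) else x
  out <- .reluF(f + s)
  if (train) b$cache <- list(x = x, a3 = a3, preRelu = f + s)
  out
}

.blockB <- function(b, dy) {
  cc <- b$cache
  dy <- dy * (cc$preRelu > 0)              # through the final ReLU
  # main branch
  d4 <- .bnB(b$bn2, dy)
  d3 <- .convB(b$conv2, cc$a3, d4)
  d3 <- d3 * (cc$a3 > 0)                   # a3 = relu(a2): mask where a3 > 0
  d1 <- .bnB(b$bn1, d3)
  dxMain <- .convB(b$conv1, cc$x, d1)
  # shortcut branch
  dxShort <- if (b$kind == "convolution") {
    dp <- .bnB(b$projBn, dy)
    .convB(b$proj, cc$x, dp)
  } else dy
  b$cache <- NULL
  dxMain + dxShort
}

.blockLayers <- function(b) {
  ls <- list(b$conv1, b$bn1, b$conv2, b$bn2)
  if (b$kind == "convolution") ls <- c(ls, list(b$proj, b$projBn))
  ls
}

# -- whole model -----------------------------------------------------------

.modelLayers <- function(model) {
  ls <- list(model$stemConv, model$stemBn)
  for (st in model$stages) for (b in st) ls <- c(ls, .blockLayers(b))
  c(ls, list(model$fc))
}

.modelBlocks <- function(model) {
  out <- list()
  for (st in model$stages) for (b in st) out <- c(out, list(b))
  out
}

.modelF <- function(model, x, train = FALSE, audit = FALSE) {
  a <- .convF(model$stemConv, x, audit)
  a <- .bnF(model$stemBn, a, train)
  preRelu <- a
  a <- .reluF(a)
  if (train) model$stemCache <- list(x = x, preRelu = preRelu)
  for (st in model$stages) for (b in st) a <- .blockF(b, a, train, audit)
  d <- dim(a)
  model$gapDim <- d
  z <- matrix(colMeans(matrix(a, d[1] * d[2], d[3] * d[4])), d[3], d[4])
  logits <- crossprod(model$fc$w, z) + model$fc$b
  if (train) model$headCache <- list(z = z)
  logits                                   # nClasses x N
}

.modelB <- function(model, dlogits) {
  z <- model$headCache$z
  model$fc$gw <- z %*% t(dlogits)
  model$fc$gb <- rowSums(dlogits)
  dz <- model$fc$w %*% dlogits             # C x N
  d <- model$gapDim
  da <- array(rep(as.numeric(dz) / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  for (st in rev(model$stages)) for (b in rev(st)) da <- .blockB(b, da)
  da <- da * (model$stemCache$preRelu > 0)
  da <- .bnB(model$stemBn, da)
  .convB(model$stemConv, model$stemCache$x, da)
  model$stemCache <- NULL; model$headCache <- NULL
  invisible(NULL)
}

.softmax <- function(logits) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  sweep(e, 2, colSums(e), `/`)
}

# cross-entropy loss + gradient w.r.t. logits; labels are integers 1..K
.ceLoss <- function(logits, labels) {
  p <- .softmax(logits)
  n <- ncol(p)
  picked <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  g <- p
  g[cbind(labels, seq_len(n))] <- g[cbind(labels, seq_len(n))] - 1
  list(loss = loss, grad = g / n, prob = p)
}

.sgdStep <- function(model, lr, momentum, weightDecay) {
  for (l in .modelLayers(model)) {
    if (l$type %in% c("conv", "fc")) {
      l$vw <- momentum * l$vw - lr * (l$gw + weightDecay * l$w)
      l$w <- l$w + l$vw
      l$vb <- momentum * l$vb - lr * l$gb
      l$b <- l$b + l$vb
    } else if (l$type == "bn") {
      l$vgamma <- momentum * l$vgamma - lr * l$ggamma
      l$gamma <- l$gamma + l$vgamma
      l$vbeta <- momentum * l$vbeta - lr * l$gbeta
      l$beta <- l$beta + l$vbeta
    }
  }
}

# snapshot of all parameters (for checkpointing, determinism checks and
# serialization)
.modelState <- function(model) {
  lapply(.modelLayers(model), function(l) {
    if (l$type == "bn")
      list(type = "bn", gamma = l$gamma, beta = l$beta,
           runMean = l$runMean, runVar = l$runVar)
    else list(type = l$type, w = l$w, b = l$b)
  })
}

# Re-estimate BatchNorm running statistics from one full pass over a
# reference image set ("precise BN"): eliminates the lag between running
# statistics and the current weights before an inference-mode evaluation.
.refreshBNStats <- function(model, images) {
  layers <- .modelLayers(model)
  bns <- Filter(function(l) l$type == "bn", layers)
  old <- lapply(bns, function(l) l$bnMomentum)
  for (l in bns) l$bnMomentum <- 1
  .modelF(model, images, train = TRUE)
  for (i in seq_along(bns)) bns[[i]]$bnMomentum <- old[[i]]
  for (l in bns) { l$cacheXhat <- NULL; l$cacheInvStd <- NULL }
  for (b in .modelBlocks(model)) b$cache <- NULL
  model$stemCache <- NULL; model$headCache <- NULL
  invisible(model)
}

.restoreState <- function(model, state) {
  layers <- .modelLayers(model)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    l <- layers[[i]]; s <- state[[i]]
    stopifnot(identical(l$type, s$type))
    if (l$type == "bn") {
      l$gamma <- s$gamma; l$beta <- s$beta
      l$runMean <- s$runMean; l$runVar <- s$runVar
    } else {
      l$w <- s$w; l$b <- s$b
    }
  }
  invisible(model)
}
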
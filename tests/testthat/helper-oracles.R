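# Independent oracles, deliberately written as naive explicit loops so they
# share no code path with the package implementations they check.

# synchronous map by double loop over (v1, v2) and explicit summation
oracleSync <- function(dynValues) {
  n <- nrow(dynValues); p <- ncol(dynValues)
  out <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    s <- 0
    for (i in seq_len(n)) s <- s + dynValues[i, a] * dynValues[i, b]
    out[a, b] <- s / (n - 1)
  }
  out
}

# asynchronous map by triple loop with the Hilbert-Noda kernel inline
oracleAsync <- function(dynValues) {
  n <- nrow(dynValues); p <- ncol(dynValues)
  out <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    s <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != k)
        s <- s + dynValues[j, a] * dynValues[k, b] / (pi * (k - j))
    }
    out[a, b] <- s / (n - 1)
  }
  out
}

# Kennard-Stone by literal max-min search, recomputing every distance from
# scratch at every step
oracleKennardStone <- function(X, k) {
  n <- nrow(X)
  d2 <- function(a, b) sum((X[a, ] - X[b, ])^2)
  best <- NULL; bestD <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d2(i, j) > bestD) { bestD <- d2(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand <- setdiff(seq_len(n), sel)
    scores <- sapply(cand, function(c) min(sapply(sel, function(s) d2(c, s))))
    sel <- c(sel, cand[which.max(scores)])
  }
  sel
}

# tiny dynamic-spectra builder for map tests
randomDynamic <- function(nSteps, p, seed) {
  rng <- get(".localRNG", asNamespace("ir2dcos"))(seed)
  makeDynamic(matrix(rng$rnorm(nSteps * p), nSteps, p))
}

# two-column sinusoidal perturbation series: y1 = A1 sin(t + dphi),
# y2 = A2 sin(t), n steps over exactly one cycle
sinusoidPair <- function(n, dphi, A1 = 1.3, A2 = 0.7) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  makeDynamic(cbind(A1 * sin(t + dphi), A2 * sin(t)))
}

# small labeled image-set builder: two visually distinct classes of
# constant-pattern images (left half vs right half bright)
toyImages <- function(nPerClass, size = 16L, seed = 1L) {
  rng <- get(".localRNG", asNamespace("ir2dcos"))(seed)
  n <- 2L * nPerClass
  x <- array(0, dim = c(size, size, 3L, n))
  labels <- character(n)
  for (i in seq_len(n)) {
    cls <- if (i <= nPerClass) 1L else 2L
    img <- array(rng$runif(size * size * 3, 0, 0.1), dim = c(size, size, 3L))
    half <- seq_len(size %/% 2L)
    if (cls == 1L) img[, half, ] <- img[, half, ] + 0.8
    else img[, size %/% 2L + half, ] <- img[, size %/% 2L + half, ] + 0.8
    x[, , , i] <- img
    labels[i] <- paste0("class", cls)
  }
  list(x = x, labels = labels)
}

# compact model configuration used by classifier unit tests
tinyConfig <- function(nClasses = 2L, inputSize = 16L, epochs = 5L,
                       seed = 1L, ...) {
  modelConfig(nClasses, inputSize = inputSize,
              channels = c(4L, 8L, 8L, 16L), stemChannels = 2L,
              stemFilter = 3L, stemStride = 1L, stemPad = 1L,
              epochs = epochs, batchSize = 8L, seed = seed,
              augmentation = character(0), ...)
}
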
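#' Stratified random external-validation holdout
#'
#' Draws `round(fraction * classSize)` samples per class (at least 1 when
#' the class has >= 2 samples) as the external-validation set; the rest form
#' the model set.  A singleton class stays entirely in the model set, with a
#' warning.
#'
#' @param set a labeled [SpectraSet]
#' @param fraction holdout proportion in (0, 1); default 0.1
#' @param seed integer seed for the random draw
#' @return list with character vectors `model` and `external` of sample ids
#' @export
holdoutExternal <- function(set, fraction = 0.1, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  lab <- spectraLabels(set)
  if (is.null(lab)) stop("a labeled set is required")
  ids <- colnames(set)
  rng <- .localRNG(as.integer(seed))
  external <- character(0)
  for (l in unique(lab)) {
    cls <- ids[lab == l]
    if (length(cls) < 2L) {
      warning("class '", l, "' has a single sample; kept in the model set")
      next
    }
    k <- max(1L, as.integer(round(fraction * length(cls))))
    external <- c(external, rng$sample(cls, k))
  }
  list(model = setdiff(ids, external), external = external)
}

#' Kennard-Stone sample selection
#'
#' Deterministic coverage-maximizing selection: the first two picks are the
#' pair at maximal Euclidean distance; every further pick maximizes its
#' minimal distance to the already-selected set.  Ties are broken by the
#' lowest row index (for the initial pair: smallest first index, then
#' smallest second).  Duplicate rows are allowed.
#'
#' @param X samples x features numeric matrix
#' @param k number of samples to select, `2 <= k <= nrow(X)`
#' @return integer vector of selected row indices, in selection order
#' @examples
#' X <- matrix(c(0, 1, 2, 10), ncol = 1)
#' kennardStone(X, 2)  # 1 4: the extreme pair
#' kennardStone(X, 3)  # adds index 3 (max-min distance)
#' @export
kennardStone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (is.na(k) || k < 2L || k > n)
    stop("k must satisfy 2 <= k <= nrow(X)")
  D <- unname(as.matrix(stats::dist(X)))
  # initial pair: maximal distance, ties -> smallest (i, j), i < j
  best <- c(1L, 2L); bestD <- -Inf
  for (i in seq_len(n - 1L)) {
    j <- which.max(D[i, (i + 1L):n]) + i   # first max in row = smallest j
    if (D[i, j] > bestD) { bestD <- D[i, j]; best <- c(i, j) }
  }
  sel <- best
  if (k > 2L) {
    minD <- pmin(D[, sel[1]], D[, sel[2]])
    minD[sel] <- -Inf
    for (step in 3L:k) {
      nxt <- as.integer(which.max(minD))  # which.max takes the lowest index on ties
      sel <- c(sel, nxt)
      minD <- pmin(minD, D[, nxt])
      minD[nxt] <- -Inf
    }
  }
  as.integer(sel)
}

#' Split a dataset into train / test / external-validation sets
#'
#' Two-stage procedure: a stratified random holdout of the external fraction
#' (`ratios[3]`), then a single global Kennard-Stone pass over the remaining
#' model set selecting the training portion
#' (`floor(ratios[1] / (ratios[1] + ratios[2]) * modelSize)` samples, i.e.
#' 7/9 of the model set under the default 0.7/0.2/0.1); the unselected
#' remainder is the test set.  Kennard-Stone distances are computed on the
#' minmax-normalized 1-D spectra.  Only the holdout is random; Kennard-Stone
#' itself is deterministic.
#'
#' @param set a labeled [SpectraSet]
#' @param ratios target (train, test, external) proportions summing to 1
#' @param seed integer seed for the holdout
#' @param perClass run Kennard-Stone separately within each class instead of
#'   one global pass (default `FALSE`)
#' @return a [SplitAssignment]
#' @examples
#' ss <- generateDataset(3, 10, seed = 1)
#' splitDataset(ss, seed = 7)
#' @export
splitDataset <- function(set, ratios = c(0.7, 0.2, 0.1), seed = 1L,
                         perClass = FALSE) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8 || any(ratios <= 0))
    stop("ratios must be 3 positive proportions summing to 1")
  hold <- holdoutExternal(set, fraction = ratios[3], seed = seed)
  ids <- colnames(set)
  lab <- spectraLabels(set)
  norm <- normalizeSpectra(set, "minmax")
  Xall <- t(absorbance(norm))            # samples x features
  rownames(Xall) <- ids
  trainFrac <- ratios[1] / (ratios[1] + ratios[2])
  pickTrain <- function(modelIds) {
    nTrain <- as.integer(floor(trainFrac * length(modelIds)))
    if (nTrain < 2L) stop("model set too small for a Kennard-Stone split")
    modelIds[kennardStone(Xall[modelIds, , drop = FALSE], nTrain)]
  }
  if (perClass) {
    train <- unlist(lapply(unique(lab), function(l)
      pickTrain(intersect(hold$model, ids[lab == l]))))
  } else {
    train <- pickTrain(hold$model)
  }
  mem <- factor(ifelse(ids %in% hold$external, "external",
                       ifelse(ids %in% train, "train", "test")),
                levels = c("train", "test", "external"))
  methods::new("SplitAssignment", sampleIds = ids, membership = mem,
               ratios = as.numeric(ratios), seed = as.integer(seed))
}

#' Serialize / read a split assignment as JSON
#'
#' @param x a [SplitAssignment]
#' @param path JSON file path
#' @return `path` invisibly; `readSplit` returns the [SplitAssignment]
#' @export
writeSplit <- function(x, path) {
  stopifnot(methods::is(x, "SplitAssignment"))
  jsonlite::write_json(
    list(sampleIds = x@sampleIds, membership = as.character(x@membership),
         ratios = x@ratios, seed = x@seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSplit
#' @export
readSplit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("SplitAssignment", sampleIds = as.character(j$sampleIds),
               membership = factor(j$membership,
                                   levels = c("train", "test", "external")),
               ratios = as.numeric(j$ratios), seed = as.integer(j$seed))
}
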
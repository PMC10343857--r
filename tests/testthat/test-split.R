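test_that("the external holdout is stratified with per-class rounding", {
  ss <- generateDataset(7, 20, seed = 3)
  hold <- holdoutExternal(ss, fraction = 0.1, seed = 5)
  expect_length(hold$external, 14)            # round(0.1 * 20) = 2 per class
  lab <- spectraLabels(ss); names(lab) <- colnames(ss)
  expect_true(all(table(lab[hold$external]) == 2))
  expect_setequal(c(hold$model, hold$external), colnames(ss))
  # same seed, same holdout
  expect_identical(hold, holdoutExternal(ss, fraction = 0.1, seed = 5))
  expect_error(holdoutExternal(ss, fraction = 1.2), "\\(0, 1\\)")
})

test_that("a singleton class stays in the model set with a warning", {
  wn <- seq(2000, 1000, by = -10)
  m <- matrix(runif(length(wn) * 5), ncol = 5)
  ss <- SpectraSet(wn, m, labels = c("a", "a", "a", "a", "b"))
  expect_warning(hold <- holdoutExternal(ss, 0.2, seed = 1), "single sample")
  expect_true("s0005" %in% hold$model)
})

test_that("Kennard-Stone picks the extreme pair first and max-min afterwards", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  expect_equal(sort(kennardStone(X, 2)), c(1, 4))
  # the point at 2 has min-distance 2 to {0, 10}, beating 1's value of 1
  expect_equal(kennardStone(X, 3), c(1, 4, 3))
  expect_equal(sort(kennardStone(X, 4)), 1:4)
  expect_error(kennardStone(X, 1), "2 <= k")
  expect_error(kennardStone(X, 5), "2 <= k")
})

test_that("Kennard-Stone matches the exhaustive max-min oracle", {
  for (seed in 1:25) {
    rng <- get(".localRNG", asNamespace("ir2dcos"))(seed)
    n <- 5 + seed %% 8
    X <- matrix(rng$rnorm(n * 3), n, 3)
    for (k in 2:n)
      expect_equal(kennardStone(X, k), oracleKennardStone(X, k))
  }
})

test_that("the selected training set always spans the model set's diameter", {
  rng <- get(".localRNG", asNamespace("ir2dcos"))(77)
  X <- matrix(rng$rnorm(40), 20, 2)
  D <- as.matrix(dist(X))
  extremes <- which(D == max(D), arr.ind = TRUE)[1, ]
  for (k in c(2, 5, 12)) {
    sel <- kennardStone(X, k)
    expect_true(all(sort(extremes) %in% sel))
    expect_equal(max(dist(X[sel, ])), max(D))
  }
})

test_that("splitDataset realizes the 70/20/10 counts with the stated rounding", {
  ss <- generateDataset(9, 20, seed = 2)        # 180 samples
  split <- splitDataset(ss, seed = 4)
  mem <- membership(split)
  expect_equal(sum(mem == "external"), 18)
  expect_equal(sum(mem == "train"), 126)        # floor(7/9 * 162)
  expect_equal(sum(mem == "test"), 36)
  expect_equal(length(mem), 180)
  expect_false(anyNA(mem))                      # disjoint and exhaustive
  # deterministic under the same seed
  split2 <- splitDataset(ss, seed = 4)
  expect_identical(membership(split), membership(split2))
  expect_false(identical(membership(split),
                         membership(splitDataset(ss, seed = 5))))
})

test_that("per-class Kennard-Stone keeps every class in the training set", {
  ss <- generateDataset(3, 12, seed = 15)
  split <- splitDataset(ss, seed = 2, perClass = TRUE)
  mem <- membership(split)
  lab <- spectraLabels(ss); names(lab) <- colnames(ss)
  trainLab <- lab[names(mem)[mem == "train"]]
  expect_setequal(unique(trainLab), unique(lab))
  expect_false(anyNA(mem))
})

test_that("split assignments round-trip through JSON", {
  ss <- generateDataset(3, 10, seed = 6)
  split <- splitDataset(ss, seed = 9)
  f <- tempfile(fileext = ".json")
  writeSplit(split, f)
  back <- readSplit(f)
  expect_identical(membership(back), membership(split))
  expect_identical(back@ratios, split@ratios)
  unlink(f)
})
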
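test_that("default recipes share the ten fingerprint positions and differ in amplitude", {
  centers <- c(3292, 2922, 2849, 1732, 1610, 1510, 1422, 1371, 1030, 920)
  recipes <- defaultRecipes(7, seed = 3)
  expect_length(recipes, 7)
  for (r in recipes) expect_equal(r$peaks$center, centers)
  amps <- sapply(recipes, function(r) r$peaks$amplitude)
  expect_gt(max(apply(amps, 1, sd)), 0)   # class-specific amplitudes
})

test_that("recipes are a pure function of their arguments", {
  expect_identical(defaultRecipes(5, seed = 9), defaultRecipes(5, seed = 9))
  expect_false(identical(defaultRecipes(5, seed = 9),
                         defaultRecipes(5, seed = 10)))
  expect_error(defaultRecipes(0, seed = 1), "between 1 and 26")
  expect_error(defaultRecipes(27, seed = 1), "between 1 and 26")
})

test_that("a single class yields spectra that differ only by noise", {
  recipes <- defaultRecipes(1, seed = 4, noiseSd = 0)
  g <- wavenumberGrid()
  s1 <- generateSpectrum(recipes[[1]], g, seed = 1)
  s2 <- generateSpectrum(recipes[[1]], g, seed = 2)
  expect_identical(s1, s2)   # no noise: identical
  recipes <- defaultRecipes(1, seed = 4, noiseSd = 0.01)
  s1 <- generateSpectrum(recipes[[1]], g, seed = 1)
  s2 <- generateSpectrum(recipes[[1]], g, seed = 2)
  expect_false(identical(s1, s2))
})

test_that("a noiseless single-peak spectrum evaluates the peak profile", {
  g <- seq(2000, 1000, by = -4)
  r <- classRecipe("x", peakSpec(1500, 20, amplitude = 0.8))
  s <- generateSpectrum(r, g, seed = 1)
  expect_equal(s[which.min(abs(g - 1500))], 0.8, tolerance = 1e-6)
  expect_identical(s, generateSpectrum(r, g, seed = 99))  # deterministic
  expect_error(generateSpectrum(r, numeric(0), seed = 1), "non-empty")
})

test_that("empirical noise sd matches the recipe noise sd", {
  g <- wavenumberGrid()              # 912 points
  r0 <- classRecipe("x", peakSpec(1500, 20, 0.8), noiseSd = 0)
  r <- classRecipe("x", peakSpec(1500, 20, 0.8), noiseSd = 0.02)
  clean <- generateSpectrum(r0, g, seed = 1)
  noisy <- generateSpectrum(r, g, seed = 1)
  expect_gt(length(g), 500)
  expect_equal(sd(noisy - clean), 0.02, tolerance = 0.2 * 0.02 / 0.02)
  expect_lt(abs(sd(noisy - clean) - 0.02) / 0.02, 0.2)
})

test_that("generated datasets have the declared shape and grid", {
  ss <- generateDataset(7, 25, seed = 2)
  expect_equal(ncol(ss), 175)
  expect_equal(length(unique(spectraLabels(ss))), 7)
  expect_equal(nrow(ss), 912)        # (4010 - 365) / 4 + 1, partial step dropped
  wn <- wavenumbers(ss)
  expect_equal(wn[1], 4010)
  expect_equal(wn[length(wn)], 366)  # descending, 365 not hit exactly
  expect_true(all(diff(wn) == -4))
  expect_error(generateDataset(0, 5), "positive")
  expect_error(generateDataset(3, 0), "positive")
})

test_that("datasets are bit-identical under the same seed, including serialization", {
  a <- generateDataset(3, 4, seed = 42)
  b <- generateDataset(3, 4, seed = 42)
  expect_identical(absorbance(a), absorbance(b))
  fa <- tempfile(fileext = ".tsv"); fb <- tempfile(fileext = ".tsv")
  writeSpectra(a, fa, sidecar = FALSE); writeSpectra(b, fb, sidecar = FALSE)
  expect_identical(readLines(fa), readLines(fb))
  unlink(c(fa, fb))
})

test_that("wider class amplitude spread makes classes more separable", {
  # training accuracy of a linear (nearest class centroid) classifier on the
  # raw spectra, non-decreasing across three spread levels
  acc <- sapply(c(0.02, 0.1, 0.4), function(spread) {
    ss <- generateDataset(5, 12, seed = 2, amplitudeSpread = spread)
    X <- t(absorbance(ss)); lab <- spectraLabels(ss)
    cent <- sapply(unique(lab), function(l) colMeans(X[lab == l, , drop = FALSE]))
    pred <- unique(lab)[apply(X, 1, function(r) which.min(colSums((cent - r)^2)))]
    mean(pred == lab)
  })
  expect_false(is.unsorted(acc))
  expect_gt(acc[3], acc[1])
})
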
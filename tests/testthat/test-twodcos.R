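test_that("the perturbation series evaluates the stated sinusoid", {
  # flat unit spectrum, 4 points, amplitude 0.1, one cycle, in phase:
  # rows are 1 + 0.1 * sin(0, pi/2, pi, 3pi/2) = 1, 1.1, 1, 0.9
  p <- perturbationParams(nSteps = 4, amplitude = 0.1, cycles = 1,
                          phaseGradient = 0)
  s <- buildPerturbationSeries(rep(1, 4), c(4, 3, 2, 1), p)
  expect_equal(s[, 1], c(1, 1.1, 1, 0.9), tolerance = 1e-12)
  expect_equal(s, matrix(rep(s[, 1], 4), ncol = 4), tolerance = 1e-12)
  # vanishing amplitude: every row tends to the parent spectrum
  tiny <- perturbationParams(nSteps = 4, amplitude = 1e-12)
  st <- buildPerturbationSeries(c(1, 2, 3), c(3, 2, 1), tiny)
  for (i in 1:4) expect_equal(st[i, ], c(1, 2, 3), tolerance = 1e-10)
  # in-phase modulation makes all columns proportional
  sp <- buildPerturbationSeries(c(2, 5), c(2, 1),
                                perturbationParams(nSteps = 8))
  expect_equal(sp[, 2] / sp[, 1], rep(2.5, 8), tolerance = 1e-12)
  expect_error(perturbationParams(nSteps = 1), "nSteps")
})

test_that("dynamic spectra are the mean-centered series", {
  d <- makeDynamic(matrix(c(1, 3), ncol = 1))
  expect_equal(as.numeric(d@values), c(-1, 1))
  expect_equal(d@reference, 2)
  const <- makeDynamic(matrix(5, nrow = 6, ncol = 3))
  expect_true(all(const@values == 0))
  rng <- get(".localRNG", asNamespace("ir2dcos"))(11)
  m <- matrix(rng$rnorm(80), 8, 10)
  dm <- makeDynamic(m)
  expect_lt(max(abs(colMeans(dm@values))), 1e-12)
})

test_that("the Hilbert-Noda matrix matches its closed form", {
  n3 <- hilbertNoda(3)
  expect_equal(n3, matrix(c(0, -1/pi, -1/(2*pi),
                            1/pi, 0, -1/pi,
                            1/(2*pi), 1/pi, 0), 3, 3), tolerance = 1e-15)
  expect_equal(hilbertNoda(2), matrix(c(0, -1/pi, 1/pi, 0), 2, 2))
  for (n in c(2, 5, 16)) {
    m <- hilbertNoda(n)
    expect_equal(m + t(m), matrix(0, n, n))
    expect_equal(diag(m), rep(0, n))
  }
  expect_error(hilbertNoda(1), ">= 2")
})

test_that("synchronous map matches hand evaluation and the loop oracle", {
  d <- makeDynamic(matrix(c(0, 2), ncol = 1))   # dynamic values -1, +1
  expect_equal(synchronousMap(d)[1, 1], 2)
  d2 <- randomDynamic(5, 6, seed = 21)
  expect_equal(synchronousMap(d2), oracleSync(d2@values), tolerance = 1e-10)
  expect_true(all(diag(synchronousMap(d2)) >= 0))
})

test_that("asynchronous map is antisymmetric with zero diagonal and matches the oracle", {
  d <- randomDynamic(7, 5, seed = 33)
  a <- asynchronousMap(d)
  expect_equal(a, oracleAsync(d@values), tolerance = 1e-10)
  expect_equal(a, -t(a), tolerance = 1e-10)
  expect_lt(max(abs(diag(a))), 1e-10)
})

test_that("sinusoid pairs obey the trigonometric phase law", {
  n <- 64
  syncPeak <- function(dphi) synchronousMap(sinusoidPair(n, dphi))[1, 2]
  asyncPeak <- function(dphi) asynchronousMap(sinusoidPair(n, dphi))[1, 2]
  s0 <- syncPeak(0); aQ <- asyncPeak(pi / 2)
  for (dphi in c(0, pi / 4, pi / 2)) {
    expect_equal(syncPeak(dphi), s0 * cos(dphi), tolerance = 0.02)
    expect_equal(asyncPeak(dphi), aQ * sin(dphi), tolerance = 0.02)
  }
  # in-phase signals have no asynchronous cross-peak; quadrature signals
  # have no synchronous cross-peak
  expect_lt(abs(asyncPeak(0)) / abs(s0), 1e-10)
  expect_lt(abs(syncPeak(pi / 2)) / abs(aQ), 1e-10)
  # cross-peaks scale with the product of the amplitudes
  d2 <- sinusoidPair(n, pi / 4, A1 = 2.6, A2 = 0.7)
  expect_equal(synchronousMap(d2)[1, 2], 2 * syncPeak(pi / 4),
               tolerance = 1e-10)
})

test_that("integrative map is the elementwise product", {
  sync <- matrix(c(1, 2, 2, 4), 2, 2)
  async <- matrix(c(0, -3, 3, 0), 2, 2)
  expect_equal(integrativeMap(sync, async),
               matrix(c(0, -6, 6, 0), 2, 2))
  expect_true(all(integrativeMap(sync, matrix(0, 2, 2)) == 0))
  expect_error(integrativeMap(sync, matrix(0, 3, 3)), "dimensions")
})

test_that("computeCorrelationMaps carries the band grid and scales homogeneously", {
  ss <- generateDataset(1, 1, seed = 9)
  s <- absorbance(ss)[, 1]; wn <- wavenumbers(ss)
  p1 <- perturbationParams(amplitude = 0.05, phaseGradient = 0.002)
  p2 <- perturbationParams(amplitude = 0.10, phaseGradient = 0.002)
  m1 <- computeCorrelationMaps(s, wn, bandPreset("bandC"), p1)
  expect_equal(length(wavenumbers(m1)), sum(wn >= 1100 & wn <= 1750))
  expect_equal(dim(syncMap(m1)), rep(length(wavenumbers(m1)), 2))
  # doubling the modulation depth scales the bilinear maps by ~4 and the
  # integrative map by ~16 (exact in the additive limit; the multiplicative
  # series also rescales the reference, hence the loose tolerance on top)
  m2 <- computeCorrelationMaps(s, wn, bandPreset("bandC"), p2)
  expect_equal(max(abs(syncMap(m2))) / max(abs(syncMap(m1))), 4,
               tolerance = 1e-6)
  expect_equal(max(abs(asyncMap(m2))) / max(abs(asyncMap(m1))), 4,
               tolerance = 1e-6)
  expect_equal(max(abs(integrativeMapOf(m2))) / max(abs(integrativeMapOf(m1))),
               16, tolerance = 1e-6)
  # fully deterministic
  expect_identical(syncMap(m1),
                   syncMap(computeCorrelationMaps(s, wn, bandPreset("bandC"), p1)))
})

test_that("map symmetries hold on random dynamic spectra", {
  for (seed in 1:10) {
    d <- randomDynamic(4 + seed %% 5, 6, seed = seed)
    sync <- synchronousMap(d); async <- asynchronousMap(d)
    expect_equal(sync, t(sync), tolerance = 1e-12)
    expect_equal(async, -t(async), tolerance = 1e-12)
    expect_true(all(diag(sync) >= 0))
    inte <- integrativeMap(sync, async)
    expect_equal(inte, -t(inte), tolerance = 1e-12)
    # sync equals the scaled cross-product of the centered series and is PSD
    expect_equal(sync, crossprod(d@values) / (nrow(d@values) - 1),
                 tolerance = 1e-12)
    expect_gt(min(eigen(sync, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("whole-set mapping yields one maps object per sample", {
  ss <- generateDataset(2, 3, seed = 4)
  maps <- mapDataset(ss, band = bandPreset("bandB"))
  expect_length(maps, 6)
  expect_named(maps, colnames(ss))
})
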
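test_that("wide-table write/read round-trips intensities bit-identically", {
  ss <- generateDataset(2, 3, seed = 5)
  f <- tempfile(fileext = ".tsv")
  writeSpectra(ss, f)
  back <- readSpectra(f)
  expect_identical(unname(absorbance(back)), unname(absorbance(ss)))
  expect_identical(wavenumbers(back), wavenumbers(ss))
  expect_identical(spectraLabels(back), spectraLabels(ss))
  expect_true(file.exists(paste0(f, ".json")))   # metadata sidecar
  unlink(c(f, paste0(f, ".json")))
})

test_that("reader handles single-row files and rejects malformed input", {
  f <- tempfile()
  writeLines(c("label\t2000\t1996\t1992", "a\t0.1\t0.2\t0.3"), f)
  one <- readSpectra(f)
  expect_equal(ncol(one), 1)
  expect_equal(absorbance(one)[, 1], c(0.1, 0.2, 0.3))

  writeLines(c("label\t2000\t1996\t1992", "a\t0.1\toops\t0.3"), f)
  expect_error(readSpectra(f), "row 1")
  writeLines(c("label\t2000\t1996\t1992", "a\t0.1\t0.2\t0.3",
               "b\t0.1\t0.2"), f)
  expect_error(readSpectra(f), "row 2")
  writeLines(c("label\t2000"), f)
  expect_error(readSpectra(f), "header|row")
  unlink(f)
})

test_that("an ascending grid is re-sorted to the descending convention", {
  f <- tempfile()
  writeLines(c("label\t1000\t1500\t2000", "a\t1\t2\t3"), f)
  ss <- readSpectra(f)
  expect_equal(wavenumbers(ss), c(2000, 1500, 1000))
  expect_equal(absorbance(ss)[, 1], c(3, 2, 1))
  unlink(f)
})

test_that("normalization follows the declared conventions", {
  expect_equal(normalizeIntensities(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalizeIntensities(c(3, 4), "vector"), c(0.6, 0.8))
  expect_error(normalizeIntensities(rep(1, 5)), "zero range")
  # idempotence of minmax
  x <- runif(50)
  expect_equal(normalizeIntensities(normalizeIntensities(x)),
               normalizeIntensities(x))
  ss <- generateDataset(2, 2, seed = 1)
  nn <- normalizeSpectra(ss)
  expect_equal(unname(apply(absorbance(nn), 2, min)), c(0, 0, 0, 0))
  expect_equal(unname(apply(absorbance(nn), 2, max)), c(1, 1, 1, 1))
  expect_equal(S4Vectors::metadata(nn)$normalization, "minmax")
})

test_that("vector normalization preserves pairwise cosine similarity", {
  ss <- generateDataset(3, 3, seed = 8)
  cosim <- function(m) {
    u <- sweep(m, 2, sqrt(colSums(m^2)), `/`)
    crossprod(u)
  }
  before <- cosim(absorbance(ss))
  after <- cosim(absorbance(normalizeSpectra(ss, "vector")))
  expect_equal(before, after, tolerance = 1e-12)
})

test_that("averaging is the pointwise mean, globally or per label", {
  wn <- c(10, 8, 6)
  ss <- SpectraSet(wn, cbind(c(0, 0, 0), c(2, 2, 2)), labels = c("a", "a"))
  avg <- averageSpectra(ss)
  expect_equal(unname(absorbance(avg)[, 1]), c(1, 1, 1))
  ss2 <- SpectraSet(wn, cbind(c(1, 2, 3), c(1, 2, 3)), labels = c("a", "a"))
  expect_equal(unname(absorbance(averageSpectra(ss2))[, 1]), c(1, 2, 3))
  multi <- generateDataset(7, 3, seed = 1)
  expect_equal(ncol(averageSpectra(multi)), 7)
  expect_equal(ncol(averageSpectra(multi, byLabel = FALSE)), 1)
})

test_that("band extraction keeps inclusive bounds and preserves order", {
  ss <- generateDataset(1, 1, seed = 1)
  bc <- extractBand(ss, bandPreset("bandC"))
  wn <- wavenumbers(bc)
  expect_true(all(wn >= 1100 & wn <= 1750))
  expect_true(all(diff(wn) < 0))
  # hand-checked inclusive-bounds case on a grid straddling both ends
  grid <- seq(3010, 2742, by = -4)      # ..., 3002, 2998, ..., 2750, 2746, ...
  s2 <- SpectraSet(grid, matrix(seq_along(grid), ncol = 1))
  got <- wavenumbers(extractBand(s2, band(3000, 2750)))
  expect_true(2750 %in% got)
  expect_false(3002 %in% got)
  expect_false(2746 %in% got)
  expect_equal(range(got), c(2750, 2998))
  # full-grid band is the identity
  expect_identical(absorbance(extractBand(ss, bandPreset("full"))),
                   absorbance(ss))
  expect_error(extractBand(ss, band(20000, 19000)), "no grid point")
})

test_that("band extraction is idempotent and commutes with averaging", {
  ss <- generateDataset(3, 4, seed = 6)
  b <- bandPreset("bandB")
  once <- extractBand(ss, b)
  expect_identical(absorbance(extractBand(once, b)), absorbance(once))
  lhs <- extractBand(averageSpectra(ss), b)
  rhs <- averageSpectra(extractBand(ss, b))
  expect_equal(absorbance(lhs), absorbance(rhs), tolerance = 1e-14)
})

test_that("band fusion concatenates the four regions on a strict grid", {
  ss <- generateDataset(2, 2, seed = 3)
  fused <- fuseBands(ss, bandPresets()[c("bandA", "bandB", "bandC", "bandD")])
  wn <- wavenumbers(fused)
  expect_true(all(diff(wn) < 0))                 # strictly decreasing
  expect_true(all(wn <= 3500 & wn >= 400))
  expect_equal(nrow(fused), length(unique(wn)))
  # a wavenumber shared by two adjacent bands is kept exactly once
  grid <- seq(3500, 2700, by = -100)             # contains 3000 itself
  s2 <- SpectraSet(grid, matrix(seq_along(grid), ncol = 1))
  f2 <- fuseBands(s2, list(band(3500, 3000), band(3000, 2700)))
  expect_equal(sum(wavenumbers(f2) == 3000), 1)
  expect_equal(wavenumbers(f2), grid)
})
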
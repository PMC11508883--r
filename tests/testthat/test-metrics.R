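test_that("normalized error absorbs the global sign and is scale-referenced", {
  x <- rnorm(32)
  expect_equal(normalizedError(x, x), 0)
  expect_equal(normalizedError(-x, x), 0)
  expect_equal(normalizedError(numeric(32), x), 1)
  expect_error(normalizedError(x, numeric(32)), "nonzero")
  expect_error(normalizedError(x, rnorm(16)), "mismatch")

  # triangle-type bound and sign invariance on random pairs
  for (s in 1:5) {
    set.seed(s)
    a <- rnorm(16); b <- rnorm(16)
    expect_equal(normalizedError(a, b), normalizedError(-a, b))
    expect_lte(normalizedError(a, b),
               (sqrt(sum(a^2)) + sqrt(sum(b^2))) / sqrt(sum(b^2)) + 1e-12)
  }
})

test_that("image quality metrics align the sign and hit known values", {
  x <- phantomImage(32)
  iq <- imageQuality(x, x)
  expect_equal(iq$psnr, 150)  # capped sentinel for a perfect match
  expect_equal(iq$ssim, 1)
  expect_equal(imageQuality(-x, x), iq)  # sign aligned before scoring

  # uniform offset of 0.1 on the [0,1] range: MSE = 0.01, PSNR = 20 dB
  iq2 <- imageQuality(x + 0.1, x)
  expect_equal(iq2$psnr, 20, tolerance = 1e-10)
  expect_lt(iq2$ssim, 1)
  expect_gte(iq2$ssim, -1)

  expect_error(imageQuality(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("success rate counts sub-threshold errors as percentages", {
  expect_equal(successRate(c(0, 0, 0), 1e-5), 100)
  expect_equal(successRate(c(0.5, 1e-9), 1e-5), 50)
  expect_error(successRate(numeric(0), 1e-5), "empty")
  expect_error(successRate(c(0.1), 0), "positive")
})

test_that("the contraction bound function peaks at ~1.0774, below 1.08", {
  expect_equal(boundFunction(0), 1)
  expect_equal(boundFunction(1), 0.5)
  expect_error(boundFunction(1.5), "\\[-1, 1\\]")

  g1 <- boundFunctionMax(1e6)
  expect_lte(g1$value, 1.08)
  expect_equal(g1$value, 1.0774, tolerance = 1e-4)
  expect_equal(g1$argmax, 2 / sqrt(3) - 1, tolerance = 1e-4)
  # stable under grid refinement
  g2 <- boundFunctionMax(2e6 + 1)
  expect_equal(g1$value, g2$value, tolerance = 1e-8)
})

test_that("diagnostics report the error geometry and basin flags", {
  x <- rnorm(64)
  d0 <- convergenceDiagnostics(x, x, x)
  expect_equal(sqrt(sum(d0@d^2)), 0)
  expect_equal(sqrt(sum(d0@e^2)), 0)
  expect_equal(d0@mu, 0)
  expect_true(d0@muOk)
  expect_true(d0@inBasin)

  # on the basin boundary: ||e|| = 0.48 ||x||, e orthogonal-ish direction
  e <- rand_dir(64, 7) * 0.48 * sqrt(sum(x^2))
  db <- convergenceDiagnostics(x, x + e, x)
  expect_true(db@inBasin)
  expect_equal(sqrt(sum(db@e^2)), 0.48 * sqrt(sum(x^2)))
  e2 <- rand_dir(64, 8) * 0.49 * sqrt(sum(x^2))
  expect_false(convergenceDiagnostics(x, x + e2, x)@inBasin)

  expect_true(all(abs(c(db@cosGB, db@cosGE, db@cosEB)) <= 1))
  expect_error(convergenceDiagnostics(x, numeric(64), x), "zero-norm")
})

test_that("mu stays below 1 along a successful noise-free run", {
  x <- generateSignal("uniform01", 64, seed = 101)
  m <- sampleMasks(64, K = 8, seed = 102)
  y <- forwardIntensity(x, m)
  a <- randomPositiveInit(y, m, seed = 103)
  b <- a
  mus <- numeric(0)
  for (n in 1:12) {
    b <- solveHalfStep(a, y, m, warm = b)
    # align the sign convention before measuring geometry
    xs <- if (sum((a - x)^2) <= sum((a + x)^2)) x else -x
    mus <- c(mus, convergenceDiagnostics(a, b, xs)@mu)
    a <- recombine(a, b)
    b <- a
  }
  expect_true(all(mus[-1] < 1))
  expect_lt(normalizedError(a, x), 1e-6)
})
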
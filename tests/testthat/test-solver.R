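test_that("half-step solves the normal equations (dense pseudoinverse oracle)", {
  m <- sampleMasks(8, K = 3, seed = 31)
  x <- runif(8)
  y <- forwardIntensity(x, m)

  # anchored at the truth the least-squares solution is x itself
  b <- solveHalfStep(x, y, m)
  expect_lt(rel_err(b, x), 1e-6)

  # dense oracle: any anchor, compare with qr-based least squares
  a <- rnorm(8)
  Ha <- dense_Ha(a, m)
  expect_gte(qr(Ha)$rank, 8)  # full column rank: minimizer unique
  bd <- qr.solve(qr(Ha, LAPACK = TRUE), as.vector(intensityMatrix(y)))
  b2 <- solveHalfStep(a, y, m, config = solverConfig(cgMax = 200))
  expect_lt(rel_err(b2, bd), 1e-8)
})

test_that("half-step handles zero observations and degenerate anchors", {
  m <- sampleMasks(8, K = 2, seed = 37)
  y0 <- forwardIntensity(numeric(8), m)
  b <- solveHalfStep(runif(8), y0, m)
  expect_true(all(b == 0))
  expect_error(solveHalfStep(numeric(8), y0, m), "degenerate")
})

test_that("recombination averages, cancels symmetric errors and fixes consistent points", {
  v <- rnorm(16)
  expect_identical(recombine(v, v), v)
  d <- rnorm(16)
  expect_equal(recombine(v + d, v - d), v)
  expect_equal(recombine(c(1, 0), c(0, 1)), c(0.5, 0.5))
  expect_error(recombine(1:3, 1:4), "mismatch")
})

test_that("the truth is a fixed point: starting there stops immediately at error 0", {
  x <- runif(64)
  m <- sampleMasks(64, K = 4, seed = 41)
  y <- forwardIntensity(x, m)
  fit <- phaseRetrieve(y, m, init = x, groundTruth = x)
  expect_true(hasConverged(fit))
  expect_lte(iterations(fit), 2L)
  expect_lt(tail(errTrace(fit), 1), 1e-12)
})

test_that("noise-free recovery succeeds from the positive random init (vector, K=4)", {
  x <- generateSignal("uniform01", 64, seed = 43)
  m <- sampleMasks(64, K = 4, seed = 44)
  y <- forwardIntensity(x, m)
  x0 <- randomPositiveInit(y, m, seed = 45)
  fit <- phaseRetrieve(y, m, x0, groundTruth = x)
  expect_true(hasConverged(fit))
  expect_lt(normalizedError(estimate(fit), x), 1e-6)
  # error trace is recorded per outer iteration
  expect_length(errTrace(fit), iterations(fit))
})

test_that("an uninformative setup is reported as failure, not error", {
  # general real signal with K=2 carries too little information
  x <- generateSignal("gaussian", c(8, 8), seed = 47)
  m <- sampleMasks(c(8, 8), K = 2, seed = 48)
  y <- forwardIntensity(x, m)
  x0 <- randomPositiveInit(y, m, seed = 49)
  fit <- phaseRetrieve(y, m, x0, config = solverConfig(maxOuter = 150),
                       groundTruth = x)
  expect_s4_class(fit, "RecoveryResult")
  expect_gt(normalizedError(estimate(fit), x), 1e-5)
})

test_that("final error is non-increasing in SNR at fixed masks and seed", {
  x <- generateSignal("uniform01", 64, seed = 51)
  m <- sampleMasks(64, K = 8, seed = 52)
  y <- forwardIntensity(x, m)
  errs <- vapply(c(10, 20, 30, Inf), function(snr) {
    yn <- addAwgn(y, snr, seed = 53)
    x0 <- randomPositiveInit(yn, m, seed = 54)
    fit <- phaseRetrieve(yn, m, x0)
    normalizedError(estimate(fit), x)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("solver rejects zero initialization and mismatched shapes", {
  m <- sampleMasks(16, K = 2, seed = 55)
  y <- forwardIntensity(runif(16), m)
  expect_error(phaseRetrieve(y, m, numeric(16)), "nonzero")
  expect_error(phaseRetrieve(y, m, runif(8)), "mismatch")
})
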
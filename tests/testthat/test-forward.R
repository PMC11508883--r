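test_that("sampled masks live in the CDP alphabet and are reproducible", {
  m <- sampleMasks(4, K = 1, seed = 42)
  w <- maskMatrix(m)
  expect_equal(dim(w), c(4L, 1L))
  expect_true(all(Mod(w) == 1))
  expect_true(all(w %in% c(1 + 0i, -1 + 0i, 0 + 1i, 0 - 1i)))
  m2 <- sampleMasks(4, K = 1, seed = 42)
  expect_identical(maskMatrix(m2), w)
  expect_false(identical(maskMatrix(sampleMasks(4, K = 1, seed = 43)), w))

  b <- maskMatrix(sampleMasks(16, K = 2, seed = 1, alphabet = "binary"))
  expect_true(all(b %in% c(1 + 0i, -1 + 0i)))
  im <- maskMatrix(sampleMasks(16, K = 2, seed = 1, alphabet = "imaginary"))
  expect_true(all(im %in% c(0 + 1i, 0 - 1i)))

  expect_error(sampleMasks(0, K = 1, seed = 1), "invalid")
  expect_error(sampleMasks(8, K = 0, seed = 1), "invalid")
})

test_that("mask moments match the zero-mean unimodular design", {
  w <- as.vector(maskMatrix(sampleMasks(c(250, 100), K = 4, seed = 7)))
  expect_length(w, 1e5)
  expect_lt(Mod(mean(w)), 0.02)
  expect_lt(Mod(mean(w^2)), 0.02)
  expect_identical(mean(Mod(w)^2), 1)  # exact: alphabet is unimodular
})

test_that("forward intensities obey zero, Parseval and the dense oracle", {
  m <- sampleMasks(16, K = 3, seed = 3)
  y0 <- forwardIntensity(numeric(16), m)
  expect_true(all(intensityMatrix(y0) == 0))

  x <- rnorm(16)
  Y <- intensityMatrix(forwardIntensity(x, m))
  expect_true(all(Y >= 0))
  expect_equal(colSums(Y), rep(16 * sum(x^2), 3))

  m4 <- sampleMasks(4, K = 2, seed = 11)
  x4 <- c(0.3, -1.2, 0.7, 2.1)
  expect_lt(rel_err(intensityMatrix(forwardIntensity(x4, m4)),
                    dense_forward(x4, m4)), 1e-12)

  expect_error(forwardIntensity(rnorm(8), m4), "mismatch")
})

test_that("2-D layout uses the 2-D DFT (kronecker dense oracle)", {
  m <- sampleMasks(c(3, 4), K = 2, seed = 5)
  x <- matrix(runif(12), 3, 4)
  expect_lt(rel_err(intensityMatrix(forwardIntensity(x, m)),
                    dense_forward(x, m)), 1e-12)
})

test_that("bilinear intensities are symmetric, diagonal-consistent and match dense H_ij", {
  m <- sampleMasks(4, K = 2, seed = 13)
  a <- rnorm(4); b <- rnorm(4); x <- runif(4)

  expect_equal(bilinearIntensity(x, x, m),
               intensityMatrix(forwardIntensity(x, m)))
  expect_equal(bilinearIntensity(a, b, m), bilinearIntensity(b, a, m))

  B <- bilinearIntensity(a, b, m)
  for (j in 1:2) for (i in 1:4) {
    expect_equal(B[i, j], as.numeric(a %*% dense_Hij(m, i, j) %*% b),
                 tolerance = 1e-10)
  }
})

test_that("bilinear map is linear in each argument", {
  m <- sampleMasks(8, K = 2, seed = 17)
  a <- rnorm(8); u <- rnorm(8); v <- rnorm(8)
  expect_equal(bilinearIntensity(a, 2 * u + 3 * v, m),
               2 * bilinearIntensity(a, u, m) + 3 * bilinearIntensity(a, v, m))
  expect_equal(bilinearIntensity(2 * u + 3 * v, a, m),
               2 * bilinearIntensity(u, a, m) + 3 * bilinearIntensity(v, a, m))
})

test_that("operator application and adjoint satisfy the inner-product identity and dense oracle", {
  m <- sampleMasks(8, K = 2, seed = 19)
  a <- rnorm(8); v <- rnorm(8)
  r <- matrix(rnorm(16), 8, 2)
  op <- bilinearOperator(a, m)

  expect_true(all(applyAdjoint(op, matrix(0, 8, 2)) == 0))

  lhs <- sum(applyOperator(op, v) * r)
  rhs <- sum(v * applyAdjoint(op, r))
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-9)

  # H_a v stacks to dense_Ha %*% v; adjoint is its transpose action
  m4 <- sampleMasks(4, K = 2, seed = 23)
  a4 <- rnorm(4); r4 <- matrix(rnorm(8), 4, 2)
  op4 <- bilinearOperator(a4, m4)
  Ha <- dense_Ha(a4, m4)
  v4 <- rnorm(4)
  expect_lt(rel_err(as.vector(applyOperator(op4, v4)), as.vector(Ha %*% v4)), 1e-9)
  expect_lt(rel_err(applyAdjoint(op4, r4), as.vector(t(Ha) %*% as.vector(r4))), 1e-9)

  # applying to the anchor reproduces the forward intensities
  expect_equal(applyOperator(op, a), intensityMatrix(forwardIntensity(a, m)))

  expect_error(applyAdjoint(op, matrix(0, 3, 2)), "mismatch")
})

test_that("AWGN hits the requested SNR, is deterministic, and Inf is a no-op", {
  m <- sampleMasks(c(64, 64), K = 4, seed = 29)
  x <- matrix(runif(4096), 64, 64)
  y <- forwardIntensity(x, m)

  expect_identical(addAwgn(y, Inf, seed = 1), y)

  yn <- addAwgn(y, 20, seed = 2)
  eta <- intensityMatrix(yn) - intensityMatrix(y)
  realized <- 10 * log10(sum(intensityMatrix(y)^2) / sum(eta^2))
  expect_lt(abs(realized - 20), 0.2)
  expect_equal(snrDb(yn), 20)

  expect_identical(intensityMatrix(addAwgn(y, 20, seed = 2)),
                   intensityMatrix(yn))
  expect_error(addAwgn(y, -3, seed = 1), "snrDb")
})
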
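test_that("signal generators produce the stated distributions, deterministically", {
  g <- generateSignal("gaussian", c(32, 32), seed = 131)
  expect_true(is.matrix(g))
  expect_lt(abs(mean(g)), 0.1)
  expect_lt(abs(var(as.vector(g)) - 1), 0.15)

  u <- generateSignal("uniform01", 64, seed = 132)
  expect_true(all(u >= 0 & u <= 1))

  expect_identical(generateSignal("gaussian", 64, seed = 7),
                   generateSignal("gaussian", 64, seed = 7))

  p <- phantomImage(48)
  expect_identical(p, phantomImage(48))
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(length(unique(as.vector(p))), 3)  # several gray levels
})

test_that("success-rate experiment is reproducible and scores known cells", {
  df <- runSuccessRateExperiment(signalKinds = "uniform01", Ks = 4L,
                                 dim = c(8L, 8L), nTrials = 8L,
                                 masterSeed = 133)
  df2 <- runSuccessRateExperiment(signalKinds = "uniform01", Ks = 4L,
                                  dim = c(8L, 8L), nTrials = 8L,
                                  masterSeed = 133)
  expect_identical(df, df2)
  expect_equal(df$success_rate, 100)
  expect_true(df$ci_lo < 100 && df$ci_hi == 100)
  expect_named(df, c("solver", "init", "signal_kind", "N", "K", "n_trials",
                     "successes", "success_rate", "ci_lo", "ci_hi"))
})

test_that("per-trial seed streams are distinct deterministic functions of (master, trial)", {
  s <- vapply(1:50, function(t) phasefuse:::.derive_seed(1L, t, 1L), integer(1))
  expect_equal(anyDuplicated(s), 0)
  expect_false(phasefuse:::.derive_seed(1L, 3L, 1L) ==
               phasefuse:::.derive_seed(1L, 3L, 2L))
  expect_identical(s, vapply(1:50, function(t) phasefuse:::.derive_seed(1L, t, 1L),
                             integer(1)))
})

test_that("convergence traces show the K and SNR trends on matched seeds", {
  x <- phantomImage(32)
  tr <- runConvergenceTrace(x, Ks = 8L, snrDbs = Inf, masterSeed = 135)
  expect_lt(min(tr$err), 1e-6)

  trK <- runConvergenceTrace(x, Ks = c(2L, 16L), snrDbs = 24, masterSeed = 136)
  fin <- tapply(trK$err, trK$K, function(e) tail(e, 1))
  expect_gte(fin[["2"]], fin[["16"]])

  trS <- runConvergenceTrace(x, Ks = 8L, snrDbs = c(10, 30), masterSeed = 137)
  finS <- tapply(trS$err, trS$snr_db, function(e) tail(e, 1))
  expect_gte(finS[["10"]], finS[["30"]])
})

test_that("noisy-reconstruction benchmark emits the frozen schema with sane values", {
  x <- phantomImage(32)
  df <- runNoisyReconstruction(x, methods = c("proposed", "wf"),
                               Ks = c(4L, 8L), snrDbs = c(Inf, 24),
                               masterSeed = 138, baselineIters = 400L)
  expect_setequal(unique(df$solver), c("proposed", "wf"))

  clean <- df[df$solver == "proposed" & !is.finite(df$snr_db), ]
  expect_true(all(clean$err < 1e-6))
  expect_true(all(clean$ssim > 0.99))

  # more masks never hurt the proposed method at fixed SNR
  noisy <- df[df$solver == "proposed" & df$snr_db == 24, ]
  expect_gte(noisy$psnr[noisy$K == 8], noisy$psnr[noisy$K == 4])

  p <- file.path(tempdir(), "bench.csv")
  writeMetricsCsv(df, p)
  back <- read.csv(p)
  expect_identical(names(back),
                   c("solver", "init", "signal_kind", "N", "K", "snr_db",
                     "trial", "err", "psnr", "ssim", "n_iters", "converged"))
  unlink(p)
})
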
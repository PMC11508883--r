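#' Generate a synthetic test signal
#'
#' @param kind \code{"uniform01"} (i.i.d. U(0,1) entries, the nonnegative
#'   study condition), \code{"gaussian"} (i.i.d. N(0,1), the general real
#'   condition), \code{"phantom"} (deterministic piecewise-constant test
#'   image in [0, 1]; seed ignored) or \code{"image_file"} (grayscale
#'   PNG/TIFF loaded to [0, 1]).
#' @param dim length N or \code{c(H, W)}.
#' @param seed integer RNG seed (random kinds).
#' @param path file path when \code{kind = "image_file"}.
#' @return a real vector or matrix.
#' @export
generateSignal <- function(kind = c("uniform01", "gaussian", "phantom", "image_file"),
                           dim, seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  N <- prod(dim)
  if (kind == "image_file") {
    if (is.null(path)) stop("image_file needs a path")
    return(readSignalImage(path))
  }
  if (kind == "phantom") return(phantomImage(dim))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- switch(kind, uniform01 = stats::runif(N), gaussian = stats::rnorm(N))
  .restore_layout(v, dim)
}

#' Deterministic piecewise-constant phantom image
#'
#' A built-in test image in [0, 1] (flat background with rectangular and
#' elliptical patches of distinct gray levels), so image experiments need
#' no downloads.
#'
#' @param dim \code{c(H, W)} (a scalar gives a square image).
#' @return an H x W matrix in [0, 1].
#' @export
phantomImage <- function(dim) {
  dim <- as.integer(dim)
  if (length(dim) == 1L) dim <- c(dim, dim)
  H <- dim[1L]; W <- dim[2L]
  ri <- (row(matrix(0, H, W)) - 0.5) / H
  ci <- (col(matrix(0, H, W)) - 0.5) / W
  img <- matrix(0.1, H, W)
  img[ri > 0.1 & ri < 0.9 & ci > 0.1 & ci < 0.9] <- 0.35
  img[((ri - 0.4)^2 / 0.07 + (ci - 0.35)^2 / 0.04) < 1] <- 0.75
  img[((ri - 0.6)^2 / 0.02 + (ci - 0.65)^2 / 0.05) < 1] <- 0.55
  img[ri > 0.65 & ri < 0.85 & ci > 0.15 & ci < 0.35] <- 0.95
  img[abs(ri - ci) < 0.03] <- pmax(img[abs(ri - ci) < 0.03], 0.85)
  img
}

# Build the initialization for one trial.
.make_init <- function(init, y, masks, seed) {
  switch(init,
    random = randomPositiveInit(y, masks, seed),
    wf = spectralInit("wf", y, masks, seed = seed),
    twf = spectralInit("twf", y, masks, seed = seed),
    taf = spectralInit("taf", y, masks, seed = seed),
    stop("unknown init: ", init))
}

# Run one solver (proposed or baseline) on prepared observations.
.run_solver <- function(solver, y, masks, x0, truth, config) {
  if (solver == "proposed") {
    phaseRetrieve(y, masks, x0, config = config, groundTruth = truth)
  } else {
    runBaseline(baselineConfig(solver), y, masks, x0, groundTruth = truth)
  }
}

#' Success-rate experiment
#'
#' For each combination of solver, initialization, signal kind and mask
#' count, draws \code{nTrials} independent (signal, mask set) pairs with
#' per-trial derived seeds, generates noise-free observations, runs the
#' solver and scores success as normalized error below \code{threshold}.
#' A trial that raises an error counts as a failure.
#'
#' @param solvers,inits,signalKinds,Ks character/integer vectors defining
#'   the experiment grid.
#' @param dim signal dimensions (default \code{c(32, 32)}).
#' @param nTrials trials per cell (default 100; 95% binomial confidence
#'   intervals are reported alongside).
#' @param threshold success cutoff on the normalized error (default 1e-5).
#' @param masterSeed master seed; per-trial signal and mask seeds are
#'   distinct deterministic functions of (masterSeed, trial).
#' @param config a [solverConfig()] for the proposed solver.
#' @return a data.frame with one row per cell: solver, init, signal_kind,
#'   N, K, n_trials, successes, success_rate, ci_lo, ci_hi.
#' @export
runSuccessRateExperiment <- function(solvers = "proposed", inits = "random",
                                     signalKinds = "uniform01", Ks = 2L,
                                     dim = c(32L, 32L), nTrials = 100L,
                                     threshold = 1e-5, masterSeed = 1L,
                                     config = solverConfig()) {
  grid <- expand.grid(solver = solvers, init = inits,
                      signal_kind = signalKinds, K = as.integer(Ks),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    errs <- vapply(seq_len(nTrials), function(t) {
      cellSeed <- .derive_seed(masterSeed, i, 900L)
      x <- generateSignal(g$signal_kind, dim, seed = .derive_seed(cellSeed, t, 1L))
      masks <- sampleMasks(dim, g$K, seed = .derive_seed(cellSeed, t, 2L))
      y <- forwardIntensity(x, masks)
      tryCatch({
        x0 <- .make_init(g$init, y, masks, .derive_seed(cellSeed, t, 3L))
        fit <- .run_solver(g$solver, y, masks, x0, NULL, config)
        normalizedError(estimate(fit), x)
      }, error = function(e) Inf)
    }, numeric(1))
    succ <- sum(errs < threshold)
    ci <- stats::binom.test(succ, nTrials)$conf.int
    data.frame(solver = g$solver, init = g$init, signal_kind = g$signal_kind,
               N = prod(as.integer(dim)), K = g$K, n_trials = nTrials,
               successes = succ, success_rate = 100 * succ / nTrials,
               ci_lo = 100 * ci[1L], ci_hi = 100 * ci[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Convergence-trace experiment
#'
#' Records the per-outer-iteration normalized error of the proposed solver
#' for every (K, SNR) combination on one ground-truth signal, with matched
#' seeds across combinations so trends in K and SNR are comparable.
#'
#' @param x ground-truth signal (vector or matrix).
#' @param Ks mask counts.
#' @param snrDbs SNR levels in dB (Inf for noise-free).
#' @param masterSeed master seed (mask and noise seeds derive from it).
#' @param init \code{"random"}, \code{"wf"}, \code{"twf"} or \code{"taf"}.
#' @param config a [solverConfig()].
#' @return long data.frame: K, snr_db, iter, err, plus the final error per
#'   combination in attribute-free rows (filter \code{iter == max(iter)}).
#' @export
runConvergenceTrace <- function(x, Ks = c(2L, 4L, 8L), snrDbs = Inf,
                                masterSeed = 1L, init = "random",
                                config = solverConfig()) {
  s <- .check_signal(x)
  rows <- list()
  for (K in Ks) for (snr in snrDbs) {
    masks <- sampleMasks(s$dim, K, seed = .derive_seed(masterSeed, K, 2L))
    y <- forwardIntensity(x, masks)
    y <- addAwgn(y, snr, seed = .derive_seed(masterSeed, K, 4L))
    x0 <- .make_init(init, y, masks, .derive_seed(masterSeed, K, 3L))
    fit <- phaseRetrieve(y, masks, x0, config = config, groundTruth = x)
    tr <- errTrace(fit)
    rows[[length(rows) + 1L]] <-
      data.frame(K = K, snr_db = snr, iter = seq_along(tr), err = tr)
  }
  do.call(rbind, rows)
}

#' Noisy-reconstruction benchmark
#'
#' Reconstructs an image-layout signal for each (method, K, SNR)
#' combination and reports the normalized error, PSNR and SSIM. The
#' TAF-family methods consume magnitudes, so their observations are
#' corrupted on the magnitudes at the same nominal SNR; the others are
#' corrupted on the squared magnitudes.
#'
#' @param x ground-truth image (matrix in [0, 1]); default a 64 x 64
#'   phantom.
#' @param methods solvers to compare (\code{"proposed"} and/or baselines).
#' @param Ks mask counts.
#' @param snrDbs SNR levels in dB.
#' @param init initialization id (shared by all methods).
#' @param masterSeed master seed.
#' @param config a [solverConfig()] for the proposed solver.
#' @param baselineIters iteration cap for baseline methods.
#' @return data.frame with columns solver, init, signal_kind, N, K,
#'   snr_db, trial, err, psnr, ssim, n_iters, converged (the frozen
#'   metrics CSV schema).
#' @export
runNoisyReconstruction <- function(x = phantomImage(64L),
                                   methods = "proposed", Ks = c(2L, 4L, 8L),
                                   snrDbs = c(Inf, 30, 24, 20, 10),
                                   init = "random", masterSeed = 1L,
                                   config = solverConfig(),
                                   baselineIters = 1000L) {
  if (!is.matrix(x)) stop("runNoisyReconstruction needs an image-layout ground truth")
  rows <- list()
  for (K in Ks) for (snr in snrDbs) {
    masks <- sampleMasks(dim(x), K, seed = .derive_seed(masterSeed, K, 2L))
    yClean <- forwardIntensity(x, masks)
    y <- addAwgn(yClean, snr, seed = .derive_seed(masterSeed, K, 4L))
    for (mth in methods) {
      isMag <- mth %in% c("taf", "mrtaf")
      if (isMag) {
        # same nominal SNR applied to the magnitudes
        mags <- new("Intensities", Y = sqrt(intensityMatrix(yClean)),
                    snrDb = Inf, dim = signalDim(yClean))
        yUse <- addAwgn(mags, snr, seed = .derive_seed(masterSeed, K, 5L))
      } else {
        yUse <- y
      }
      x0 <- .make_init(init, y, masks, .derive_seed(masterSeed, K, 3L))
      fit <- if (mth == "proposed") {
        phaseRetrieve(y, masks, x0, config = config, groundTruth = x)
      } else {
        runBaseline(baselineConfig(mth, maxIters = baselineIters), yUse,
                    masks, x0, groundTruth = x, inputIsMagnitude = isMag)
      }
      iq <- imageQuality(estimate(fit), x)
      rows[[length(rows) + 1L]] <- data.frame(
        solver = mth, init = init, signal_kind = "image", N = length(x),
        K = K, snr_db = snr, trial = 1L,
        err = normalizedError(estimate(fit), x),
        psnr = iq$psnr, ssim = iq$ssim,
        n_iters = iterations(fit), converged = hasConverged(fit),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a metrics table in the frozen CSV schema
#'
#' Column order is fixed (solver, init, signal_kind, N, K, snr_db, trial,
#' err, psnr, ssim, n_iters, converged) so runs can be diffed.
#'
#' @param df a data.frame holding at least the schema columns it has;
#'   missing schema columns are filled with NA.
#' @param path output file.
#' @export
writeMetricsCsv <- function(df, path) {
  schema <- c("solver", "init", "signal_kind", "N", "K", "snr_db", "trial",
              "err", "psnr", "ssim", "n_iters", "converged")
  for (cn in setdiff(schema, names(df))) df[[cn]] <- NA
  utils::write.csv(df[schema], path, row.names = FALSE)
  invisible(path)
}
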
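#' Positive random initialization
#'
#' Draws i.i.d. uniform(0, 1) entries and rescales them so that
#' ||x0||^2 = sum(Y) / (N K), the Parseval-based energy estimate of
#' ||x||^2 (exact for noise-free observations under the unnormalized DFT
#' with unimodular masks). Two properties matter: all entries are strictly
#' positive, and the norm matches the truth to within the noise. Its error
#' is essentially independent of K, and for nonnegative signals the
#' positivity makes it a surprisingly strong start.
#'
#' @param y an [Intensities-class].
#' @param masks the matching [MaskSet-class].
#' @param seed integer RNG seed.
#' @return a strictly positive real signal in the observations' layout.
#' @export
randomPositiveInit <- function(y, masks, seed) {
  Y <- intensityMatrix(y)
  energy2 <- sum(Y) / length(Y)
  if (!is.finite(energy2) || energy2 <= 0)
    stop("cannot scale the initialization: observations carry no energy")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- stats::runif(nrow(Y))
  v <- v * sqrt(energy2) / sqrt(sum(v^2))
  .restore_layout(v, signalDim(y))
}

#' Spectral initialization configuration
#'
#' @param powerIters power-method iterations (default 50).
#' @param truncationAlpha TWF truncation multiplier alpha_y (default 3):
#'   samples with y > alpha^2 * lambda^2 are discarded, lambda^2 being the
#'   Parseval energy estimate.
#' @param tafFraction fraction of rows kept by the TAF
#'   orthogonality-promoting rule (default 1/6): the rows with the
#'   smallest amplitudes span (approximately) the orthogonal complement
#'   of x, so the practical rule power-iterates on the complementary set
#'   of largest correlations.
#' @return a list of class \code{"SpectralInitConfig"}.
#' @export
spectralInitConfig <- function(powerIters = 50L, truncationAlpha = 3,
                               tafFraction = 1 / 6) {
  stopifnot(powerIters >= 1, truncationAlpha > 0,
            tafFraction > 0, tafFraction < 1)
  structure(list(powerIters = as.integer(powerIters),
                 truncationAlpha = truncationAlpha,
                 tafFraction = tafFraction),
            class = "SpectralInitConfig")
}

#' Spectral initializations (WF, TWF, TAF)
#'
#' Estimates x as the leading eigenvector, computed by power iteration, of
#' the data-weighted operator v -> sum_ij w_ij H_ij v, applied matrix-free
#' (each application costs 2K FFTs). The weights are method-specific:
#' \describe{
#'   \item{wf}{w = y (the plain spectral method).}
#'   \item{twf}{w = y truncated at alpha^2 lambda^2, discarding outlier
#'     samples that dominate the unweighted operator's tail.}
#'   \item{taf}{unit weights on the rows with the largest amplitudes
#'     (the orthogonality-promoting rule; for CDP rows all row norms equal
#'     sqrt(N), so the normalized correlation ordering is the amplitude
#'     ordering).}
#' }
#' The eigenvector is rescaled to the Parseval energy estimate, so for
#' noise-free data every init's norm matches ||x|| to within rounding.
#'
#' @param method \code{"wf"}, \code{"twf"} or \code{"taf"}.
#' @param y an [Intensities-class].
#' @param masks the matching [MaskSet-class].
#' @param config a [spectralInitConfig()].
#' @param seed integer RNG seed for the power method's starting vector.
#' @return a real signal in the observations' layout (sign arbitrary).
#' @export
spectralInit <- function(method = c("wf", "twf", "taf"), y, masks,
                         config = spectralInitConfig(), seed = 1L) {
  method <- match.arg(method)
  Y <- intensityMatrix(y)
  lambda2 <- sum(Y) / length(Y)
  if (!is.finite(lambda2) || lambda2 <= 0)
    stop("cannot scale the initialization: observations carry no energy")
  W <- switch(method,
    wf = Y,
    twf = Y * (Y <= config$truncationAlpha^2 * lambda2),
    taf = {
      psi <- sqrt(pmax(Y, 0))
      thr <- stats::quantile(psi, 1 - config$tafFraction, names = FALSE)
      (psi >= thr) * 1
    })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- stats::rnorm(nrow(Y))
  v <- v / sqrt(sum(v^2))
  for (it in seq_len(config$powerIters)) {
    op <- bilinearOperator(.restore_layout(v, signalDim(masks)), masks)
    v <- applyAdjoint(op, W)
    nv <- sqrt(sum(v^2))
    if (!is.finite(nv) || nv == 0)
      stop("power iteration failed to produce a finite eigenvector")
    v <- v / nv
  }
  .restore_layout(v * sqrt(lambda2), signalDim(y))
}
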
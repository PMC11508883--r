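#' Sign-invariant normalized reconstruction error
#'
#' For real signals the observations determine x only up to a global sign,
#' so the error is min(||xhat - x||, ||xhat + x||) / ||x|| (the real-signal
#' specialization of the global-phase-invariant metric).
#'
#' @param xhat estimate (vector or matrix).
#' @param x ground truth, same shape, nonzero.
#' @return nonnegative scalar.
#' @export
normalizedError <- function(xhat, x) {
  if (length(xhat) != length(x)) stop("shape mismatch")
  nx <- sqrt(sum(x^2))
  if (nx == 0) stop("ground truth must be nonzero")
  v <- as.vector(xhat); w <- as.vector(x)
  min(sqrt(sum((v - w)^2)), sqrt(sum((v + w)^2))) / nx
}

#' PSNR and SSIM of a reconstructed image
#'
#' The estimate is first sign-aligned to the ground truth (the global sign
#' is unidentifiable), then PSNR is computed on the nominal [0, 1] dynamic
#' range and SSIM with the standard constants (11 x 11 Gaussian window,
#' sigma 1.5, K1 = 0.01, K2 = 0.03). A perfect reconstruction reports the
#' capped sentinel \code{psnrCap} instead of infinite PSNR.
#'
#' @param xhat,x image-layout signals (matrices) of identical shape.
#' @param psnrCap PSNR (dB) reported when the MSE is zero.
#' @return list with elements \code{psnr} (dB) and \code{ssim} (in [-1, 1]).
#' @export
imageQuality <- function(xhat, x, psnrCap = 150) {
  if (!is.matrix(xhat) || !is.matrix(x) || !all(dim(xhat) == dim(x)))
    stop("shape mismatch: imageQuality needs two matrices of equal size")
  if (sum((xhat - x)^2) > sum((xhat + x)^2)) xhat <- -xhat
  mse <- mean((xhat - x)^2)
  psnr <- if (mse == 0) psnrCap else min(10 * log10(1 / mse), psnrCap)
  list(psnr = psnr, ssim = .ssim(xhat, x))
}

# SSIM with the standard Wang et al. constants on dynamic range 1.
.ssim <- function(a, b, winSize = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  C1 <- K1^2; C2 <- K2^2
  winSize <- min(winSize, nrow(a), ncol(a))  # shrink window for tiny images
  w <- .gaussian_kernel(winSize, sigma)
  mu_a <- .conv2_valid(a, w); mu_b <- .conv2_valid(b, w)
  s_aa <- .conv2_valid(a * a, w) - mu_a^2
  s_bb <- .conv2_valid(b * b, w) - mu_b^2
  s_ab <- .conv2_valid(a * b, w) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + C1) * (2 * s_ab + C2)
  den <- (mu_a^2 + mu_b^2 + C1) * (s_aa + s_bb + C2)
  mean(num / den)
}

.gaussian_kernel <- function(n, sigma) {
  r <- seq_len(n) - (n + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# 2-D 'valid' convolution of image A with small kernel w.
.conv2_valid <- function(A, w) {
  n <- nrow(w)
  out <- matrix(0, nrow(A) - n + 1L, ncol(A) - n + 1L)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    out <- out + w[i, j] *
      A[i:(i + nrow(out) - 1L), j:(j + ncol(out) - 1L)]
  }
  out
}

#' Success rate of a batch of reconstructions
#'
#' @param errors numeric vector of normalized errors, one per trial.
#' @param threshold success cutoff (default 1e-5, the package's convention
#'   for "exact" recovery in success-rate tables).
#' @return percentage in [0, 100].
#' @export
successRate <- function(errors, threshold = 1e-5) {
  if (length(errors) == 0) stop("empty error list")
  if (threshold <= 0) stop("threshold must be positive")
  100 * mean(errors < threshold)
}

#' Worst-case contraction bound function
#'
#' The scalar function f(u) = (u + 1) / (1 + 3 u^2) of the angle cosine
#' u = cos(theta_gb) that appears in the solver's convergence analysis;
#' its maximum over [-1, 1] (about 1.0774, attained near u = 0.1547)
#' stays below the worst-case constant 1.08 used in the contraction and
#' basin-radius bounds.
#'
#' @param u numeric values in [-1, 1].
#' @return f(u), vectorized.
#' @export
boundFunction <- function(u) {
  if (any(u < -1 | u > 1)) stop("u must lie in [-1, 1]")
  (u + 1) / (1 + 3 * u^2)
}

#' @rdname boundFunction
#' @param gridPoints grid size for the dense search (default 1e6).
#' @return \code{boundFunctionMax}: list with the grid maximum \code{value}
#'   and its location \code{argmax}.
#' @export
boundFunctionMax <- function(gridPoints = 1e6) {
  u <- seq(-1, 1, length.out = gridPoints)
  f <- boundFunction(u)
  i <- which.max(f)
  list(value = f[i], argmax = u[i])
}

#' Error-geometry diagnostics against a known truth
#'
#' Computes the error vectors d = a - x and e = b - x, their sum g, the
#' contraction ratio mu = ||e||/||b|| and the angle cosines between g, b
#' and e, and flags whether mu <= 1/1.08 (the zero-slack convergence
#' condition) and whether ||e|| <= 0.48 ||x|| (the basin-of-attraction
#' radius).
#'
#' @param a,b the split variables.
#' @param x ground truth; ||x|| and ||b|| must be positive.
#' @return a [ConvergenceDiagnostics-class].
#' @export
convergenceDiagnostics <- function(a, b, x) {
  a <- as.vector(a); b <- as.vector(b); x <- as.vector(x)
  if (sqrt(sum(x^2)) == 0 || sqrt(sum(b^2)) == 0)
    stop("zero-norm input: x and b must be nonzero")
  d <- a - x; e <- b - x; g <- d + e
  nb <- sqrt(sum(b^2)); ne <- sqrt(sum(e^2)); nx <- sqrt(sum(x^2))
  mu <- ne / nb
  cosang <- function(u, v) {
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) return(0)
    max(-1, min(1, sum(u * v) / (nu * nv)))
  }
  new("ConvergenceDiagnostics", d = d, e = e, g = g, mu = mu,
      cosGB = cosang(g, b), cosGE = cosang(g, e), cosEB = cosang(e, b),
      muOk = mu <= 1 / 1.08, inBasin = ne <= 0.48 * nx)
}
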
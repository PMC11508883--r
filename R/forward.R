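#' Draw a set of coded diffraction pattern masks
#'
#' Samples K diagonal modulation masks with entries drawn i.i.d. uniformly
#' from a unimodular alphabet, by default the quaternary CDP dictionary
#' \{1, -1, i, -i\}. These masks make the measurement operator behave like a
#' random sensing matrix: the entries satisfy E(w) = 0, E(w^2) = 0 and
#' |w|^2 = 1 exactly, the moment structure the solver's convergence theory
#' relies on. The \code{"binary"} (\{1, -1\}) and \code{"imaginary"}
#' (\{i, -i\}) sub-alphabets preserve the zero-mean property and are
#' offered as variants.
#'
#' @param dim signal dimensions: a single length N (vector layout) or a
#'   pair \code{c(H, W)} (image layout, N = H * W).
#' @param K number of masks (>= 1).
#' @param seed integer RNG seed; the draw is reproducible given the seed.
#' @param alphabet \code{"quaternary"}, \code{"binary"} or \code{"imaginary"}.
#' @return a [MaskSet-class].
#' @examples
#' m <- sampleMasks(64, K = 4, seed = 1)
#' nMasks(m)
#' @export
sampleMasks <- function(dim, K, seed, alphabet = c("quaternary", "binary", "imaginary")) {
  alphabet <- match.arg(alphabet)
  dim <- as.integer(dim)
  if (any(dim < 1L) || prod(dim) < 2L) stop("invalid dim: need N >= 2")
  if (K < 1L) stop("invalid K: need K >= 1")
  N <- prod(dim)
  dict <- switch(alphabet,
    quaternary = c(1 + 0i, -1 + 0i, 0 + 1i, 0 - 1i),
    binary     = c(1 + 0i, -1 + 0i),
    imaginary  = c(0 + 1i, 0 - 1i))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m <- matrix(sample(dict, N * K, replace = TRUE), N, K)
  new("MaskSet", masks = m, dim = dim, alphabet = alphabet,
      seed = as.integer(seed))
}

# Save/restore the global RNG state so that seeded draws inside the package
# do not perturb a caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' CDP intensity forward model
#'
#' Computes the noise-free squared-magnitude observations
#' y[i, j] = |DFT(W_j x)_i|^2 with the unnormalized DFT (2-D DFT for image
#' layout). By Parseval's identity each mask column sums to N ||x||^2.
#'
#' @param x real signal (vector or matrix matching the masks' layout).
#' @param masks a [MaskSet-class] with matching N.
#' @return an [Intensities-class] with \code{snrDb = Inf}.
#' @examples
#' m <- sampleMasks(16, K = 2, seed = 7)
#' y <- forwardIntensity(runif(16), m)
#' @export
forwardIntensity <- function(x, masks) {
  s <- .check_signal(x)
  .match_dims(s, masks)
  Z <- .masked_spectra(s$values, masks)
  new("Intensities", Y = Mod(Z)^2, snrDb = Inf, dim = signalDim(masks))
}

#' Bilinear split-variable intensities
#'
#' Entry (i, j) is a' H_ij b with H_ij = Re(W_j^* conj(f_i) f_i' W_j),
#' computed matrix-free as Re(z_a conj(z_b)) from the masked spectra. The
#' diagonal case \code{bilinearIntensity(x, x, masks)} reproduces
#' [forwardIntensity()]; the map is symmetric in (a, b) and linear in each
#' argument separately.
#'
#' @param a,b real signals sharing the masks' layout.
#' @param masks a [MaskSet-class].
#' @return real N x K matrix.
#' @export
bilinearIntensity <- function(a, b, masks) {
  sa <- .check_signal(a, "a"); sb <- .check_signal(b, "b")
  .match_dims(sa, masks); .match_dims(sb, masks)
  Za <- .masked_spectra(sa$values, masks)
  Zb <- .masked_spectra(sb$values, masks)
  Re(Za * Conj(Zb))
}

#' Build the anchored bilinear operator H_a
#'
#' Caches the anchor spectra so that repeated applications of H_a and its
#' adjoint cost K FFTs each.
#'
#' @param anchor real signal a.
#' @param masks a [MaskSet-class].
#' @return a [BilinearOperator-class].
#' @export
bilinearOperator <- function(anchor, masks) {
  s <- .check_signal(anchor, "anchor")
  .match_dims(s, masks)
  new("BilinearOperator", anchor = s$values, masks = masks,
      spectra = .masked_spectra(s$values, masks))
}

#' Apply an anchored bilinear operator
#'
#' \code{applyOperator(op, v)} returns the N x K matrix with entries
#' a' H_ij v (the stacked H_a v of the normal equations);
#' \code{applyAdjoint(op, r)} returns the real N-vector
#' sum_ij r[i, j] H_ij a, so that the inner-product identity
#' \code{sum(applyOperator(op, v) * r) == sum(v * applyAdjoint(op, r))}
#' holds. Both are matrix-free through the cached anchor spectra.
#'
#' @param op a [BilinearOperator-class].
#' @param v real signal with the operator's N.
#' @return \code{applyOperator}: real N x K matrix.
#' @export
applyOperator <- function(op, v) {
  s <- .check_signal(v, "v")
  if (length(s$values) != length(op@anchor)) stop("size mismatch")
  Zv <- .masked_spectra(s$values, op@masks)
  Re(op@spectra * Conj(Zv))
}

#' @rdname applyOperator
#' @param r real N x K matrix of residuals/weights.
#' @return \code{applyAdjoint}: real N-vector.
#' @export
applyAdjoint <- function(op, r) {
  m <- maskMatrix(op@masks)
  d <- signalDim(op@masks)
  if (!is.matrix(r) || nrow(r) != nrow(m) || ncol(r) != ncol(m))
    stop("shape mismatch: r must be N x K")
  N <- nrow(m)
  acc <- complex(N)
  for (j in seq_len(ncol(m))) {
    u <- r[, j] * op@spectra[, j]
    acc <- acc + Conj(m[, j]) * .layout_fft_h(u, d)
  }
  Re(acc)
}

#' Corrupt observations with additive white Gaussian noise
#'
#' Adds i.i.d. zero-mean Gaussian noise to the squared magnitudes, with the
#' variance set so that the expected SNR, 10 log10(||Y||^2 / ||eta||^2)
#' over the full stacked observation vector, equals \code{snrDb}.
#' \code{snrDb = Inf} returns the input unchanged.
#'
#' @param obs an [Intensities-class].
#' @param snrDb target SNR in dB (> 0, or Inf).
#' @param seed integer RNG seed (reproducible).
#' @return an [Intensities-class] with the nominal \code{snrDb} recorded.
#' @export
addAwgn <- function(obs, snrDb, seed) {
  if (!is.finite(snrDb)) return(obs)
  if (snrDb <= 0) stop("snrDb must be in (0, Inf]")
  Y <- intensityMatrix(obs)
  sigma2 <- sum(Y^2) / length(Y) / 10^(snrDb / 10)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eta <- matrix(stats::rnorm(length(Y), sd = sqrt(sigma2)), nrow(Y), ncol(Y))
  new("Intensities", Y = Y + eta, snrDb = snrDb, dim = signalDim(obs))
}
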
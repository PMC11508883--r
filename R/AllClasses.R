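#' @import methods
#' @importFrom stats fft rnorm runif quantile median sd binom.test
#' @importFrom utils write.csv write.table read.table tail
#' @importFrom tools file_ext
#' @importFrom Rcpp evalCpp
#' @useDynLib phasefuse, .registration = TRUE
NULL

#' Coded diffraction pattern mask set
#'
#' A set of K diagonal modulation masks for the coded diffraction pattern
#' (CDP) acquisition model. Each mask is stored as the N-vector of its
#' diagonal; entries are drawn from a unimodular alphabet (by default the
#' quaternary CDP dictionary \{1, -1, i, -i\}). The signal layout
#' (1-D vector or 2-D image) travels with the masks so that all FFT-based
#' operators know which DFT to apply.
#'
#' @slot masks complex N x K matrix; column j is the diagonal of mask j.
#' @slot dim integer signal dimensions: length 1 (vector layout) or
#'   length 2 (image layout, \code{prod(dim) == N}).
#' @slot alphabet character, one of \code{"quaternary"} (\{1,-1,i,-i\}),
#'   \code{"binary"} (\{1,-1\}) or \code{"imaginary"} (\{i,-i\}).
#' @slot seed integer RNG seed used to draw the masks.
#'
#' @seealso [sampleMasks()], [forwardIntensity()]
#' @export
setClass("MaskSet",
  representation(masks = "matrix", dim = "integer",
                 alphabet = "character", seed = "integer"))

setValidity("MaskSet", function(object) {
  m <- object@masks
  if (!is.complex(m)) return("masks must be a complex matrix")
  if (ncol(m) < 1L) return("K must be >= 1")
  if (nrow(m) != prod(object@dim)) return("mask length must equal prod(dim)")
  if (nrow(m) < 2L) return("signal length N must be >= 2")
  if (max(abs(Mod(m) - 1)) > 1e-12) return("mask entries must be unimodular")
  on_axis <- (abs(Re(m)) < 1e-12) | (abs(Im(m)) < 1e-12)
  if (!all(on_axis)) return("mask entries must lie in {1,-1,i,-i}")
  TRUE
})

#' CDP intensity observations
#'
#' The N x K matrix of (optionally noisy) squared DFT magnitudes
#' y[i, j] = |DFT(W_j x)_i|^2 + eta[i, j] produced by the CDP forward
#' model. The convention is squared magnitudes throughout; solvers that
#' consume plain magnitudes take the square root themselves.
#'
#' @slot Y real N x K observation matrix.
#' @slot snrDb nominal SNR in dB at which noise was added
#'   (\code{Inf} for noise-free data).
#' @slot dim integer signal dimensions (as in [MaskSet-class]).
#'
#' @seealso [forwardIntensity()], [addAwgn()]
#' @export
setClass("Intensities",
  representation(Y = "matrix", snrDb = "numeric", dim = "integer"))

setValidity("Intensities", function(object) {
  if (!is.numeric(object@Y)) return("Y must be a numeric matrix")
  if (nrow(object@Y) != prod(object@dim)) return("nrow(Y) must equal prod(dim)")
  if (length(object@snrDb) != 1L) return("snrDb must be a scalar")
  if (!is.na(object@snrDb) && object@snrDb <= 0) return("snrDb must be positive (use Inf for noise-free)")
  TRUE
})

#' Bilinear split-variable measurement operator
#'
#' The linear operator H_a obtained by anchoring one of the split
#' variables: (H_a v)(i, j) = a' H_ij v, where
#' H_ij = Re(W_j^* conj(f_i) f_i' W_j) and f_i is the i-th DFT row.
#' The K anchor spectra z_{a, ., j} = DFT(W_j a) are cached so repeated
#' applications cost K FFTs each; the N x N matrices H_ij are never formed.
#'
#' @slot anchor real N-vector (the anchoring split variable).
#' @slot masks a [MaskSet-class].
#' @slot spectra complex N x K matrix of cached anchor spectra.
#'
#' @seealso [bilinearOperator()], [applyOperator()], [applyAdjoint()]
#' @export
setClass("BilinearOperator",
  representation(anchor = "numeric", masks = "MaskSet", spectra = "matrix"))

#' Result of a phase-retrieval solve
#'
#' @slot xhat recovered signal (vector or matrix, matching the input layout).
#' @slot errTrace per-outer-iteration sign-invariant normalized error
#'   (empty unless a ground truth was supplied).
#' @slot deltaTrace per-iteration relative step size of the fused estimate.
#' @slot nIters outer iterations used.
#' @slot converged logical; TRUE when the stopping rule fired before the
#'   iteration cap (non-convergence is a result, not an error).
#' @slot method,init character labels for bookkeeping.
#'
#' @seealso [phaseRetrieve()], [runBaseline()]
#' @export
setClass("RecoveryResult",
  representation(xhat = "ANY", errTrace = "numeric", deltaTrace = "numeric",
                 nIters = "integer", converged = "logical",
                 method = "character", init = "character"))

#' Error-geometry diagnostics of the split-variable iteration
#'
#' Quantities from the solver's convergence analysis, measured against a
#' known ground truth x: the error vectors d = a - x and e = b - x, their
#' sum g = d + e, the contraction ratio mu = ||e||/||b||, and the angle
#' cosines between g, b and e that drive the theoretical bound. The
#' concentration slack is taken in its zero limit, so the convergence
#' condition checked is mu <= 1/1.08 and the basin condition
#' ||e|| <= 0.48 ||x||.
#'
#' @slot d,e,g real N-vectors (errors of a, of b, and their sum).
#' @slot mu ||e||/||b||, non-negative.
#' @slot cosGB,cosGE,cosEB angle cosines, each in [-1, 1].
#' @slot muOk logical: mu <= 1/1.08.
#' @slot inBasin logical: ||e|| <= 0.48 ||x||.
#'
#' @seealso [convergenceDiagnostics()], [boundFunction()]
#' @export
setClass("ConvergenceDiagnostics",
  representation(d = "numeric", e = "numeric", g = "numeric", mu = "numeric",
                 cosGB = "numeric", cosGE = "numeric", cosEB = "numeric",
                 muOk = "logical", inBasin = "logical"))

setMethod("show", "MaskSet", function(object) {
  cat(sprintf("MaskSet: K = %d masks, N = %d (%s), alphabet = %s, seed = %d\n",
              ncol(object@masks), nrow(object@masks),
              paste(object@dim, collapse = " x "),
              object@alphabet, object@seed))
})

setMethod("show", "Intensities", function(object) {
  cat(sprintf("Intensities: %d x %d squared magnitudes (%s layout), SNR = %s dB\n",
              nrow(object@Y), ncol(object@Y),
              if (length(object@dim) == 2L) "image" else "vector",
              format(object@snrDb)))
})

setMethod("show", "BilinearOperator", function(object) {
  cat(sprintf("BilinearOperator: H_a with N = %d, K = %d (matrix-free, spectra cached)\n",
              length(object@anchor), ncol(object@spectra)))
})

setMethod("show", "RecoveryResult", function(object) {
  cat(sprintf("RecoveryResult: method = %s, init = %s, %d outer iterations, converged = %s\n",
              object@method, object@init, object@nIters, object@converged))
  if (length(object@errTrace))
    cat(sprintf("  final normalized error: %.3e\n", tail(object@errTrace, 1L)))
})

setMethod("show", "ConvergenceDiagnostics", function(object) {
  cat(sprintf("ConvergenceDiagnostics: mu = %.4f (mu <= 1/1.08: %s), in 0.48 basin: %s\n",
              object@mu, object@muOk, object@inBasin))
})

#' @describeIn MaskSet-class number of masks K
#' @param object a \code{MaskSet}
#' @export
setGeneric("nMasks", function(object) standardGeneric("nMasks"))
setMethod("nMasks", "MaskSet", function(object) ncol(object@masks))

#' @describeIn MaskSet-class the complex N x K matrix of mask diagonals
#' @export
setGeneric("maskMatrix", function(object) standardGeneric("maskMatrix"))
setMethod("maskMatrix", "MaskSet", function(object) object@masks)

#' Signal dimensions stored in an object
#' @param object a \code{MaskSet} or \code{Intensities}
#' @export
setGeneric("signalDim", function(object) standardGeneric("signalDim"))
setMethod("signalDim", "MaskSet", function(object) object@dim)
setMethod("signalDim", "Intensities", function(object) object@dim)

#' @describeIn Intensities-class the N x K observation matrix
#' @param object an \code{Intensities}
#' @export
setGeneric("intensityMatrix", function(object) standardGeneric("intensityMatrix"))
setMethod("intensityMatrix", "Intensities", function(object) object@Y)

#' @describeIn Intensities-class nominal SNR (dB) of the observations
#' @export
setGeneric("snrDb", function(object) standardGeneric("snrDb"))
setMethod("snrDb", "Intensities", function(object) object@snrDb)

#' @describeIn RecoveryResult-class the recovered signal
#' @param object a \code{RecoveryResult}
#' @export
setGeneric("estimate", function(object) standardGeneric("estimate"))
setMethod("estimate", "RecoveryResult", function(object) object@xhat)

#' @describeIn RecoveryResult-class per-iteration normalized error trace
#' @export
setGeneric("errTrace", function(object) standardGeneric("errTrace"))
setMethod("errTrace", "RecoveryResult", function(object) object@errTrace)

#' @describeIn RecoveryResult-class number of outer iterations used
#' @export
setGeneric("iterations", function(object) standardGeneric("iterations"))
setMethod("iterations", "RecoveryResult", function(object) object@nIters)

#' @describeIn RecoveryResult-class did the stopping rule fire?
#' @export
setGeneric("hasConverged", function(object) standardGeneric("hasConverged"))
setMethod("hasConverged", "RecoveryResult", function(object) object@converged)
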
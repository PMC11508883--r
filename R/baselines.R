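#' Baseline solver configuration
#'
#' Defaults follow the cited methods' published constants where stated;
#' quantities the original descriptions leave open (the ADMM penalty of
#' the split-ADMM baseline, the momentum and reweighting constants of
#' MRTAF) are exposed here with documented defaults, since their behavior
#' is known to be parameter-sensitive.
#'
#' @param method one of \code{"wf"}, \code{"twf"}, \code{"taf"},
#'   \code{"mrtaf"}, \code{"phasesplit"}.
#' @param maxIters iteration cap.
#' @param step gradient step size (mu). Defaults: WF ramps
#'   min(1 - exp(-t/330), 0.2); TWF 0.2; TAF/MRTAF 0.6.
#' @param twfAlphaY,twfAlphaLb,twfAlphaUb,twfAlphaH TWF truncation
#'   constants (defaults 3, 0.3, 5, 5).
#' @param tafGamma TAF truncation parameter (default 0.7): rows with
#'   |z_i| < psi_i / (1 + gamma) are dropped from the gradient.
#' @param momentum MRTAF momentum coefficient (default 0.3).
#' @param medianC MRTAF median-reweighting cutoff (default 3): residuals
#'   beyond medianC times the median absolute residual are down-weighted.
#' @param admmRho split-ADMM penalty, as a multiple of the measurement
#'   energy scale N K lambda^2 (default 1).
#' @param admmInner CG iterations per ADMM subproblem (default 50).
#' @param tol stopping tolerance on the relative iterate change.
#' @return a list of class \code{"BaselineConfig"}.
#' @export
baselineConfig <- function(method = c("wf", "twf", "taf", "mrtaf", "phasesplit"),
                           maxIters = 2500L, step = NULL,
                           twfAlphaY = 3, twfAlphaLb = 0.3, twfAlphaUb = 5,
                           twfAlphaH = 5, tafGamma = 0.7, momentum = 0.3,
                           medianC = 3, admmRho = 1, admmInner = 50L,
                           tol = 1e-15) {
  method <- match.arg(method)
  stopifnot(maxIters >= 1, admmRho > 0)
  if (is.null(step))
    step <- switch(method, wf = 0.2, twf = 0.2, taf = 0.6, mrtaf = 0.6,
                   phasesplit = NA_real_)
  structure(list(method = method, maxIters = as.integer(maxIters),
                 step = step, twfAlphaY = twfAlphaY, twfAlphaLb = twfAlphaLb,
                 twfAlphaUb = twfAlphaUb, twfAlphaH = twfAlphaH,
                 tafGamma = tafGamma, momentum = momentum, medianC = medianC,
                 admmRho = admmRho, admmInner = as.integer(admmInner),
                 tol = tol),
            class = "BaselineConfig")
}

#' Run a comparison solver
#'
#' Reference implementations of the gradient-descent (WF, TWF, TAF, MRTAF)
#' and split-ADMM (PhaseSplit-style) phase-retrieval methods, rebuilt from
#' their published descriptions with default constants, for qualitative
#' comparison against [phaseRetrieve()]. All iterations are matrix-free
#' through the same FFT operators as the main solver. The TAF family
#' consumes plain (non-squared) magnitudes; \code{y} always carries squared
#' magnitudes and the square root is taken internally, unless
#' \code{inputIsMagnitude} signals that the Y slot already holds noisy
#' magnitudes (the convention used when comparing methods at a matched
#' SNR).
#'
#' @param config a [baselineConfig()] (or a method name, for defaults).
#' @param y an [Intensities-class].
#' @param masks the matching [MaskSet-class].
#' @param init nonzero starting signal.
#' @param groundTruth optional truth; records the per-iteration error.
#' @param inputIsMagnitude if TRUE, \code{y}'s matrix holds magnitudes,
#'   not squared magnitudes (TAF-family noisy experiments).
#' @return a [RecoveryResult-class].
#' @export
runBaseline <- function(config, y, masks, init, groundTruth = NULL,
                        inputIsMagnitude = FALSE) {
  if (is.character(config)) config <- baselineConfig(config)
  if (!inherits(config, "BaselineConfig")) stop("unknown method id")
  s <- .check_signal(init, "init")
  .match_dims(s, masks)
  Y <- intensityMatrix(y)
  if (inputIsMagnitude) {
    psi <- Y
    Y <- Y^2
  } else {
    psi <- sqrt(pmax(Y, 0))
  }
  truth <- if (is.null(groundTruth)) NULL else as.vector(groundTruth)
  res <- switch(config$method,
    wf = .grad_flow(config, Y, psi, masks, s$values, truth),
    twf = .grad_flow(config, Y, psi, masks, s$values, truth),
    taf = .grad_flow(config, Y, psi, masks, s$values, truth),
    mrtaf = .grad_flow(config, Y, psi, masks, s$values, truth),
    phasesplit = .split_admm(config, Y, masks, s$values, truth))
  new("RecoveryResult",
      xhat = .restore_layout(res$v, signalDim(masks)),
      errTrace = res$err, deltaTrace = res$delta,
      nIters = res$n, converged = res$converged,
      method = config$method, init = "user")
}

# Shared gradient-flow loop. Each method maps the current residuals to a
# coefficient matrix r; the gradient is (1/m) sum_ij r_ij H_ij v, i.e. one
# adjoint application anchored at v.
.grad_flow <- function(config, Y, psi, masks, v, truth) {
  m <- length(Y)
  n0sq <- sum(v^2)
  xnorm <- if (is.null(truth)) NA_real_ else sqrt(sum(truth^2))
  err <- delta <- numeric(0)
  v_prev <- v
  converged <- FALSE
  d <- signalDim(masks)
  t_final <- config$maxIters
  for (t in seq_len(config$maxIters)) {
    op <- bilinearOperator(.restore_layout(v, d), masks)
    B <- Re(op@spectra * Conj(op@spectra))  # |z_v|^2, N x K
    r <- switch(config$method,
      wf = B - Y,
      twf = {
        az <- sqrt(B)
        nv <- sqrt(sum(v^2))
        resid <- B - Y
        e1 <- az >= config$twfAlphaLb * nv & az <= config$twfAlphaUb * nv
        e2 <- abs(resid) <= config$twfAlphaH * mean(abs(resid)) * az / nv
        2 * resid / pmax(B, 1e-300) * (e1 & e2)
      },
      taf = {
        az <- sqrt(B)
        keep <- az >= psi / (1 + config$tafGamma)
        (1 - psi / pmax(az, 1e-300)) * keep
      },
      mrtaf = {
        az <- sqrt(B)
        keep <- az >= psi / (1 + config$tafGamma)
        resid <- abs(az - psi)
        md <- stats::median(resid)
        w <- if (md > 0) pmin(1, config$medianC * md / pmax(resid, 1e-300)) else 1
        (1 - psi / pmax(az, 1e-300)) * keep * w
      })
    g <- applyAdjoint(op, r) / m
    # WF normalizes its step by the squared norm of the starting point
    mu <- if (config$method == "wf")
      min(1 - exp(-t / 330), config$step) / n0sq else config$step
    v_new <- if (config$method == "mrtaf")
      v - mu * g + config$momentum * (v - v_prev)
    else v - mu * g
    if (!all(is.finite(v_new))) stop("baseline iteration diverged to non-finite values")
    dd <- sqrt(sum((v_new - v)^2)) / max(sqrt(sum(v_new^2)), 1e-300)
    v_prev <- v
    v <- v_new
    delta <- c(delta, dd)
    if (!is.null(truth))
      err <- c(err, min(sqrt(sum((v - truth)^2)), sqrt(sum((v + truth)^2))) / xnorm)
    if (dd < config$tol) { converged <- TRUE; t_final <- t; break }
    t_final <- t
  }
  list(v = v, err = err, delta = delta, n = as.integer(t_final),
       converged = converged)
}

# Split-variable ADMM: the same bilinear factorization as the main solver,
# but equality of the split variables is driven by an augmented-Lagrangian
# penalty and a dual ascent step instead of the fusing average.
.split_admm <- function(config, Y, masks, a, truth) {
  N <- nrow(Y); K <- ncol(Y)
  rho <- config$admmRho * sum(Y) / length(Y) * N * K
  xnorm <- if (is.null(truth)) NA_real_ else sqrt(sum(truth^2))
  b <- a
  u <- numeric(N)
  err <- delta <- numeric(0)
  converged <- FALSE
  d <- signalDim(masks)
  hw <- .cpp_dims(d)
  t_final <- config$maxIters
  # regularized CG: (H'H + rho/2 I) z = rhs, matrix-free
  reg_cg <- function(op, rhs, x0) {
    x <- x0
    r <- rhs - (applyAdjoint(op, applyOperator(op, .restore_layout(x, d))) + rho / 2 * x)
    p <- r
    rs <- sum(r^2)
    rhsn <- sqrt(sum(rhs^2))
    if (rhsn == 0) return(numeric(length(rhs)))
    for (it in seq_len(config$admmInner)) {
      if (sqrt(rs) <= 1e-12 * rhsn) break
      Ap <- applyAdjoint(op, applyOperator(op, .restore_layout(p, d))) + rho / 2 * p
      pAp <- sum(p * Ap)
      if (pAp <= 0) break
      al <- rs / pAp
      x <- x + al * p
      r <- r - al * Ap
      rs2 <- sum(r^2)
      p <- r + (rs2 / rs) * p
      rs <- rs2
    }
    x
  }
  for (t in seq_len(config$maxIters)) {
    a_old <- a
    opA <- bilinearOperator(.restore_layout(a, d), masks)
    b <- reg_cg(opA, applyAdjoint(opA, Y) + rho / 2 * (a - u), b)
    opB <- bilinearOperator(.restore_layout(b, d), masks)
    a <- reg_cg(opB, applyAdjoint(opB, Y) + rho / 2 * (b + u), a)
    u <- u + b - a
    dd <- sqrt(sum((a - a_old)^2)) / max(sqrt(sum(a^2)), 1e-300)
    delta <- c(delta, dd)
    if (!is.null(truth))
      err <- c(err, min(sqrt(sum((a - truth)^2)), sqrt(sum((a + truth)^2))) / xnorm)
    if (dd < config$tol) { converged <- TRUE; t_final <- t; break }
    t_final <- t
  }
  list(v = a, err = err, delta = delta, n = as.integer(t_final),
       converged = converged)
}
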
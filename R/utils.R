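# Internal helpers: layout handling, DFTs on either layout, seed derivation.

# Normalize a signal to (values, dim): dim has length 1 for vectors,
# length 2 for images.
.as_signal <- function(x) {
  if (is.matrix(x)) {
    list(values = as.vector(x), dim = as.integer(dim(x)))
  } else {
    list(values = as.numeric(x), dim = length(x))
  }
}

.check_signal <- function(x, what = "signal") {
  s <- .as_signal(x)
  if (length(s$values) < 2L) stop(what, " must have length N >= 2")
  if (!all(is.finite(s$values))) stop(what, " must have finite entries")
  s
}

# Reshape a plain vector back to the stored layout.
.restore_layout <- function(v, dim) {
  if (length(dim) == 2L) matrix(v, dim[1L], dim[2L]) else v
}

# Unnormalized forward DFT on a vector holding either layout.
.layout_fft <- function(v, dim) {
  if (length(dim) == 2L) as.vector(stats::fft(matrix(v, dim[1L], dim[2L])))
  else stats::fft(v)
}

# Conjugate-transpose DFT F^H u (the unnormalized inverse).
.layout_fft_h <- function(u, dim) {
  if (length(dim) == 2L)
    as.vector(stats::fft(matrix(u, dim[1L], dim[2L]), inverse = TRUE))
  else stats::fft(u, inverse = TRUE)
}

# K spectra z_j = DFT(w_j . v) as a complex N x K matrix.
.masked_spectra <- function(v, masks) {
  m <- maskMatrix(masks)
  d <- signalDim(masks)
  vapply(seq_len(ncol(m)),
         function(j) .layout_fft(m[, j] * v, d),
         complex(nrow(m)))
}

.match_dims <- function(sig, obj, what = "masks") {
  if (length(sig$values) != prod(signalDim(obj)))
    stop("size mismatch: signal has N = ", length(sig$values),
         " but ", what, " expect N = ", prod(signalDim(obj)))
}

# Deterministic per-trial seed derivation. Roles keep the signal, mask and
# noise streams of one trial independent; everything stays below 2^31 - 1.
.derive_seed <- function(master, trial, role = 0L) {
  m <- as.numeric(master) %% 2147483647
  v <- (m * 48271 + as.numeric(trial) * 7919 + as.numeric(role) * 104729 + 12345) %%
    2147483647
  as.integer(v) + 1L
}

.cpp_dims <- function(dim) {
  if (length(dim) == 2L) c(dim[1L], dim[2L]) else c(dim[1L], 1L)
}
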
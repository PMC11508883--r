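# Dense-matrix oracles, independent of the package's FFT-based operators.
# Everything here is built from explicitly constructed DFT matrices and
# N x N sampling matrices H_ij = Re(conj(h) h^T), h = w_j . f_i, and is
# only usable at tiny N.

# Unnormalized DFT matrix with rows f_i^T (f_i[k] = exp(-2*pi*1i*i*k/N)).
dft_matrix <- function(N) {
  idx <- 0:(N - 1)
  outer(idx, idx, function(i, k) exp(-2i * pi * i * k / N))
}

# 2-D DFT on column-major vectorized H x W images:
# vec(F_H X t(F_W)) = kronecker(F_W, F_H) vec(X).
dense_dft_for <- function(dim) {
  if (length(dim) == 2L) kronecker(dft_matrix(dim[2L]), dft_matrix(dim[1L]))
  else dft_matrix(dim)
}

# The sampling vector h_{ij} = w_j . f_i (elementwise), as a column.
dense_h <- function(masks, i, j) {
  Fm <- dense_dft_for(signalDim(masks))
  maskMatrix(masks)[, j] * Fm[i, ]
}

# H_ij = Re(conj(h) h^T), real N x N.
dense_Hij <- function(masks, i, j) {
  h <- dense_h(masks, i, j)
  Re(Conj(h) %*% t(h))
}

# Stacked KN x N matrix H_a with row i + N(j-1) equal to a^T H_ij.
dense_Ha <- function(anchor, masks) {
  N <- prod(signalDim(masks))
  K <- nMasks(masks)
  a <- as.vector(anchor)
  out <- matrix(0, N * K, N)
  for (j in seq_len(K)) for (i in seq_len(N)) {
    out[i + N * (j - 1L), ] <- as.vector(a %*% dense_Hij(masks, i, j))
  }
  out
}

# Dense forward intensities |f_i^T W_j x|^2 as an N x K matrix.
dense_forward <- function(x, masks) {
  Fm <- dense_dft_for(signalDim(masks))
  m <- maskMatrix(masks)
  vapply(seq_len(ncol(m)),
         function(j) Mod(Fm %*% (m[, j] * as.vector(x)))^2,
         numeric(nrow(m)))
}

rel_err <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.xmin)
}

# A unit-norm random direction of length n.
rand_dir <- function(n, seed) {
  set.seed(seed)
  e <- rnorm(n)
  e / sqrt(sum(e^2))
}
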
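#' Read a grayscale image as a signal in [0, 1]
#'
#' PNG and TIFF are supported; RGB(A) images are averaged to grayscale.
#'
#' @param path image file.
#' @return an H x W matrix in [0, 1].
#' @export
readSignalImage <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3L, dim(img)[3L]), drop = FALSE], c(1, 2), mean)
  img
}

#' @rdname readSignalImage
#' @param x matrix in [0, 1] (values are clipped).
#' @export
writeSignalImage <- function(x, path) {
  x <- pmin(pmax(x, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = , tiff = tiff::writeTIFF(x, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Serialize observations and masks to text files
#'
#' Writes three files next to \code{base}: \code{<base>_Y.tsv} (the N x K
#' observation matrix), \code{<base>_masks.tsv} (real and imaginary parts
#' of the mask diagonals, 2K columns) and \code{<base>.json} (dim, K,
#' snr_db, seed, alphabet). Text formats keep runs portable and diffable.
#'
#' @param obs an [Intensities-class].
#' @param masks the matching [MaskSet-class].
#' @param base path prefix.
#' @return \code{base}, invisibly.
#' @export
saveObservations <- function(obs, masks, base) {
  Y <- intensityMatrix(obs)
  m <- maskMatrix(masks)
  utils::write.table(Y, paste0(base, "_Y.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  mm <- cbind(Re(m), Im(m))
  utils::write.table(mm, paste0(base, "_masks.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(dim = signalDim(obs), K = nMasks(masks),
               snr_db = if (is.finite(snrDb(obs))) snrDb(obs) else "Inf",
               seed = masks@seed, alphabet = masks@alphabet)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE)
  invisible(base)
}

#' @rdname saveObservations
#' @return \code{loadObservations}: list with elements \code{obs}
#'   ([Intensities-class]) and \code{masks} ([MaskSet-class]).
#' @export
loadObservations <- function(base) {
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  dim <- as.integer(meta$dim)
  K <- as.integer(meta$K)
  Y <- as.matrix(utils::read.table(paste0(base, "_Y.tsv"), sep = "\t"))
  dimnames(Y) <- NULL
  mm <- as.matrix(utils::read.table(paste0(base, "_masks.tsv"), sep = "\t"))
  m <- mm[, seq_len(K), drop = FALSE] + 1i * mm[, K + seq_len(K), drop = FALSE]
  dimnames(m) <- NULL
  snr <- if (identical(meta$snr_db, "Inf")) Inf else as.numeric(meta$snr_db)
  list(obs = new("Intensities", Y = Y, snrDb = snr, dim = dim),
       masks = new("MaskSet", masks = m, dim = dim,
                   alphabet = meta$alphabet, seed = as.integer(meta$seed)))
}
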
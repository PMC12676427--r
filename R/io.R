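# Image IO on the package's fixed conventions: intensities are integers on
# [0, 4095] stored in 16-bit grayscale TIFF (lossless round-trip); masks are
# 8-bit 0/255 PNG.

#' Write a 12-bit-scale intensity matrix as 16-bit grayscale TIFF
#' @param image Integer-valued matrix on \[0, 65535\].
#' @param path Output path.
#' @export
write_gray16 <- function(image, path) {
  ok <- tryCatch({
    tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L)
    TRUE
  }, error = function(e) {
    stop("failed to write image ", path, ": ", conditionMessage(e))
  })
  invisible(ok)
}

#' Read a 16-bit grayscale TIFF back to an integer intensity matrix
#' @param path Input path.
#' @return Integer matrix on the stored scale.
#' @export
read_gray16 <- function(path) {
  if (!file.exists(path)) stop("no such image file: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3) x <- x[, , 1]
  storage.mode(x) <- "double"
  x
}

#' Write a binary mask as 8-bit 0/255 PNG
#' @param mask Logical matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  tryCatch(png::writePNG(as_binary(mask) * 1.0, path),
           error = function(e) stop("failed to write mask ", path, ": ",
                                    conditionMessage(e)))
  invisible(TRUE)
}

#' Read a 0/255 PNG mask as a logical matrix
#' @param path Input path.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such mask file: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x > 0.5
}
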
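# Conventional signal-processing spot detectors: Gaussian blur difference
# (bright residual after subtracting a smoothed image) and white top-hat
# (residual after a grayscale opening), each averaged over several kernel
# sizes so that deposits of different diameters respond without per-image
# parameter tuning.

# 1D Gaussian convolution as a dense banded matrix with symmetric (reflect)
# boundary handling; blur is then K_rows %*% X %*% t(K_cols). Cached per
# (n, sigma) since the matrix depends only on the geometry.
blur_matrix_1d <- function(n, sigma) {
  cache_get_or(sprintf("blur_%d_%g", n, sigma), function() {
    r <- max(1L, ceiling(4 * sigma))
    w <- exp(-((-r:r)^2) / (2 * sigma^2))
    w <- w / sum(w)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      # symmetric reflection, iterated so kernels wider than the image fold
      # back correctly: ... 2 1 | 1 2 ... n-1 n | n n-1 ...
      j <- reflect_index(i + (-r:r), n)
      for (k in seq_along(j)) K[i, j[k]] <- K[i, j[k]] + w[k]
    }
    K
  })
}

#' Gaussian blur with reflective boundaries
#' @param image Numeric matrix.
#' @param sigma Gaussian standard deviation in pixels.
#' @return Blurred matrix of the same shape.
#' @export
gaussian_blur <- function(image, sigma) {
  stopifnot(sigma > 0)
  Kr <- blur_matrix_1d(nrow(image), sigma)
  Kc <- blur_matrix_1d(ncol(image), sigma)
  Kr %*% image %*% t(Kc)
}

# Min-max normalize a non-negative response map to [0, 1]. A map whose
# dynamic range is numerically zero (below 1e-8 intensity units, i.e. pure
# floating-point residue on the 12-bit scale) stays zero, so flat images
# produce no signal.
minmax01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi - lo <= 1e-8) return(matrix(0, nrow(x), ncol(x)))
  (x - lo) / (hi - lo)
}

#' Gaussian-blur-difference detection map
#'
#' For each scale, takes the positive part of (image - blur) -- bright
#' deposits stand out above the smoothed tissue; negative residuals carry no
#' calcification evidence -- min-max normalizes it to \[0, 1\], and averages
#' the per-scale maps. One threshold then works across scales.
#'
#' @param image Numeric intensity matrix.
#' @param sigmas Strictly increasing positive Gaussian sigmas
#'   (default `c(1, 2, 4, 8)`).
#' @return Probability-like matrix in \[0, 1\] of the same shape.
#' @export
gbd_map <- function(image, sigmas = c(1, 2, 4, 8)) {
  check_kernel_sizes(sigmas)
  maps <- lapply(sigmas, function(s) {
    minmax01(pmax(image - gaussian_blur(image, s), 0))
  })
  Reduce(`+`, maps) / length(maps)
}

# Grayscale opening by a discrete Euclidean disk, with reflective padding
# wide enough for both the erosion and the dilation pass. EBImage clamps
# grayscale images to [0, 1], so intensities are mapped there and back
# (min/max filters commute with increasing affine maps).
gray_opening <- function(image, radius) {
  pad <- 2L * ceiling(radius) + 1L
  p <- pad_reflect(image, pad)
  lo <- min(p); hi <- max(p)
  if (hi - lo <= 0) return(image)
  o <- EBImage::opening((p - lo) / (hi - lo), disk_kernel(radius))
  o <- lo + (hi - lo) * matrix(as.numeric(o), nrow(p), ncol(p))
  unpad(o, pad, nrow(image), ncol(image))
}

#' White top-hat detection map
#'
#' For each disk radius, computes the white top-hat transform
#' (image minus its grayscale opening), which responds to bright structures
#' narrower than the disk; min-max normalizes each map and averages over
#' radii.
#'
#' @param image Numeric intensity matrix.
#' @param radii Strictly increasing positive disk radii
#'   (default `c(2, 4, 8, 16)`).
#' @return Probability-like matrix in \[0, 1\] of the same shape.
#' @export
tht_map <- function(image, radii = c(2, 4, 8, 16)) {
  check_kernel_sizes(radii)
  maps <- lapply(radii, function(r) {
    minmax01(pmax(image - gray_opening(image, r), 0))
  })
  Reduce(`+`, maps) / length(maps)
}

check_kernel_sizes <- function(sizes) {
  if (length(sizes) == 0) stop("kernel size list must be non-empty")
  if (any(sizes <= 0)) stop("kernel sizes must be strictly positive")
  if (length(sizes) > 1 && any(diff(sizes) <= 0)) {
    stop("kernel sizes must be strictly increasing")
  }
  invisible(TRUE)
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is positive iff its value strictly exceeds the threshold, so a
#' threshold of 1 always yields an empty mask and ties break negative.
#'
#' @param map Matrix in \[0, 1\].
#' @param threshold Scalar in \[0, 1\].
#' @param source Optional matrix whose shape the map must match.
#' @return Logical matrix.
#' @export
binarize <- function(map, threshold, source = NULL) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!is.null(source)) assert_same_shape(map, source, "map and source image")
  matrix(map > threshold, nrow(map), ncol(map))
}
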
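#' @import methods
#' @importFrom stats rnorm runif sd wilcox.test
#' @importFrom utils read.csv write.csv
NULL

# Intensity scale: 12-bit DICOM-style units.
INTENSITY_MAX <- 4095

clip_intensity <- function(x) pmin(pmax(x, 0), INTENSITY_MAX)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(index) * 7919) %% 2147483647L)
}

# Offsets (drow, dcol) of the discrete Euclidean disk of given radius:
# all integer offsets with drow^2 + dcol^2 <= radius^2.
disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}

# 0/1 kernel matrix of the discrete Euclidean disk (odd-sized square).
disk_kernel <- function(radius) {
  r <- max(1L, floor(radius))
  d <- outer((-r:r)^2, (-r:r)^2, "+")
  k <- matrix(0, 2 * r + 1, 2 * r + 1)
  k[d <= radius^2] <- 1
  k
}

# Paint Euclidean disks of the given radii at the given centers into a
# logical matrix, clipped to the image bounds.
paint_disks <- function(mask, centers, radii) {
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(centers))) {
    off <- disk_offsets(radii[i])
    rr <- centers[i, 1] + off[, 1]
    cc <- centers[i, 2] + off[, 2]
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}

# Binary dilation by a discrete Euclidean disk. radius 0 is the identity.
dilate_disk <- function(mask, radius) {
  stopifnot(is.matrix(mask))
  if (radius <= 0) return(mask)
  out <- EBImage::dilate(mask * 1, disk_kernel(radius))
  matrix(as.numeric(out) > 0.5, nrow(mask), ncol(mask))
}

# Reflective (symmetric) padding of a matrix by `pad` pixels on every side;
# reflection iterates, so the padding may be wider than the image.
reflect_index <- function(i, n) {
  m <- (i - 1) %% (2 * n)
  ifelse(m < n, m + 1, 2 * n - m)
}

pad_reflect <- function(x, pad) {
  if (pad <= 0) return(x)
  nr <- nrow(x); nc <- ncol(x)
  x[reflect_index((1 - pad):(nr + pad), nr),
    reflect_index((1 - pad):(nc + pad), nc), drop = FALSE]
}

unpad <- function(x, pad, nr, nc) x[pad + (1:nr), pad + (1:nc), drop = FALSE]

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s must have identical dimensions (%s vs %s)",
                 what, paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  }
  invisible(TRUE)
}

as_binary <- function(x) {
  if (is.logical(x)) return(matrix(x, nrow(x), ncol(x)))
  matrix(x > 0.5, nrow(x), ncol(x))
}

# Session cache for shape-dependent operators (blur matrices, Laplacians).
.calcrefine_cache <- new.env(parent = emptyenv())

cache_get_or <- function(key, make) {
  if (!exists(key, envir = .calcrefine_cache, inherits = FALSE)) {
    assign(key, make(), envir = .calcrefine_cache)
  }
  get(key, envir = .calcrefine_cache, inherits = FALSE)
}
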
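# Mask-guided inpainting: replace the pixels under a mask with "virtual
# normal" values interpolated from the surrounding context, leaving every
# unmasked pixel bit-identical. The default backends solve the harmonic
# (Laplace) or biharmonic equation on the masked set with boundary data from
# the unmasked neighbours -- deterministic, training-free, and exact for
# affine images. A small learned backend (a trained local diffusion kernel)
# implements the unsupervised masked-reconstruction training scheme.

# 5-point graph Laplacian of the rows x cols grid with Neumann boundaries
# (degree = number of in-grid neighbours); column-major vertex indexing.
# Depends only on the shape, so it is cached, as is its square (the
# discrete biharmonic operator).
grid_laplacian <- function(rows, cols) {
  cache_get_or(sprintf("lap_%d_%d", rows, cols), function() {
    n <- rows * cols
    idx <- matrix(seq_len(n), rows, cols)
    from <- c(idx[-rows, ], idx[, -cols])
    to <- c(idx[-1, ], idx[, -1])
    A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from), x = 1,
                              dims = c(n, n))
    deg <- Matrix::rowSums(A)
    Matrix::Diagonal(n, deg) - A
  })
}

grid_biharmonic <- function(rows, cols) {
  cache_get_or(sprintf("bih_%d_%d", rows, cols), function() {
    L <- grid_laplacian(rows, cols)
    L %*% L
  })
}

solve_pde_fill <- function(image, mask, op, solver_tol) {
  m <- which(mask)
  x0 <- as.numeric(image)
  x0[m] <- 0
  rhs <- -(op %*% x0)[m]
  A <- Matrix::forceSymmetric(op[m, m, drop = FALSE])
  u <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(as.numeric(A %*% u) - rhs))
  scale <- max(1, max(abs(rhs)))
  if (resid / scale > solver_tol) {
    stop(sprintf("inpainting solver did not reach tolerance: residual %.3g", resid))
  }
  out <- image
  out[m] <- clip_intensity(u)
  out
}

#' Inpaint masked pixels with virtual calcification-free values
#'
#' Fills the pixels under `mask` by solving the harmonic (`"harmonic"`,
#' Laplace equation) or biharmonic (`"biharmonic"`, the default; smoother,
#' matches gradients at the mask boundary) equation with boundary values
#' taken from the unmasked pixels, or by a trained local-filter backend
#' (`"learned"`, see [train_masked_autoencoder()]). Pixels outside the mask
#' are returned bit-identical to the input for every backend; inpainted
#' values are clipped to \[0, 4095\]. The linear systems are solved by
#' sparse direct factorisation and the residual is checked against
#' `solver_tol`.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of pixels to replace; must not cover the whole
#'   image (some context must remain).
#' @param backend `"biharmonic"`, `"harmonic"`, or `"learned"`.
#' @param model A trained model from [train_masked_autoencoder()], required
#'   for the learned backend.
#' @param solver_tol Residual tolerance of the fill (default 1e-6).
#' @return Matrix of the same shape; the virtual-normal image.
#' @export
inpaint <- function(image, mask, backend = c("biharmonic", "harmonic", "learned"),
                    model = NULL, solver_tol = 1e-6) {
  backend <- match.arg(backend)
  mask <- as_binary(mask)
  assert_same_shape(image, mask, "image and mask")
  if (!any(mask)) return(image)
  if (all(mask)) stop("no context: mask covers the entire image")
  rows <- nrow(image); cols <- ncol(image)
  switch(backend,
    harmonic = solve_pde_fill(image, mask, grid_laplacian(rows, cols), solver_tol),
    biharmonic = solve_pde_fill(image, mask, grid_biharmonic(rows, cols), solver_tol),
    learned = {
      if (is.null(model) || !inherits(model, "learned_inpainter")) {
        stop("learned backend requires a model from train_masked_autoencoder()")
      }
      if (!isTRUE(model$trained)) stop("refusing to inpaint with an untrained model")
      learned_fill(image, mask, model, solver_tol)
    }
  )
}

#' Seeded random box masks
#'
#' Draws `box_size` x `box_size` boxes at seeded random positions on the
#' box-aligned tiling grid (so full coverage is reachable) until the masked
#' fraction reaches `coverage`. Boxes at the right/bottom edge are shifted
#' inward to stay inside the image, so they may overlap their neighbours.
#'
#' @param shape Integer `(rows, cols)`.
#' @param box_size Box side length in pixels.
#' @param coverage Target masked fraction in (0, 1].
#' @param seed Integer seed.
#' @return Logical mask.
#' @export
sample_boxes <- function(shape, box_size, coverage, seed = 1L) {
  rows <- shape[1]; cols <- shape[2]
  stopifnot(box_size >= 1, coverage > 0, coverage <= 1)
  if (box_size > rows && box_size > cols) {
    stop("box_size exceeds both image dimensions")
  }
  cells <- box_grid(rows, cols, box_size)
  mask <- matrix(FALSE, rows, cols)
  total <- rows * cols
  with_seed(seed, {
    guard <- 0L
    while (sum(mask) / total < coverage && guard < 1000L * nrow(cells)) {
      guard <- guard + 1L
      k <- sample.int(nrow(cells), 1)
      mask[cells[k, 1]:cells[k, 2], cells[k, 3]:cells[k, 4]] <- TRUE
    }
  })
  mask
}

# Box-aligned tiling of the image: rows of (r0, r1, c0, c1). Edge cells are
# shifted inward so every cell is exactly box-sized (dims permitting).
box_grid <- function(rows, cols, box) {
  br <- min(box, rows); bc <- min(box, cols)
  rstart <- unique(pmin(seq(1L, rows, by = br), rows - br + 1L))
  cstart <- unique(pmin(seq(1L, cols, by = bc), cols - bc + 1L))
  g <- expand.grid(r0 = rstart, c0 = cstart)
  cbind(g$r0, g$r0 + br - 1L, g$c0, g$c0 + bc - 1L)
}

#' Train the masked-reconstruction inpainting backend
#'
#' Implements the unsupervised training scheme behind learned inpainting:
#' random box masks are applied to calcification-free patches and the model
#' is trained to reproduce the masked pixels from their surroundings. The
#' model itself is deliberately small -- a learned 8-neighbour diffusion
#' kernel (non-negative weights summing to one, fitted by projected
#' full-batch gradient descent on the masked-pixel reconstruction error) --
#' so training is seeded, deterministic, and CPU-cheap. At inference the
#' kernel defines a linear system analogous to the harmonic fill but with
#' learned, anisotropy-aware weights.
#'
#' @param normal_patches List of intensity matrices containing no
#'   calcification pixels.
#' @param box_size,coverage Mask sampler settings used to draw the training
#'   masks (see [sample_boxes()]).
#' @param epochs Number of gradient steps; 0 returns an explicitly untrained
#'   model that [inpaint()] refuses.
#' @param seed Integer seed.
#' @param gt_masks Optional list of ground-truth masks aligned with
#'   `normal_patches`; any positive pixel aborts training.
#' @return Object of class `learned_inpainter` with fields `weights`
#'   (8-vector over the neighbour offsets), `final_loss` (RMSE on the
#'   training masked pixels, intensity units), `trained`, `seed`.
#' @export
train_masked_autoencoder <- function(normal_patches, box_size = 8, coverage = 0.25,
                                     epochs = 200, seed = 1L, gt_masks = NULL) {
  stopifnot(length(normal_patches) > 0, epochs >= 0)
  if (!is.null(gt_masks)) {
    for (i in seq_along(normal_patches)) {
      if (any(as_binary(gt_masks[[i]]))) {
        stop("abnormal pixels in training data: patch ", i,
             " intersects the provided ground-truth mask")
      }
    }
  }
  offs <- neighbour_offsets8()
  model <- structure(list(weights = rep(1 / 8, 8), offsets = offs,
                          trained = FALSE, final_loss = NA_real_, seed = seed),
                     class = "learned_inpainter")
  if (epochs == 0) return(model)

  # assemble the training design: masked pixels with a full 8-neighbourhood
  X <- list(); y <- list()
  for (i in seq_along(normal_patches)) {
    p <- normal_patches[[i]]
    m <- sample_boxes(dim(p), box_size, coverage, seed = derive_seed(seed, i))
    m[c(1, nrow(p)), ] <- FALSE
    m[, c(1, ncol(p))] <- FALSE
    pix <- which(m)
    if (!length(pix)) next
    nr <- nrow(p)
    rr <- (pix - 1) %% nr + 1; cc <- (pix - 1) %/% nr + 1
    feats <- sapply(seq_len(8), function(k) {
      p[cbind(rr + offs[k, 1], cc + offs[k, 2])]
    })
    X[[length(X) + 1]] <- matrix(feats, ncol = 8)
    y[[length(y) + 1]] <- p[pix]
  }
  X <- do.call(rbind, X) / INTENSITY_MAX
  y <- do.call(c, y) / INTENSITY_MAX
  if (is.null(X) || nrow(X) < 8) stop("not enough training pixels")

  w <- rep(1 / 8, 8)
  lr <- 0.05
  n <- nrow(X)
  for (e in seq_len(epochs)) {
    r <- y - as.numeric(X %*% w)
    grad <- -2 * as.numeric(crossprod(X, r)) / n
    w <- w - lr * grad
    w <- pmax(w, 0)                 # projection: non-negative, sum to one,
    w <- w / sum(w)                 # so constants are reproduced exactly
  }
  rmse <- sqrt(mean((y - as.numeric(X %*% w))^2)) * INTENSITY_MAX
  model$weights <- w
  model$trained <- TRUE
  model$final_loss <- rmse
  model
}

neighbour_offsets8 <- function() {
  g <- expand.grid(dr = -1:1, dc = -1:1)
  as.matrix(g[!(g$dr == 0 & g$dc == 0), ])
}

# Inference with the learned kernel: each masked pixel equals the learned
# weighted mean of its neighbours (weights renormalised over in-grid
# neighbours at the border); solve the induced sparse linear system and
# composite the solution into the mask only.
learned_fill <- function(image, mask, model, solver_tol) {
  rows <- nrow(image); cols <- ncol(image)
  n <- rows * cols
  offs <- model$offsets
  idx <- matrix(seq_len(n), rows, cols)
  ii <- jj <- xx <- list()
  for (k in seq_len(8)) {
    dr <- offs[k, 1]; dc <- offs[k, 2]
    rs <- max(1, 1 - dr):min(rows, rows - dr)
    cs <- max(1, 1 - dc):min(cols, cols - dc)
    ii[[k]] <- as.numeric(idx[rs, cs])
    jj[[k]] <- as.numeric(idx[rs + dr, cs + dc])
    xx[[k]] <- rep(model$weights[k], length(rs) * length(cs))
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  rs <- Matrix::rowSums(W)
  W <- Matrix::Diagonal(n, 1 / rs) %*% W
  m <- which(mask)
  x0 <- as.numeric(image); x0[m] <- 0
  A <- Matrix::Diagonal(length(m)) - W[m, m, drop = FALSE]
  rhs <- (W %*% x0)[m]
  u <- as.numeric(Matrix::solve(A, rhs))
  resid <- max(abs(as.numeric(A %*% u) - rhs))
  if (resid / max(1, max(abs(rhs))) > solver_tol) {
    stop(sprintf("learned fill did not reach tolerance: residual %.3g", resid))
  }
  out <- image
  out[m] <- clip_intensity(u)
  out
}
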
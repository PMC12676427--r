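# Independent brute-force oracles, deliberately written as naive per-pixel
# loops so they share no code with the implementation they check.

# 4-connected labelling by repeated flood fill.
bf_label4 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nid <- 0L
  for (c0 in seq_len(ncol(mask))) for (r0 in seq_len(nrow(mask))) {
    if (!mask[r0, c0] || lab[r0, c0] > 0) next
    nid <- nid + 1L
    stack <- list(c(r0, c0))
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      r <- p[1]; c <- p[2]
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
      if (!mask[r, c] || lab[r, c] > 0) next
      lab[r, c] <- nid
      stack <- c(stack, list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1)))
    }
  }
  lab
}

# Per-object interior/exterior densities by pixel enumeration: the ring is
# every non-gt pixel within Euclidean distance ring_width of the component.
bf_object_features <- function(image, gt, ring_width = 5) {
  lab <- bf_label4(gt)
  n <- max(lab)
  out <- list()
  for (id in seq_len(n)) {
    comp <- which(lab == id, arr.ind = TRUE)
    ring_vals <- c()
    for (c in seq_len(ncol(image))) for (r in seq_len(nrow(image))) {
      if (gt[r, c]) next
      d2 <- min((comp[, 1] - r)^2 + (comp[, 2] - c)^2)
      if (d2 <= ring_width^2) ring_vals <- c(ring_vals, image[r, c])
    }
    ext <- mean(ring_vals)
    vals <- image[lab == id]
    out[[id]] <- data.frame(object_id = id, size_px = nrow(comp),
                            interior_density = mean(vals) - ext,
                            exterior_density = ext)
  }
  do.call(rbind, out)
}

# Direct 2D Gaussian convolution with symmetric reflection.
bf_gaussian_blur <- function(image, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w1 <- exp(-((-r:r)^2) / (2 * sigma^2)); w1 <- w1 / sum(w1)
  w2 <- outer(w1, w1)
  n <- nrow(image); m <- ncol(image)
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (c in seq_len(m)) for (r0 in seq_len(n)) {
    acc <- 0
    for (dc in -r:r) for (dr in -r:r) {
      acc <- acc + w2[dr + r + 1, dc + r + 1] *
        image[reflect(r0 + dr, n), reflect(c + dc, m)]
    }
    out[r0, c] <- acc
  }
  out
}

# Grayscale erosion / dilation / white top-hat by direct min/max over the
# disk neighbourhood, with symmetric reflection at the border.
bf_tophat <- function(image, radius) {
  n <- nrow(image); m <- ncol(image)
  reflect <- function(i, lim) {
    while (i < 1 || i > lim) {
      if (i < 1) i <- 1 - i
      if (i > lim) i <- 2 * lim + 1 - i
    }
    i
  }
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  neigh <- function(x, r, c, f) {
    v <- mapply(function(dr, dc) x[reflect(r + dr, n), reflect(c + dc, m)],
                offs$dr, offs$dc)
    f(v)
  }
  er <- matrix(0, n, m); di <- matrix(0, n, m)
  for (c in seq_len(m)) for (r in seq_len(n)) er[r, c] <- neigh(image, r, c, min)
  for (c in seq_len(m)) for (r in seq_len(n)) di[r, c] <- neigh(er, r, c, max)
  image - di
}

# Exact two-sided signed-rank p-value by enumerating every sign assignment.
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  ranks <- rank(abs(d))
  w_obs <- sum(ranks[d > 0])
  stats <- numeric(2^n)
  for (k in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(k))[1:n]
    stats[k + 1] <- sum(ranks[signs == 1])
  }
  p_hi <- mean(stats >= w_obs)
  p_lo <- mean(stats <= w_obs)
  min(1, 2 * min(p_hi, p_lo))
}

# Brute-force confusion recount by explicit pixel loop.
bf_confusion <- function(pred, gt, breast) {
  tp <- fp <- fn <- tn <- 0L
  for (c in seq_len(ncol(pred))) for (r in seq_len(nrow(pred))) {
    if (!breast[r, c]) next
    if (pred[r, c] && gt[r, c]) tp <- tp + 1L
    else if (pred[r, c]) fp <- fp + 1L
    else if (gt[r, c]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Small textured test phantom spec used across files; dots override the
# defaults below.
tiny_spec <- function(seed = 1, ...) {
  args <- modifyList(list(image_shape = c(96, 96), n_objects_range = c(1, 3),
                          dense_region_fraction = 0, seed = seed),
                     list(...))
  do.call(phantom_spec, args)
}
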
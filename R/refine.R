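# Stage-2 refinement: inpaint the Stage-1 candidate mask, subtract the
# virtual calcification-free image from the original, and keep only
# candidate pixels whose difference exceeds an absolute intensity threshold
# tau. Because the difference is measured in intensity units, the decision
# uses absolute calcification contrast -- the information a binary
# segmenter cannot see -- and the refined mask is a subset of the Stage-1
# mask by construction.

#' Refinement configuration
#'
#' @param tau Difference threshold in intensity units (default 50): a
#'   candidate pixel survives refinement only if the original exceeds its
#'   virtual calcification-free value by more than `tau`.
#' @param patch_size Side of the square patches used for full-field
#'   processing (default 512).
#' @param overlap Fractional overlap between neighbouring patches in
#'   \[0, 1) (default 0.5).
#' @param backend Inpainting backend id (see [inpaint()]).
#' @param model Optional trained model for the learned backend.
#' @return Object of class `refine_config`.
#' @export
refine_config <- function(tau = 50, patch_size = 512, overlap = 0.5,
                          backend = "biharmonic", model = NULL) {
  stopifnot(tau >= 0, overlap >= 0, overlap < 1, patch_size >= 64)
  structure(list(tau = tau, patch_size = as.integer(patch_size),
                 overlap = overlap, backend = backend, model = model),
            class = "refine_config")
}

#' Positive difference map between original and virtual-normal image
#'
#' Inside the mask, `max(original - virtual, 0)`: calcifications are
#' hyperintense, so only positive evidence counts. Outside the mask the map
#' is zero by construction.
#'
#' @param original,virtual Intensity matrices of identical shape.
#' @param mask Logical matrix delimiting where the virtual image was
#'   generated.
#' @return Non-negative matrix of the same shape.
#' @export
difference_map <- function(original, virtual, mask) {
  assert_same_shape(original, virtual, "original and virtual")
  mask <- as_binary(mask)
  assert_same_shape(original, mask, "image and mask")
  d <- pmax(original - virtual, 0)
  d[!mask] <- 0
  d
}

#' Refine a Stage-1 candidate mask by inpainting and differencing
#'
#' The core of the method: the Stage-1 mask is inpainted to a virtual
#' calcification-free image, and a candidate pixel is kept iff the original
#' exceeds the virtual value by more than `cfg$tau`. The result is always a
#' subset of the Stage-1 mask, so refinement can only remove false
#' positives, never activate new pixels.
#'
#' @param image Intensity matrix.
#' @param stage1_mask Logical candidate mask aligned with `image`.
#' @param cfg A [refine_config()].
#' @return Logical refined mask, subset of `stage1_mask`.
#' @export
refine_mask <- function(image, stage1_mask, cfg = refine_config()) {
  stage1_mask <- as_binary(stage1_mask)
  assert_same_shape(image, stage1_mask, "image and stage1_mask")
  if (!any(stage1_mask)) return(stage1_mask)
  virtual <- inpaint(image, stage1_mask, backend = cfg$backend, model = cfg$model)
  d <- difference_map(image, virtual, stage1_mask)
  (d > cfg$tau) & stage1_mask
}

#' Signal-processing refinement comparators
#'
#' The conventional alternative to generative refinement: run a
#' signal-processing detector over the full image, binarize it, and
#' intersect with the Stage-1 candidate mask.
#'
#' @param image Intensity matrix.
#' @param stage1_mask Logical candidate mask.
#' @param method `"gbd"` or `"tht"`.
#' @param sp_threshold Binarization threshold in \[0, 1\].
#' @param sigmas,radii Kernel sets passed to the detector.
#' @return Logical refined mask, subset of `stage1_mask`.
#' @export
sp_refine <- function(image, stage1_mask, method = c("gbd", "tht"),
                      sp_threshold = 0.3,
                      sigmas = c(1, 2, 4, 8), radii = c(2, 4, 8, 16)) {
  method <- match.arg(method)
  stage1_mask <- as_binary(stage1_mask)
  assert_same_shape(image, stage1_mask, "image and stage1_mask")
  map <- if (method == "gbd") gbd_map(image, sigmas) else tht_map(image, radii)
  binarize(map, sp_threshold, source = image) & stage1_mask
}

#' Baseline generative detection with exhaustive random-box masks
#'
#' The comparator the mask-guided refinement improves on: instead of a
#' Stage-1 mask, the whole image is covered by a disjoint tiling of
#' `box_size` boxes; each box is inpainted alone (with the rest of the
#' image as context), the positive differences are accumulated, and the
#' accumulated map is thresholded at `cfg$tau` inside the breast. Masking
#' 100\% of the image means every texture fluctuation the inpainter cannot
#' reproduce becomes a potential false positive.
#'
#' @param image Intensity matrix.
#' @param breast_mask Logical breast-region mask.
#' @param cfg A [refine_config()] supplying `tau` and the backend.
#' @param box_size Side of the tiling boxes (default 32).
#' @return Logical detection mask inside the breast.
#' @export
baseline_generative_mask <- function(image, breast_mask, cfg = refine_config(),
                                     box_size = 32) {
  breast_mask <- as_binary(breast_mask)
  assert_same_shape(image, breast_mask, "image and breast_mask")
  cells <- box_grid(nrow(image), ncol(image), box_size)
  acc <- matrix(0, nrow(image), ncol(image))
  for (k in seq_len(nrow(cells))) {
    box <- matrix(FALSE, nrow(image), ncol(image))
    box[cells[k, 1]:cells[k, 2], cells[k, 3]:cells[k, 4]] <- TRUE
    virtual <- inpaint(image, box, backend = cfg$backend, model = cfg$model)
    d <- difference_map(image, virtual, box)
    acc <- pmax(acc, d)
  }
  (acc > cfg$tau) & breast_mask
}

# Patch grid covering an n-pixel axis with patches of side `patch` and the
# given stride; the last start is pulled back so the final patch ends at n.
patch_starts <- function(n, patch, stride) {
  if (patch >= n) return(1L)
  s <- seq(1L, n - patch + 1L, by = max(1L, stride))
  sort(unique(c(s, n - patch + 1L)))
}

#' Full-field processing by overlapping patches
#'
#' Large images are processed as overlapping square patches (default
#' 512 x 512 with 50\% overlap): each patch is inpainted under its part of
#' the Stage-1 mask, the virtual patches are merged by per-pixel averaging
#' of all covering patches, and the refined mask is recomputed from the
#' merged virtual image -- so stitching seams cannot create positives.
#' Images smaller than the patch size are processed as a single patch.
#'
#' @param image Intensity matrix.
#' @param stage1_mask Logical candidate mask.
#' @param cfg A [refine_config()].
#' @return List with `virtual` (merged full-field virtual-normal image) and
#'   `refined` (logical mask, subset of `stage1_mask`).
#' @export
run_fullfield <- function(image, stage1_mask, cfg = refine_config()) {
  stage1_mask <- as_binary(stage1_mask)
  assert_same_shape(image, stage1_mask, "image and stage1_mask")
  rows <- nrow(image); cols <- ncol(image)
  patch <- min(cfg$patch_size, rows, cols)
  stride <- as.integer(round(patch * (1 - cfg$overlap)))
  rs <- patch_starts(rows, patch, stride)
  cs <- patch_starts(cols, patch, stride)
  acc <- matrix(0, rows, cols)
  cover <- matrix(0, rows, cols)
  for (r0 in rs) for (c0 in cs) {
    ri <- r0:(r0 + patch - 1); ci <- c0:(c0 + patch - 1)
    sub_img <- image[ri, ci]
    sub_msk <- stage1_mask[ri, ci]
    v <- if (any(sub_msk) && !all(sub_msk)) {
      inpaint(sub_img, sub_msk, backend = cfg$backend, model = cfg$model)
    } else {
      # nothing to inpaint, or no context in this patch: pass through
      sub_img
    }
    acc[ri, ci] <- acc[ri, ci] + v
    cover[ri, ci] <- cover[ri, ci] + 1
  }
  virtual <- acc / cover
  d <- difference_map(image, virtual, stage1_mask)
  list(virtual = virtual, refined = (d > cfg$tau) & stage1_mask)
}
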
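# Stage-1 candidate generation. The refinement method assumes a
# high-sensitivity, low-precision candidate mask from an upstream detector
# (in deployment, a trained segmentation network). Two providers are
# available: a calibrated ground-truth-derived mock, which isolates the
# Stage-2 refinement contribution for testing, and the signal-processing
# detectors as whole-image candidate generators.

#' Configuration of the Stage-1 candidate provider
#'
#' @param provider `"mock"` (ground-truth-derived, for controlled
#'   experiments) or `"sp"` (a signal-processing detector).
#' @param dilation_radius Mock: Euclidean-disk dilation of the ground truth
#'   in pixels (default 2), emulating the over-segmentation halo of a
#'   high-sensitivity detector.
#' @param target_activation Mock: target predicted-positive fraction of the
#'   breast area (default 0.012, the ~1.2\% activation profile of a
#'   high-sensitivity segmentation network).
#' @param fp_blob_radius_range Mock: inclusive radius range of random
#'   false-positive blobs (default `c(1, 3)`).
#' @param seed Integer seed for the mock's blob placement.
#' @param sp_method `"gbd"` or `"tht"` when `provider = "sp"`.
#' @param sp_threshold Binarization threshold for the SP provider.
#' @param sp_sigmas,sp_radii Kernel sets for the SP provider.
#' @return An object of class `stage1_config`.
#' @export
stage1_config <- function(provider = c("mock", "sp"),
                          dilation_radius = 2,
                          target_activation = 0.012,
                          fp_blob_radius_range = c(1L, 3L),
                          seed = 1L,
                          sp_method = c("gbd", "tht"),
                          sp_threshold = 0.3,
                          sp_sigmas = c(1, 2, 4, 8),
                          sp_radii = c(2, 4, 8, 16)) {
  provider <- match.arg(provider)
  stopifnot(target_activation >= 0, target_activation < 1, dilation_radius >= 0)
  structure(list(
    provider = provider,
    dilation_radius = dilation_radius,
    target_activation = target_activation,
    fp_blob_radius_range = as.integer(fp_blob_radius_range),
    seed = as.integer(seed),
    sp_method = match.arg(sp_method),
    sp_threshold = sp_threshold,
    sp_sigmas = sp_sigmas,
    sp_radii = sp_radii
  ), class = "stage1_config")
}

#' Mock high-sensitivity Stage-1 segmenter
#'
#' Emulates the detection profile of a high-sensitivity, low-precision
#' segmentation network without training one: the ground truth is dilated
#' by a Euclidean disk (so sensitivity is 100\% by construction) and seeded
#' random false-positive blobs are added inside the breast, away from the
#' ground truth, until the activation rate reaches the configured target or
#' the breast is exhausted.
#'
#' @param gt_mask Logical ground-truth mask (must be contained in the
#'   breast mask).
#' @param breast_mask Logical breast-region mask.
#' @param cfg A [stage1_config()] with `provider = "mock"`.
#' @return Logical candidate mask, a subset of `breast_mask` containing
#'   `gt_mask`.
#' @export
mock_segmenter <- function(gt_mask, breast_mask, cfg = stage1_config()) {
  gt_mask <- as_binary(gt_mask); breast_mask <- as_binary(breast_mask)
  assert_same_shape(gt_mask, breast_mask, "gt_mask and breast_mask")
  if (any(gt_mask & !breast_mask)) {
    stop("gt_mask must be contained in breast_mask")
  }
  out <- dilate_disk(gt_mask, cfg$dilation_radius) & breast_mask
  out <- out | gt_mask
  breast_n <- sum(breast_mask)
  if (breast_n == 0) return(out)

  with_seed(cfg$seed, {
    target_px <- cfg$target_activation * breast_n
    candidates <- which(breast_mask & !gt_mask)
    attempts <- 0L
    nr <- nrow(out)
    rmin <- cfg$fp_blob_radius_range[1]; rmax <- cfg$fp_blob_radius_range[2]
    while (sum(out) < target_px && attempts < 10000L && length(candidates) > 0) {
      attempts <- attempts + 1L
      ctr <- candidates[sample.int(length(candidates), 1)]
      center <- cbind((ctr - 1) %% nr + 1, (ctr - 1) %/% nr + 1)
      radius <- rmin + sample.int(rmax - rmin + 1, 1) - 1L
      blob <- paint_disks(matrix(FALSE, nr, ncol(out)), center, radius)
      if (any(blob & gt_mask)) next  # false positives never cover true pixels
      out <- out | (blob & breast_mask)
    }
    out
  })
}

#' Signal-processing Stage-1 provider
#'
#' Runs the configured detector (Gaussian blur difference or top-hat) over
#' the whole image, binarizes at the configured threshold, and restricts to
#' the breast region.
#'
#' @param image Numeric intensity matrix.
#' @param breast_mask Logical breast-region mask.
#' @param cfg A [stage1_config()] with `provider = "sp"`.
#' @return Logical candidate mask, a subset of `breast_mask`.
#' @export
sp_stage1 <- function(image, breast_mask, cfg) {
  stopifnot(inherits(cfg, "stage1_config"), cfg$provider == "sp")
  map <- switch(cfg$sp_method,
    gbd = gbd_map(image, cfg$sp_sigmas),
    tht = tht_map(image, cfg$sp_radii),
    stop("unknown SP method: ", cfg$sp_method)
  )
  binarize(map, cfg$sp_threshold, source = image) & as_binary(breast_mask)
}
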
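#' Specification of a synthetic mammography-like phantom
#'
#' Bundles every knob of the phantom generator: image geometry, textured
#' tissue background, one contiguous high-density patch, and sparse bright
#' calcification-like objects. Intensities are on a 12-bit DICOM-style scale
#' (0--4095). The defaults describe the cohort used throughout the package's
#' own experiments: small (radius 1--3 px) deposits of 150--600 units of
#' contrast embedded in tissue with ~30 units of correlated fluctuation.
#'
#' @param image_shape Integer `(rows, cols)`, at least 64 x 64.
#' @param background_level Mean tissue intensity (default 800).
#' @param texture_sigma Spatial correlation length of the background texture
#'   in pixels (Gaussian smoothing scale of the driving noise).
#' @param texture_amplitude Standard deviation of the background texture in
#'   intensity units; 0 disables texture.
#' @param n_objects_range Inclusive integer range of the calcification count.
#' @param object_radius_range Inclusive integer range of object disk radii
#'   (pixels).
#' @param object_amplitude_range Inclusive range of object contrast added
#'   above the local background (intensity units); must be positive.
#' @param dense_region_fraction Fraction of the breast covered by one
#'   contiguous high-density patch (0 disables it).
#' @param dense_region_boost Intensity added inside the dense patch.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   spec including this seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         background_level = 800,
                         texture_sigma = 4,
                         texture_amplitude = 30,
                         n_objects_range = c(3L, 8L),
                         object_radius_range = c(1L, 3L),
                         object_amplitude_range = c(150, 600),
                         dense_region_fraction = 0.15,
                         dense_region_boost = 150,
                         seed = 1L) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2, all(image_shape >= 64))
  check_range <- function(r, name, positive = FALSE) {
    if (length(r) != 2 || any(is.na(r)) || r[2] < r[1]) {
      stop(sprintf("%s must be a non-empty (lo, hi) range", name))
    }
    if (any(r < 0)) stop(sprintf("%s must be non-negative", name))
    if (positive && any(r <= 0)) stop(sprintf("%s must be positive", name))
  }
  check_range(n_objects_range, "n_objects_range")
  check_range(object_radius_range, "object_radius_range")
  check_range(object_amplitude_range, "object_amplitude_range", positive = TRUE)
  stopifnot(texture_sigma >= 0, texture_amplitude >= 0,
            dense_region_fraction >= 0, dense_region_fraction < 1,
            dense_region_boost >= 0)
  structure(list(
    image_shape = image_shape,
    background_level = background_level,
    texture_sigma = texture_sigma,
    texture_amplitude = texture_amplitude,
    n_objects_range = as.integer(n_objects_range),
    object_radius_range = as.integer(object_radius_range),
    object_amplitude_range = as.numeric(object_amplitude_range),
    dense_region_fraction = dense_region_fraction,
    dense_region_boost = dense_region_boost,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Half-ellipse breast region anchored on the left image edge, the usual
# footprint of a single-view mammogram.
breast_halfellipse <- function(rows, cols) {
  r0 <- (rows + 1) / 2
  a <- 0.42 * rows
  b <- 0.85 * cols
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  ((rr - r0) / a)^2 + ((cc - 1) / b)^2 <= 1
}

# Max allowed ground-truth area as a fraction of the breast area.
SPARSITY_LIMIT <- 0.015

phantom_attempt <- function(spec, seed) {
  rows <- spec$image_shape[1]; cols <- spec$image_shape[2]
  breast <- breast_halfellipse(rows, cols)
  breast_n <- sum(breast)

  with_seed(seed, {
    img <- matrix(spec$background_level, rows, cols)

    if (spec$texture_amplitude > 0) {
      noise <- matrix(rnorm(rows * cols), rows, cols)
      if (spec$texture_sigma > 0) noise <- gaussian_blur(noise, spec$texture_sigma)
      noise <- noise / sd(noise)
      img <- img + spec$texture_amplitude * noise
    }

    if (spec$dense_region_fraction > 0 && spec$dense_region_boost > 0) {
      target_area <- spec$dense_region_fraction * breast_n
      radius <- sqrt(target_area / pi)
      idx <- which(breast)
      ctr <- idx[sample.int(length(idx), 1)]
      center <- cbind((ctr - 1) %% rows + 1, (ctr - 1) %/% rows + 1)
      dense <- paint_disks(matrix(FALSE, rows, cols), center, radius) & breast
      img <- img + spec$dense_region_boost * dense
    }

    gt <- matrix(FALSE, rows, cols)
    n_obj <- if (spec$n_objects_range[2] > spec$n_objects_range[1]) {
      spec$n_objects_range[1] +
        sample.int(spec$n_objects_range[2] - spec$n_objects_range[1] + 1, 1) - 1L
    } else {
      spec$n_objects_range[1]
    }
    placed <- 0L
    attempts <- 0L
    while (placed < n_obj && attempts < 200L * max(1L, n_obj)) {
      attempts <- attempts + 1L
      radius <- spec$object_radius_range[1] +
        sample.int(spec$object_radius_range[2] - spec$object_radius_range[1] + 1, 1) - 1L
      amp <- runif(1, spec$object_amplitude_range[1], spec$object_amplitude_range[2])
      r <- sample.int(rows, 1); c <- sample.int(cols, 1)
      disk <- paint_disks(matrix(FALSE, rows, cols), cbind(r, c), radius)
      # object must lie fully inside the breast, clear of existing objects
      # (2-px moat keeps components 4-separated)
      if (!all(breast[disk])) next
      if (any(dilate_disk(disk, 2)[gt])) next
      img[disk] <- img[disk] + amp
      gt <- gt | disk
      placed <- placed + 1L
    }
    if (placed < n_obj) stop("phantom placement failed: breast too crowded for requested objects")

    img <- round(clip_intensity(img))
    list(image = img, breast_mask = breast, gt_mask = gt)
  })
}

#' Generate one synthetic phantom patient
#'
#' Builds a deterministic mammography-like image from a [phantom_spec()]:
#' half-ellipse breast region, correlated tissue texture, one contiguous
#' dense patch, and sparse bright disk objects with pixel-exact ground
#' truth. Intensities are rounded to integers on \[0, 4095\] so the phantom
#' round-trips losslessly through 16-bit image files. The ground-truth area
#' must stay below 1.5\% of the breast area (the sparsity regime the
#' refinement method assumes); if a spec cannot satisfy that after bounded
#' retries, an error names the violated invariant.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: list with `image`, `breast_mask`,
#'   `gt_mask`, `objects` (data frame of per-object features, see
#'   [compute_object_features()]), `labels` (integer component map), `seed`,
#'   and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  for (retry in 0:9) {
    p <- phantom_attempt(spec, derive_seed(spec$seed, retry))
    gt_frac <- sum(p$gt_mask) / sum(p$breast_mask)
    if (gt_frac < SPARSITY_LIMIT) {
      feats <- compute_object_features(p$image, p$gt_mask)
      return(structure(list(
        image = p$image,
        breast_mask = p$breast_mask,
        gt_mask = p$gt_mask,
        objects = feats$objects,
        labels = feats$labels,
        seed = spec$seed,
        spec = spec
      ), class = "phantom"))
    }
  }
  stop(sprintf(
    "sparsity invariant violated: ground-truth area >= %.1f%% of breast after retries",
    100 * SPARSITY_LIMIT))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom %dx%d: %d object(s), gt %.3f%% of breast, seed %d\n",
              nrow(x$image), ncol(x$image), nrow(x$objects),
              100 * sum(x$gt_mask) / sum(x$breast_mask), x$seed))
  invisible(x)
}

#' Per-object interior/exterior density features
#'
#' Labels the ground-truth mask into 4-connected components and, for each
#' component (one calcification object), measures its size and an
#' interior/exterior density pair: `exterior_density` is the mean intensity
#' over a dilation ring of width `ring_width` around the object with all
#' ground-truth-positive pixels excluded (so neighbouring objects do not
#' contaminate each other), and `interior_density` is the mean intensity
#' over the object minus `exterior_density`, i.e. the object's contrast
#' above its local surroundings.
#'
#' @param image Numeric matrix of intensities.
#' @param gt_mask Logical matrix of ground-truth calcification pixels.
#' @param ring_width Width in pixels of the surrounding ring (default 5).
#' @return List with `objects`, a data frame with columns `object_id`,
#'   `size_px`, `interior_density`, `exterior_density`, `centroid_row`,
#'   `centroid_col` (1-based), and `labels`, the integer component map
#'   (0 = background).
#' @export
compute_object_features <- function(image, gt_mask, ring_width = 5) {
  gt_mask <- as_binary(gt_mask)
  assert_same_shape(image, gt_mask, "image and gt_mask")
  stopifnot(ring_width >= 1)
  labels <- label_components4(gt_mask)
  n <- max(labels)
  if (n == 0) {
    return(list(
      objects = data.frame(object_id = integer(), size_px = integer(),
                           interior_density = numeric(), exterior_density = numeric(),
                           centroid_row = numeric(), centroid_col = numeric()),
      labels = labels))
  }
  rows <- row(labels); cols <- col(labels)
  out <- lapply(seq_len(n), function(id) {
    comp <- labels == id
    ring <- dilate_disk(comp, ring_width) & !gt_mask
    ext <- mean(image[ring])
    data.frame(
      object_id = id,
      size_px = sum(comp),
      interior_density = mean(image[comp]) - ext,
      exterior_density = ext,
      centroid_row = mean(rows[comp]),
      centroid_col = mean(cols[comp])
    )
  })
  list(objects = do.call(rbind, out), labels = labels)
}

# 4-connected component labelling (EBImage::bwlabel labels connected sets of
# foreground pixels using 4-connectivity, which is the object definition
# used throughout).
label_components4 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  matrix(as.integer(round(as.numeric(lab))), nrow(mask), ncol(mask))
}

#' Write a cohort of phantoms to disk
#'
#' Generates one phantom per spec and writes, per patient, the image as
#' 16-bit TIFF, the breast/ground-truth masks as 8-bit 0/255 PNG, plus a
#' cohort-wide object feature CSV and a YAML manifest. One phantom is one
#' patient.
#'
#' @param spec_grid List of [phantom_spec()] objects (may be empty).
#' @param out_dir Output directory, created if missing.
#' @return The manifest (invisibly), a list with one entry per patient
#'   holding `patient_id`, `seed`, and relative file paths.
#' @export
generate_cohort <- function(spec_grid, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  manifest <- list()
  all_objects <- list()
  for (i in seq_along(spec_grid)) {
    ph <- make_phantom(spec_grid[[i]])
    pid <- sprintf("patient_%03d", i)
    paths <- list(
      image = file.path(out_dir, paste0(pid, "_image.tif")),
      breast = file.path(out_dir, paste0(pid, "_breast.png")),
      gt = file.path(out_dir, paste0(pid, "_gt.png"))
    )
    write_gray16(ph$image, paths$image)
    write_mask(ph$breast_mask, paths$breast)
    write_mask(ph$gt_mask, paths$gt)
    if (nrow(ph$objects) > 0) {
      all_objects[[pid]] <- cbind(patient_id = pid, ph$objects)
    }
    manifest[[pid]] <- list(patient_id = pid, seed = ph$seed,
                            image = basename(paths$image),
                            breast_mask = basename(paths$breast),
                            gt_mask = basename(paths$gt))
  }
  obj_path <- file.path(out_dir, "objects.csv")
  obj_df <- if (length(all_objects)) {
    do.call(rbind, c(all_objects, list(make.row.names = FALSE)))
  } else {
    data.frame(patient_id = character(), object_id = integer(), size_px = integer(),
               interior_density = numeric(), exterior_density = numeric(),
               centroid_row = numeric(), centroid_col = numeric())
  }
  write.csv(obj_df, obj_path, row.names = FALSE)
  yaml::write_yaml(list(patients = unname(manifest), objects = "objects.csv"),
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read back a cohort written by [generate_cohort()]
#'
#' @param dir Cohort directory containing `manifest.yaml`.
#' @return List of per-patient lists with `patient_id`, `seed`, `image`,
#'   `breast_mask`, `gt_mask`.
#' @export
read_cohort <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  lapply(mf$patients, function(p) {
    list(patient_id = p$patient_id, seed = p$seed,
         image = read_gray16(file.path(dir, p$image)),
         breast_mask = read_mask(file.path(dir, p$breast_mask)),
         gt_mask = read_mask(file.path(dir, p$gt_mask)))
  })
}
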
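test_that("difference maps clip at zero and vanish outside the mask", {
  orig <- matrix(c(100, 80, 100, 100), 2, 2)
  virt <- matrix(c(90, 90, 90, 90), 2, 2)
  mask <- matrix(c(TRUE, TRUE, FALSE, TRUE), 2, 2)
  d <- difference_map(orig, virt, mask)
  expect_equal(d[1, 1], 10)
  expect_equal(d[2, 1], 0)          # negative difference clipped
  expect_equal(d[1, 2], 0)          # outside mask
  expect_true(all(difference_map(orig, orig, mask) == 0))
  expect_error(difference_map(orig, virt[1, , drop = FALSE], mask), "dimensions")
})

test_that("refinement keeps a bright object and drops spurious ramp pixels", {
  ramp <- outer(1:32, 1:32, function(i, j) 100 + 100 * (j - 1) / 31)
  obj <- calcrefine:::paint_disks(matrix(FALSE, 32, 32), cbind(16, 16), 2)
  img <- ramp + 400 * obj
  s1 <- calcrefine:::dilate_disk(obj, 2)
  s1[5:7, 5:7] <- TRUE              # spurious candidate on clean ramp
  ref <- refine_mask(img, s1, refine_config(tau = 50, backend = "biharmonic"))
  expect_equal(sum(ref & obj), 13)  # all object pixels survive
  expect_equal(sum(ref[5:7, 5:7]), 0)
  expect_true(all(s1[ref]))         # refined subset of stage 1

  # SP refinement retains the object at a low threshold on the same patch
  spr <- sp_refine(img, s1, method = "gbd", sp_threshold = 0.05)
  expect_gt(sum(spr & obj), 0)
  expect_true(all(s1[spr]))
})

test_that("empty and extreme inputs behave per contract", {
  p <- make_phantom(tiny_spec(seed = 61))
  empty <- matrix(FALSE, nrow(p$image), ncol(p$image))
  expect_identical(refine_mask(p$image, empty), empty)
  expect_identical(sp_refine(p$image, empty), empty)
  flat <- matrix(800, 96, 96)
  s1 <- matrix(FALSE, 96, 96); s1[10:20, 10:20] <- TRUE
  expect_false(any(sp_refine(flat, s1)))           # zero SP map on constants
  ref <- refine_mask(p$image, p$gt_mask, refine_config(tau = 5000))
  expect_false(any(ref))                           # tau above the intensity range
})

test_that("refinement is monotone in tau and never raises activation", {
  p <- make_phantom(tiny_spec(seed = 71))
  s1 <- mock_segmenter(p$gt_mask, p$breast_mask, stage1_config(seed = 3))
  virt <- inpaint(p$image, s1)
  d <- difference_map(p$image, virt, s1)
  r20 <- (d > 20) & s1; r80 <- (d > 80) & s1
  expect_true(all(r20[r80]))                       # antitone in tau
  expect_lte(sum(r80), sum(r20))
  expect_lte(sum(r20), sum(s1))                    # activation ordering
})

test_that("the baseline generative mode tiles exhaustively and is noisier", {
  # tiling arithmetic: 64x64 with 16px boxes = 16 disjoint boxes, full union
  cells <- calcrefine:::box_grid(64, 64, 16)
  expect_equal(nrow(cells), 16)
  u <- matrix(FALSE, 64, 64)
  for (k in seq_len(nrow(cells))) u[cells[k, 1]:cells[k, 2], cells[k, 3]:cells[k, 4]] <- TRUE
  expect_true(all(u))

  flat <- matrix(700, 64, 64)
  breast <- matrix(TRUE, 64, 64)
  expect_false(any(baseline_generative_mask(flat, breast, refine_config(tau = 1),
                                            box_size = 16)))

  p <- make_phantom(tiny_spec(seed = 81))
  cfg <- refine_config(tau = 50)
  base <- baseline_generative_mask(p$image, p$breast_mask, cfg, box_size = 16)
  s1 <- mock_segmenter(p$gt_mask, p$breast_mask, stage1_config(seed = 9))
  ref <- refine_mask(p$image, s1, cfg)
  expect_gte(sum(base), sum(ref))                  # baseline activates more
})

test_that("full-field stitching is exact for unmodified images", {
  p <- make_phantom(phantom_spec(image_shape = c(150, 150), seed = 91,
                                 n_objects_range = c(1, 2)))
  empty <- matrix(FALSE, 150, 150)
  out <- run_fullfield(p$image, empty, refine_config(patch_size = 64, overlap = 0.5))
  expect_equal(out$virtual, p$image)               # split-then-merge identity
  expect_false(any(out$refined))
})

test_that("full-field refinement matches the single-patch result near an interior object", {
  p <- make_phantom(phantom_spec(image_shape = c(150, 150), seed = 95,
                                 n_objects_range = c(1, 1),
                                 object_radius_range = c(2, 2)))
  s1 <- mock_segmenter(p$gt_mask, p$breast_mask,
                       stage1_config(seed = 2, target_activation = 0.005))
  cfg <- refine_config(tau = 50, patch_size = 96, overlap = 0.5)
  ff <- run_fullfield(p$image, s1, cfg)
  expect_true(all(s1[ff$refined]))
  single <- refine_mask(p$image, s1, cfg)
  ctr <- round(c(p$objects$centroid_row[1], p$objects$centroid_col[1]))
  ri <- max(1, ctr[1] - 8):min(150, ctr[1] + 8)
  ci <- max(1, ctr[2] - 8):min(150, ctr[2] + 8)
  expect_equal(ff$refined[ri, ci], single[ri, ci])
})
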
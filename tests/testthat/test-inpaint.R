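test_that("inpainting honours identity, constant, and affine contracts", {
  set.seed(2)
  img <- matrix(runif(64 * 64, 0, 4000), 64, 64)
  mask <- matrix(FALSE, 64, 64)
  expect_identical(inpaint(img, mask), img)        # empty mask -> identity

  const <- matrix(1234, 64, 64)
  mask[20:44, 18:40] <- TRUE
  ramp <- outer(1:64, 1:64, function(i, j) 3.5 * i + 2 * j + 400)
  for (backend in c("harmonic", "biharmonic")) {
    expect_equal(inpaint(const, mask, backend), const, tolerance = 1e-9)
    v <- inpaint(ramp, mask, backend)
    expect_lt(max(abs(v - ramp)), 1e-3)            # affine solves both PDEs
    w <- inpaint(img, mask, backend)
    expect_identical(w[!mask], img[!mask])         # outside-mask bit-identity
  }
})

test_that("harmonic fills obey the discrete maximum principle", {
  set.seed(8)
  for (k in 1:5) {
    img <- matrix(runif(32 * 32, 0, 4000), 32, 32)
    mask <- matrix(FALSE, 32, 32)
    r0 <- sample(5:15, 1); c0 <- sample(5:15, 1)
    mask[r0:(r0 + 10), c0:(c0 + 10)] <- TRUE
    v <- inpaint(img, mask, "harmonic")
    boundary <- calcrefine:::dilate_disk(mask, 1) & !mask
    expect_gte(min(v[mask]), min(img[boundary]) - 1e-8)
    expect_lte(max(v[mask]), max(img[boundary]) + 1e-8)
  }
})

test_that("degenerate masks are rejected", {
  img <- matrix(1, 16, 16)
  expect_error(inpaint(img, matrix(TRUE, 16, 16)), "no context")
  expect_error(inpaint(img, matrix(FALSE, 8, 8)), "dimensions")
})

test_that("box sampling reaches its coverage target deterministically", {
  m <- sample_boxes(c(64, 64), box_size = 16, coverage = 1.0, seed = 3)
  expect_equal(mean(m), 1)                         # full tiling reachable

  m2 <- sample_boxes(c(256, 256), box_size = 32, coverage = 0.25, seed = 4)
  frac <- mean(m2)
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.25 + 32^2 / 256^2)            # overshoot <= one box

  expect_identical(sample_boxes(c(64, 64), 16, 0.5, seed = 9),
                   sample_boxes(c(64, 64), 16, 0.5, seed = 9))
  expect_error(sample_boxes(c(16, 16), 32, 0.5), "exceeds")
})

test_that("the learned backend trains on masked reconstruction and beats the texture floor", {
  # 200 calcification-free textured patches from object-free phantoms
  patches <- list()
  for (s in 1:8) {
    p <- make_phantom(phantom_spec(image_shape = c(128, 128),
                                   n_objects_range = c(0, 0),
                                   dense_region_fraction = 0, seed = 300 + s))
    for (r0 in seq(1, 101, by = 25)) for (c0 in seq(1, 101, by = 20)) {
      patches[[length(patches) + 1]] <- p$image[r0:(r0 + 23), c0:(c0 + 23)]
    }
  }
  expect_gte(length(patches), 200)
  train <- patches[1:200]
  held <- patches[201:length(patches)]

  model <- train_masked_autoencoder(train, box_size = 6, coverage = 0.2,
                                    epochs = 150, seed = 5)
  expect_true(model$trained)
  expect_lt(model$final_loss, 30)                  # texture sd of the generator

  model2 <- train_masked_autoencoder(train, box_size = 6, coverage = 0.2,
                                     epochs = 150, seed = 5)
  expect_identical(model$final_loss, model2$final_loss)

  # held-out masked-region RMSE below the texture amplitude
  errs <- sapply(held, function(p) {
    m <- sample_boxes(dim(p), 6, 0.2, seed = 77)
    v <- inpaint(p, m, backend = "learned", model = model)
    expect_identical(v[!m], p[!m])                 # composited outside mask
    sqrt(mean((v[m] - p[m])^2))
  })
  expect_lt(mean(errs), 30)

  # constants are reproduced exactly (weights live on the simplex)
  const <- matrix(900, 32, 32)
  m <- matrix(FALSE, 32, 32); m[10:20, 10:20] <- TRUE
  expect_equal(inpaint(const, m, "learned", model = model), const,
               tolerance = 1e-6)
})

test_that("an untrained learned model is refused", {
  m0 <- train_masked_autoencoder(list(matrix(500, 32, 32)), epochs = 0)
  expect_false(m0$trained)
  img <- matrix(500, 32, 32)
  msk <- matrix(FALSE, 32, 32); msk[5:10, 5:10] <- TRUE
  expect_error(inpaint(img, msk, "learned", model = m0), "untrained")
  expect_error(inpaint(img, msk, "learned"), "requires a model")
})

test_that("training data containing abnormal pixels is rejected", {
  p <- matrix(500, 32, 32)
  gt <- matrix(FALSE, 32, 32); gt[4, 4] <- TRUE
  expect_error(
    train_masked_autoencoder(list(p), gt_masks = list(gt), epochs = 10),
    "abnormal pixels")
})
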
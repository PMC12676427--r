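mask_from <- function(coords, shape = c(4, 4)) {
  m <- matrix(FALSE, shape[1], shape[2])
  if (length(coords)) m[do.call(rbind, coords)] <- TRUE
  m
}

test_that("confusion counts and derived metrics match hand counts", {
  gt <- mask_from(list(c(1, 1), c(1, 2), c(1, 3)))
  pred <- mask_from(list(c(1, 2), c(1, 3), c(2, 3)))
  breast <- matrix(TRUE, 4, 4)
  cm <- pixel_confusion(pred, gt, breast)
  expect_equal(cm[c("tp", "fp", "fn", "tn")], list(tp = 2, fp = 1, fn = 1, tn = 12))
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, cm$breast_n)
  im <- image_metrics(cm)
  expect_equal(im$sensitivity, 200 / 3, tolerance = 1e-12)
  expect_equal(im$ppv, 200 / 3, tolerance = 1e-12)
  expect_equal(im$dice, 200 * 2 / 6, tolerance = 1e-12)

  im2 <- image_metrics(pixel_confusion(gt, gt, breast))
  expect_equal(c(im2$sensitivity, im2$ppv, im2$dice), c(100, 100, 100))

  expect_error(pixel_confusion(pred, gt, mask_from(list(c(2, 2)))), "contained")
})

test_that("activation rate is the predicted fraction of the breast", {
  breast <- matrix(FALSE, 40, 40); breast[1:25, 1:40] <- TRUE  # 1000 px
  pred <- matrix(FALSE, 40, 40); pred[1, 1:12] <- TRUE
  gt <- matrix(FALSE, 40, 40)
  im <- image_metrics(pixel_confusion(pred, gt, breast))
  expect_equal(im$activation_rate, 1.2)
})

test_that("all pixel metrics agree with a brute-force recount on random masks", {
  set.seed(42)
  for (k in 1:50) {
    breast <- matrix(runif(64) < 0.8, 8, 8)
    gt <- matrix(runif(64) < 0.2, 8, 8) & breast
    pred <- matrix(runif(64) < 0.3, 8, 8)
    cm <- pixel_confusion(pred, gt, breast)
    bf <- bf_confusion(pred, gt, breast)
    expect_identical(cm[c("tp", "fp", "fn", "tn")], bf)
    im <- image_metrics(cm)
    if (bf$tp + bf$fn > 0) {
      expect_equal(im$sensitivity, 100 * bf$tp / (bf$tp + bf$fn))
    }
    if (2 * bf$tp + bf$fp + bf$fn > 0) {
      expect_equal(im$dice, 200 * bf$tp / (2 * bf$tp + bf$fp + bf$fn))
    }
  }
})

test_that("cohort aggregation is an unweighted permutation-invariant mean", {
  one <- list(list(sensitivity = 80, ppv = 10, dice = 17, activation_rate = 1,
                   true_activation_rate = 0.1))
  a1 <- aggregate_cohort(one)
  expect_equal(a1$sd, rep(0, 5))                      # single image -> sd 0

  two <- c(one, list(list(sensitivity = 90, ppv = 30, dice = 44,
                          activation_rate = 2, true_activation_rate = 0.2)))
  a2 <- aggregate_cohort(two)
  expect_equal(a2$mean[a2$metric == "ppv"], 20)
  expect_equal(aggregate_cohort(rev(two))$mean, a2$mean)
  expect_error(aggregate_cohort(list()), "empty")
})

test_that("paired Wilcoxon matches exact enumeration and its symmetries", {
  a <- c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14)
  expect_equal(paired_test(a, a), 1.0)
  b <- a - c(1, 2, 1.5, 0.5, 3, 2.5, 0.7, 1.2, 1.8, 0.9)
  p <- paired_test(a, b)
  expect_equal(p, 2 / 1024)                           # all-positive differences
  expect_equal(p, bf_signed_rank_p(a - b))
  expect_equal(paired_test(b, a), p)                  # two-sided symmetry
})

test_that("paired Wilcoxon agrees with enumeration on random mixed-sign data", {
  set.seed(13)
  for (k in 1:5) {
    a <- round(rnorm(9, 50, 10), 3)
    b <- round(a + rnorm(9, 0, 5), 3)
    expect_equal(paired_test(a, b), bf_signed_rank_p(a - b), tolerance = 1e-12)
  }
})

test_that("patient-level detection needs one predicted pixel per object", {
  gt <- calcrefine:::paint_disks(matrix(FALSE, 32, 32), cbind(10, 10), 2)
  gt2 <- gt | calcrefine:::paint_disks(matrix(FALSE, 32, 32), cbind(24, 24), 1)
  labels <- compute_object_features(matrix(500, 32, 32) + 400 * gt2, gt2)$labels
  empty <- matrix(FALSE, 32, 32)
  d0 <- patient_detected(empty, labels)
  expect_false(d0$patient_detected)
  expect_false(any(d0$object_detected))

  one_px <- empty; one_px[10, 10] <- TRUE             # single pixel of object 1
  d1 <- patient_detected(one_px, labels)
  expect_true(d1$patient_detected)
  expect_equal(sum(d1$object_detected), 1)
})

test_that("conditional error rates follow the exclusion and omission rules", {
  mk_patient <- function(sizes, ints, dets) {
    # synthetic patient with one object per size; labels on a tiny grid
    labels <- matrix(0L, 8, 8)
    for (i in seq_along(sizes)) labels[i, 1] <- i
    pred <- matrix(FALSE, 8, 8)
    for (i in seq_along(sizes)) if (dets[i]) pred[i, 1] <- TRUE
    list(patient = list(objects = data.frame(object_id = seq_along(sizes),
                                             size_px = sizes,
                                             interior_density = ints,
                                             exterior_density = 500),
                        labels = labels),
         pred = pred)
  }
  # object of size 60 excluded; patient B's only object is size 60 -> omitted
  a <- mk_patient(c(30, 60), c(400, 400), c(FALSE, TRUE))
  b <- mk_patient(60, 400, TRUE)
  ce <- conditional_error_rate(list(a$patient, b$patient), list(a$pred, b$pred),
                               condition_spec(max_size_px = 50))
  expect_equal(ce$n_patients, 1)
  expect_equal(ce$error_rate, 100)    # A's retained size-30 object was missed

  # 3 retained patients, 2 detected -> 33.3%
  ps <- lapply(1:3, function(i) mk_patient(20, 400, i <= 2))
  ce2 <- conditional_error_rate(lapply(ps, `[[`, "patient"),
                                lapply(ps, `[[`, "pred"),
                                condition_spec(max_size_px = 50))
  expect_equal(ce2$error_rate, 100 / 3, tolerance = 1e-9)
  expect_equal(ce2$n_patients, 3)

  expect_error(condition_spec(), "at least one bound")
  expect_error(conditional_error_rate(list(a$patient), list(a$pred),
                                      condition_spec(max_size_px = 10)),
               "empty condition stratum")
})

test_that("adding predicted positives never increases the conditional error", {
  set.seed(31)
  ps <- list(); preds_lo <- list(); preds_hi <- list()
  for (i in 1:6) {
    p <- make_phantom(tiny_spec(seed = 400 + i))
    ps[[i]] <- list(objects = p$objects, labels = p$labels)
    lo <- matrix(runif(96 * 96) < 0.002, 96, 96)
    preds_lo[[i]] <- lo
    preds_hi[[i]] <- lo | (matrix(runif(96 * 96) < 0.01, 96, 96))
  }
  cond <- condition_spec(max_size_px = 50)
  e_lo <- conditional_error_rate(ps, preds_lo, cond)$error_rate
  e_hi <- conditional_error_rate(ps, preds_hi, cond)$error_rate
  expect_lte(e_hi, e_lo)
})

test_that("fidelity matches closed forms", {
  img <- matrix(500, 32, 32)
  breast <- matrix(TRUE, 32, 32)
  gt <- matrix(FALSE, 32, 32)
  f0 <- fidelity(img, img, gt, breast)
  expect_equal(f0$error_ratio_normal, 0)
  expect_equal(f0$psnr_normal, 99)                    # capped
  expect_true(is.na(f0$rmse_abnormal))                # no abnormal region

  f1 <- fidelity(img, img - 1, gt, breast)            # |diff| = 1 everywhere
  expect_equal(f1$error_ratio_normal, 0)              # "exceeds 1" is strict
  expect_equal(f1$rmse_normal, 1)
  expect_equal(f1$psnr_normal, 20 * log10(4095), tolerance = 1e-9)

  obj <- calcrefine:::paint_disks(matrix(FALSE, 32, 32), cbind(16, 16), 2)
  orig <- img + 400 * obj
  virt <- img                                         # object fully removed
  f2 <- fidelity(orig, virt, obj, breast)
  expect_equal(f2$rmse_abnormal, 400)
  expect_equal(f2$error_ratio_abnormal, 100)
  expect_equal(f2$error_ratio_normal, 0)
  expect_equal(f2$psnr_abnormal, 20 * log10(4095 / 400), tolerance = 1e-9)
})
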
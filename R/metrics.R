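# Evaluation protocol: pixel-level confusion inside the breast region,
# per-image sensitivity/PPV/Dice/activation, cohort aggregation as
# unweighted mean +/- sample sd over images, a paired Wilcoxon signed-rank
# test between methods, patient-level conditional detection error, and
# fidelity of the virtual-normal image (PSNR / RMSE / error ratio split by
# ground-truth normal vs abnormal region).

#' Pixel-level confusion counts within the breast region
#'
#' Counts are restricted to breast pixels; predictions outside the breast
#' are ignored. The ground truth must be contained in the breast.
#'
#' @param pred,gt,breast Logical matrices of identical shape.
#' @return List with integer fields `tp`, `fp`, `fn`, `tn`, `breast_n`;
#'   `tp + fp + fn + tn == breast_n`.
#' @export
pixel_confusion <- function(pred, gt, breast) {
  pred <- as_binary(pred); gt <- as_binary(gt); breast <- as_binary(breast)
  assert_same_shape(pred, gt, "pred and gt")
  assert_same_shape(pred, breast, "pred and breast")
  if (any(gt & !breast)) stop("gt must be contained in the breast region")
  p <- pred[breast]; g <- gt[breast]
  list(tp = sum(p & g), fp = sum(p & !g), fn = sum(!p & g), tn = sum(!p & !g),
       breast_n = sum(breast))
}

#' Per-image detection metrics
#'
#' Converts confusion counts to the percentage metrics reported per image:
#' sensitivity, PPV, Dice, activation rate (predicted-positive fraction of
#' the breast) and true activation rate (ground-truth fraction of the
#' breast). Degenerate images: with no ground truth, sensitivity is `NA`;
#' with no predicted positives, PPV is 0 when ground truth exists and `NA`
#' when the image has neither ground truth nor predictions (such images are
#' dropped from the corresponding cohort averages).
#'
#' @param counts Result of [pixel_confusion()].
#' @return List with `sensitivity`, `ppv`, `dice`, `activation_rate`,
#'   `true_activation_rate`, all in percent.
#' @export
image_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) {
    100 * tp / (tp + fp)
  } else if (tp + fn > 0) 0 else NA_real_
  dice <- if (2 * tp + fp + fn > 0) 200 * tp / (2 * tp + fp + fn) else NA_real_
  list(sensitivity = sens, ppv = ppv, dice = dice,
       activation_rate = 100 * (tp + fp) / counts$breast_n,
       true_activation_rate = 100 * (tp + fn) / counts$breast_n)
}

#' Aggregate per-image metrics over a cohort
#'
#' Unweighted mean and sample standard deviation across images, computed
#' per metric with `NA` images dropped for that metric; a single-image
#' cohort reports sd 0.
#'
#' @param per_image List of [image_metrics()] results (non-empty).
#' @return Data frame with one row per metric: `metric`, `mean`, `sd`, `n`.
#' @export
aggregate_cohort <- function(per_image) {
  if (length(per_image) == 0) stop("cannot aggregate an empty cohort")
  metrics <- names(per_image[[1]])
  rows <- lapply(metrics, function(m) {
    v <- vapply(per_image, function(x) as.numeric(x[[m]]), numeric(1))
    v <- v[!is.na(v)]
    data.frame(metric = m,
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) sd(v) else 0,
               n = length(v))
  })
  do.call(rbind, rows)
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Exact two-sided signed-rank p-value on the per-image paired differences,
#' with zero differences dropped first (so `a == b` everywhere gives
#' p = 1). Used to compare a metric between two methods over the same
#' cohort.
#'
#' @param metric_a,metric_b Numeric vectors of equal length (>= 5).
#' @return p-value in (0, 1].
#' @export
paired_test <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 5)
  d <- metric_a - metric_b
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) return(1.0)
  suppressWarnings(
    wilcox.test(d, exact = length(unique(abs(d))) == length(d))$p.value
  )
}

#' Per-object and per-patient detection flags
#'
#' An object counts as detected iff at least one of its pixels is predicted
#' positive; the patient is detected iff at least one object is.
#'
#' @param pred Logical prediction mask.
#' @param labels Integer component map of the ground truth (from
#'   [compute_object_features()]), aligned with `pred`.
#' @return List with `object_detected` (logical vector indexed by
#'   object id) and `patient_detected` (scalar logical).
#' @export
patient_detected <- function(pred, labels) {
  pred <- as_binary(pred)
  assert_same_shape(pred, labels, "pred and labels")
  n <- max(labels)
  if (n == 0) return(list(object_detected = logical(0), patient_detected = FALSE))
  hit <- vapply(seq_len(n), function(id) any(pred[labels == id]), logical(1))
  list(object_detected = hit, patient_detected = any(hit))
}

#' Stratum definition for conditional patient-level analysis
#'
#' At least one bound must be set. Objects are retained when
#' `size_px < max_size_px`, `exterior_density >= min_exterior_density`, and
#' `interior_density <= max_interior_density`, each bound applied only if
#' given -- i.e. the strata of small, high-surround-density, and
#' low-contrast deposits where detection is hardest.
#'
#' @param max_size_px,min_exterior_density,max_interior_density Optional
#'   bounds.
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(max_size_px = NULL, min_exterior_density = NULL,
                           max_interior_density = NULL) {
  if (is.null(max_size_px) && is.null(min_exterior_density) &&
      is.null(max_interior_density)) {
    stop("condition_spec requires at least one bound")
  }
  structure(list(max_size_px = max_size_px,
                 min_exterior_density = min_exterior_density,
                 max_interior_density = max_interior_density),
            class = "condition_spec")
}

retain_objects <- function(objects, cond) {
  keep <- rep(TRUE, nrow(objects))
  if (!is.null(cond$max_size_px)) keep <- keep & objects$size_px < cond$max_size_px
  if (!is.null(cond$min_exterior_density)) {
    keep <- keep & objects$exterior_density >= cond$min_exterior_density
  }
  if (!is.null(cond$max_interior_density)) {
    keep <- keep & objects$interior_density <= cond$max_interior_density
  }
  keep
}

#' Patient-level conditional detection error rate
#'
#' For each patient, objects failing the condition are excluded; patients
#' with no remaining objects are omitted from the stratum. A retained
#' patient counts as an error iff none of their remaining objects is
#' detected. Reported as mean +/- sample sd (in percent) of the per-patient
#' error indicators, with the number of retained patients.
#'
#' @param patients List of per-patient lists, each with `objects` (feature
#'   data frame) and `labels` (component map).
#' @param preds List of prediction masks aligned with `patients`.
#' @param cond A [condition_spec()].
#' @return List with `error_rate` (percent), `sd` (percent), `n_patients`,
#'   and `errors` (per-patient logical over the retained patients).
#' @export
conditional_error_rate <- function(patients, preds, cond) {
  stopifnot(inherits(cond, "condition_spec"), length(patients) == length(preds))
  indicators <- logical(0)
  for (i in seq_along(patients)) {
    obj <- patients[[i]]$objects
    if (nrow(obj) == 0) next
    keep <- retain_objects(obj, cond)
    if (!any(keep)) next
    det <- patient_detected(preds[[i]], patients[[i]]$labels)$object_detected
    indicators <- c(indicators, !any(det[obj$object_id[keep]]))
  }
  if (length(indicators) == 0) stop("empty condition stratum: all patients omitted")
  list(error_rate = 100 * mean(indicators),
       sd = if (length(indicators) > 1) 100 * sd(indicators) else 0,
       n_patients = length(indicators),
       errors = indicators)
}

#' Fidelity of a virtual-normal image
#'
#' Compares original and virtual images separately over the ground-truth
#' normal breast pixels and the ground-truth abnormal (calcification)
#' pixels: RMSE, PSNR with a 12-bit peak of 4095 (capped at 99 dB for
#' near-zero RMSE), and the error ratio -- the percentage of region pixels
#' whose absolute difference strictly exceeds 1 intensity unit. A good
#' mask-guided inpainter leaves normal pixels untouched (error ratio ~0)
#' while changing most abnormal pixels.
#'
#' @param original,virtual Intensity matrices.
#' @param gt Logical ground-truth mask.
#' @param breast Logical breast-region mask.
#' @return List with `psnr_normal`, `psnr_abnormal` (dB), `rmse_normal`,
#'   `rmse_abnormal`, `error_ratio_normal`, `error_ratio_abnormal`
#'   (percent); abnormal fields are `NA` when the image has no abnormal
#'   pixels.
#' @export
fidelity <- function(original, virtual, gt, breast) {
  assert_same_shape(original, virtual, "original and virtual")
  gt <- as_binary(gt); breast <- as_binary(breast)
  region_stats <- function(sel) {
    if (!any(sel)) {
      return(list(psnr = NA_real_, rmse = NA_real_, error_ratio = NA_real_))
    }
    d <- original[sel] - virtual[sel]
    rmse <- sqrt(mean(d^2))
    psnr <- if (rmse < INTENSITY_MAX * 10^(-99 / 20)) 99 else {
      20 * log10(INTENSITY_MAX / rmse)
    }
    list(psnr = psnr, rmse = rmse, error_ratio = 100 * mean(abs(d) > 1))
  }
  norm <- region_stats(breast & !gt)
  abn <- region_stats(gt)
  list(psnr_normal = norm$psnr, psnr_abnormal = abn$psnr,
       rmse_normal = norm$rmse, rmse_abnormal = abn$rmse,
       error_ratio_normal = norm$error_ratio,
       error_ratio_abnormal = abn$error_ratio)
}
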
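#' Soft Dice loss
#'
#' `1 - (2 |It . Ip| + eps) / (|It| + |Ip| + eps)` with the intersection
#' taken as the sum of elementwise products, so the loss is differentiable
#' in the predicted probabilities.  With `eps > 0` two empty masks give
#' loss 0.
#'
#' @param prob_map numeric array of foreground probabilities in \[0, 1\].
#' @param truth_mask binary array of the same shape.
#' @param eps smoothing constant added to numerator and denominator.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(prob_map, truth_mask, eps = 1e-6) {
  if (!identical(dim(prob_map), dim(truth_mask)) &&
      length(prob_map) != length(truth_mask))
    stop("prob_map and truth_mask shapes differ")
  if (min(prob_map) < 0 || max(prob_map) > 1)
    stop("prob_map values must lie in [0, 1]")
  I <- sum(prob_map * truth_mask)
  U <- sum(prob_map) + sum(truth_mask)
  1 - (2 * I + eps) / (U + eps)
}

#' Pixel confusion counts
#'
#' @param pred_mask,truth_mask binary arrays of identical shape.
#' @return list with integer fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred_mask, truth_mask) {
  p <- as.vector(pred_mask)
  t <- as.vector(truth_mask)
  if (length(p) != length(t)) stop("mask shapes differ")
  if (!all(p %in% c(0, 1))) stop("pred_mask is not binary")
  if (!all(t %in% c(0, 1))) stop("truth_mask is not binary")
  tp <- sum(p == 1 & t == 1)
  fp <- sum(p == 1 & t == 0)
  fn <- sum(p == 0 & t == 1)
  tn <- sum(p == 0 & t == 0)
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Overlap metrics from confusion counts
#'
#' Dice = 2TP / (2TP + FP + FN), IoU = TP / (TP + FP + FN), precision =
#' TP / (TP + FP), specificity = TN / (TN + FP).  An empty denominator
#' returns 1 when both prediction and truth are empty for that quantity
#' (flagged via the `empty` field), else 0.
#'
#' @param cs list from [confusion_counts()].
#' @return list with `dice`, `iou`, `precision`, `specificity`, `empty`.
#' @export
overlap_metrics <- function(cs) {
  safe <- function(num, den, both_empty) {
    if (den == 0) return(if (both_empty) 1 else 0)
    num / den
  }
  both_empty <- (cs$tp + cs$fp + cs$fn) == 0
  list(
    dice = safe(2 * cs$tp, 2 * cs$tp + cs$fp + cs$fn, both_empty),
    iou = safe(cs$tp, cs$tp + cs$fp + cs$fn, both_empty),
    precision = safe(cs$tp, cs$tp + cs$fp, both_empty),
    specificity = safe(cs$tn, cs$tn + cs$fp, (cs$tn + cs$fp) == 0),
    empty = both_empty
  )
}

# boundary pixels: foreground pixels with at least one 4-neighbor outside
# the foreground (image border counts as background)
mask_boundary <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  m & !interior
}

#' 95th-percentile Hausdorff distance
#'
#' For each direction, nearest-neighbor Euclidean distances are computed
#' from every point of one set to the other set and summarized by their
#' 95% quantile (linear interpolation between order statistics); HD95 is
#' the maximum of the two directed values, in pixel units.
#'
#' @param pred_mask,truth_mask binary matrices (H, W).
#' @param backend point sets used: `"boundary"` (default) extracts
#'   foreground boundary pixels by erosion difference; `"foreground"` uses
#'   all foreground pixels.
#' @param q quantile level (0.95).
#' @return distance in pixels, or `NA` with attribute `undefined = TRUE`
#'   when either mask is empty.
#' @export
hd95 <- function(pred_mask, truth_mask, backend = c("boundary", "foreground"),
                 q = 0.95) {
  backend <- match.arg(backend)
  pm <- as.matrix(pred_mask) > 0
  tm <- as.matrix(truth_mask) > 0
  if (!any(pm) || !any(tm)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  if (backend == "boundary") {
    pm <- mask_boundary(pm)
    tm <- mask_boundary(tm)
  }
  A <- which(pm, arr.ind = TRUE) * 1.0
  B <- which(tm, arr.ind = TRUE) * 1.0
  dtp <- stats::quantile(cpp_nn_dists(B, A), q, names = FALSE, type = 7)
  dpt <- stats::quantile(cpp_nn_dists(A, B), q, names = FALSE, type = 7)
  max(dtp, dpt)
}

#' Per-image metric report
#'
#' @param pred_mask,truth_mask binary matrices.
#' @param hd95_backend see [hd95()].
#' @return one-row data.frame with dice, iou, precision, specificity, hd95
#'   (NA when undefined) and the empty-prediction flag.
#' @export
metrics_report <- function(pred_mask, truth_mask, hd95_backend = "boundary") {
  cs <- confusion_counts(pred_mask, truth_mask)
  om <- overlap_metrics(cs)
  h <- hd95(pred_mask, truth_mask, backend = hd95_backend)
  data.frame(dice = om$dice, iou = om$iou, precision = om$precision,
             specificity = om$specificity, hd95 = as.numeric(h),
             hd95_undefined = isTRUE(attr(h, "undefined")),
             empty = om$empty)
}
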
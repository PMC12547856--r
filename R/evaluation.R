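# Detection/segmentation evaluation: IoU, greedy confidence-ordered
# instance matching, precision/recall/F1, all-point-interpolated average
# precision, mAP over IoU thresholds 0.50:0.05:0.95, and a confusion
# matrix with a background row/column.

#' Intersection over union of two masks
#'
#' @param a,b logical matrices of the same shape, not both empty.
#' @return IoU in `[0, 1]`; 1 means perfect overlap, 0 no overlap.
#' @export
mask_iou <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  u <- sum(a | b)
  if (u == 0) stop("mask_iou: both masks are empty")
  sum(a & b) / u
}

#' Match predicted instances to ground truth
#'
#' Greedy matching in descending prediction confidence: each prediction
#' takes the highest-IoU unmatched truth of the same class with IoU at or
#' above the threshold. Each truth and each prediction appears in at most
#' one pair.
#'
#' @param truth,pred [roi_set()]s on the same frame with the same class
#'   list.
#' @param iou_threshold minimum IoU for a true positive (default 0.5, the
#'   usual convention).
#' @return object of class `match_result`: `pairs` (data frame truth_id,
#'   pred_id, iou), `unmatched_truth`, `unmatched_pred`, `iou_threshold`,
#'   and per-set sizes.
#' @export
match_instances <- function(truth, pred, iou_threshold = 0.5) {
  stopifnot(inherits(truth, "roi_set"), inherits(pred, "roi_set"),
            all(truth$image_shape == pred$image_shape),
            identical(truth$classes, pred$classes))
  ord <- order(pred$table$confidence, decreasing = TRUE)
  matched_truth <- rep(FALSE, length(truth))
  pairs <- data.frame(truth_id = integer(), pred_id = integer(), iou = numeric())
  unmatched_pred <- integer()
  for (pi in ord) {
    cand <- which(!matched_truth & truth$table$class_id == pred$table$class_id[pi])
    best <- 0; best_t <- NA_integer_
    for (ti in cand) {
      v <- iou_idx(truth$pixels[[ti]], pred$pixels[[pi]])
      if (v > best) { best <- v; best_t <- ti }
    }
    if (!is.na(best_t) && best >= iou_threshold) {
      matched_truth[best_t] <- TRUE
      pairs <- rbind(pairs, data.frame(truth_id = truth$table$id[best_t],
                                       pred_id = pred$table$id[pi],
                                       iou = best))
    } else {
      unmatched_pred <- c(unmatched_pred, pred$table$id[pi])
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_truth = truth$table$id[!matched_truth],
    unmatched_pred = unmatched_pred,
    iou_threshold = iou_threshold,
    n_truth = length(truth), n_pred = length(pred)
  ), class = "match_result")
}

#' Precision, recall and F1 from a match result
#'
#' TP = matched pairs, FP = unmatched predictions, FN = unmatched truths.
#' Degenerate cases follow the usual conventions: precision (recall) is 0
#' when there are no predictions (truths) but the other side is nonempty,
#' and F1 = 0 when precision + recall = 0.
#'
#' @param match a [match_instances()] result.
#' @return named numeric: `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(match) {
  tp <- nrow(match$pairs)
  fp <- length(match$unmatched_pred)
  fn <- length(match$unmatched_truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else if (fn == 0) 1 else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else if (fp == 0) 1 else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Segmentation "loss" of a match result
#'
#' Reported as `1 - recall` (the fraction of truths missed). The training
#' loss of a neural detector is a different quantity; the name is kept for
#' continuity with recall/loss curve plots and can be disabled.
#'
#' @param match a [match_instances()] result.
#' @param as_loss if FALSE, returns recall instead.
#' @return numeric scalar.
#' @export
segmentation_loss <- function(match, as_loss = TRUE) {
  r <- precision_recall_f1(match)[["recall"]]
  if (as_loss) 1 - r else r
}

# greedy TP/FP flags for one class's detections (internal AP machinery)
ap_flags <- function(truth_pixels, det_pixels, det_conf, iou_threshold) {
  ord <- order(det_conf, decreasing = TRUE)
  used <- rep(FALSE, length(truth_pixels))
  tp <- logical(length(det_pixels))
  for (k in ord) {
    best <- 0; best_t <- NA_integer_
    for (ti in seq_along(truth_pixels)) {
      if (used[ti]) next
      v <- iou_idx(truth_pixels[[ti]], det_pixels[[k]])
      if (v > best) { best <- v; best_t <- ti }
    }
    if (!is.na(best_t) && best >= iou_threshold) {
      used[best_t] <- TRUE
      tp[k] <- TRUE
    }
  }
  tp[ord] # in descending-confidence order
}

#' Average precision for one class
#'
#' Builds the precision-recall curve by sweeping detections in descending
#' confidence and integrates the all-point-interpolated curve (precision
#' envelope), the modern convention of detection tooling. AP is invariant
#' to any strictly increasing rescaling of the confidences.
#'
#' @param truth,pred [roi_set()]s on the same frame.
#' @param class_id class to evaluate (must have at least one truth
#'   instance).
#' @param iou_threshold IoU threshold for a true positive.
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(truth, pred, class_id, iou_threshold = 0.5) {
  t_sel <- which(truth$table$class_id == class_id)
  if (length(t_sel) == 0) {
    stop("average_precision: class ", class_id, " has no truth instances")
  }
  p_sel <- which(pred$table$class_id == class_id)
  if (length(p_sel) == 0) return(0)
  tp <- ap_flags(truth$pixels[t_sel], pred$pixels[p_sel],
                 pred$table$confidence[p_sel], iou_threshold)
  tp_cum <- cumsum(tp)
  fp_cum <- cumsum(!tp)
  recall <- tp_cum / length(t_sel)
  precision <- tp_cum / (tp_cum + fp_cum)
  # all-point interpolation: envelope of precision from the right
  penv <- rev(cummax(rev(precision)))
  r_prev <- c(0, recall[-length(recall)])
  sum((recall - r_prev) * penv)
}

#' Mean average precision over IoU thresholds 0.50 to 0.95
#'
#' AP is averaged over thresholds `seq(0.5, 0.95, by = 0.05)` and then over
#' the classes present in the truth; classes with no truth instance are
#' excluded from the mean.
#'
#' @param truth,pred [roi_set()]s.
#' @param thresholds IoU thresholds (default the 0.50:0.05:0.95 ladder).
#' @return list with `map` (scalar), `per_class` (named vector of
#'   threshold-averaged AP), and `ap50` (named vector of AP at 0.5).
#' @export
map_50_95 <- function(truth, pred, thresholds = seq(0.5, 0.95, by = 0.05)) {
  classes_present <- sort(unique(truth$table$class_id))
  if (length(classes_present) == 0) stop("map_50_95: truth is empty")
  per_class <- vapply(classes_present, function(ci) {
    mean(vapply(thresholds, function(th) {
      average_precision(truth, pred, ci, th)
    }, numeric(1)))
  }, numeric(1))
  ap50 <- vapply(classes_present, function(ci) {
    average_precision(truth, pred, ci, 0.5)
  }, numeric(1))
  names(per_class) <- truth$classes[classes_present]
  names(ap50) <- truth$classes[classes_present]
  list(map = mean(per_class), per_class = per_class, ap50 = ap50)
}

#' Confusion matrix with a background row and column
#'
#' Instances are matched class-agnostically (greedy by confidence, IoU at
#' or above the threshold); a matched pair increments
#' (predicted class, true class); an unmatched truth increments
#' (background, true class); an unmatched prediction increments
#' (predicted class, background). Columns are true classes and rows are
#' predicted classes; every column is normalized to relative frequencies
#' (true-class columns sum to 1 when that class occurs; the background
#' column is normalized over the spurious predictions it contains).
#'
#' @param truth,pred [roi_set()]s.
#' @param iou_threshold IoU threshold (default 0.5).
#' @param normalize set FALSE for raw counts.
#' @return `(C+1) x (C+1)` matrix, last row/column named "background".
#' @export
confusion_matrix <- function(truth, pred, iou_threshold = 0.5,
                             normalize = TRUE) {
  C <- length(truth$classes)
  M <- matrix(0, C + 1, C + 1,
              dimnames = list(predicted = c(truth$classes, "background"),
                              true = c(truth$classes, "background")))
  ord <- order(pred$table$confidence, decreasing = TRUE)
  used <- rep(FALSE, length(truth))
  for (pi in ord) {
    best <- 0; best_t <- NA_integer_
    for (ti in seq_len(length(truth))) {
      if (used[ti]) next
      v <- iou_idx(truth$pixels[[ti]], pred$pixels[[pi]])
      if (v > best) { best <- v; best_t <- ti }
    }
    pc <- pred$table$class_id[pi]
    if (!is.na(best_t) && best >= iou_threshold) {
      used[best_t] <- TRUE
      M[pc, truth$table$class_id[best_t]] <- M[pc, truth$table$class_id[best_t]] + 1
    } else {
      M[pc, C + 1] <- M[pc, C + 1] + 1
    }
  }
  for (ti in which(!used)) {
    tc <- truth$table$class_id[ti]
    M[C + 1, tc] <- M[C + 1, tc] + 1
  }
  if (normalize) {
    cs <- colSums(M)
    nz <- cs > 0
    M[, nz] <- sweep(M[, nz, drop = FALSE], 2, cs[nz], "/")
  }
  M
}
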
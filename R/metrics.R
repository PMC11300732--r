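# Detection / classification evaluation: IoU matching, interpolated-PR
# average precision, mAP@0.5, confusion matrices with a background label,
# sensitivity and balanced accuracy.

#' Intersection over union of two boxes
#'
#' Boxes are `c(x, y, w, h)`, 0-based, half-open.
#'
#' @param box_a,box_b numeric `c(x, y, w, h)` with positive area.
#' @return scalar in `[0, 1]`; 0 for disjoint boxes.
#' @export
iou <- function(box_a, box_b) {
  if (box_a[3] <= 0 || box_a[4] <= 0 || box_b[3] <= 0 || box_b[4] <= 0)
    mcp_stop("boxes must have positive width and height", "invalid_box_error")
  ix <- min(box_a[1] + box_a[3], box_b[1] + box_b[3]) - max(box_a[1], box_b[1])
  iy <- min(box_a[2] + box_a[4], box_b[2] + box_b[4]) - max(box_a[2], box_b[2])
  if (ix <= 0 || iy <= 0) return(0)
  inter <- ix * iy
  inter / (box_a[3] * box_a[4] + box_b[3] * box_b[4] - inter)
}

#' Greedy score-ordered matching of detections to ground truth
#'
#' Detections are visited in descending score order (stable in input order on
#' ties); each is matched to the unmatched ground-truth box of highest IoU.
#' A match with IoU >= the threshold is a true positive; everything else —
#' including duplicates on an already-matched box — is a false positive.
#'
#' @param det_boxes list or n x 4 matrix of detection boxes `c(x, y, w, h)`.
#' @param scores numeric vector of detection scores in `[0, 1]`.
#' @param gt_boxes list or m x 4 matrix of ground-truth boxes.
#' @param iou_threshold IoU acceptance threshold (default 0.5).
#' @return list with `order` (visit order of detections), `tp` (logical, in
#'   visit order), `matched_gt` (gt index per visited detection or NA), and
#'   `undetected_gt` (indices of unmatched ground truth).
#' @export
match_detections <- function(det_boxes, scores, gt_boxes,
                             iou_threshold = 0.5) {
  det_boxes <- as_box_list(det_boxes); gt_boxes <- as_box_list(gt_boxes)
  if (length(scores) != length(det_boxes))
    mcp_stop("one score per detection required", "shape_error")
  ord <- order(-scores)  # stable: ties keep input order
  gt_taken <- rep(FALSE, length(gt_boxes))
  tp <- logical(length(ord)); matched <- rep(NA_integer_, length(ord))
  for (i in seq_along(ord)) {
    d <- det_boxes[[ord[i]]]
    best <- 0; best_j <- NA_integer_
    for (j in seq_along(gt_boxes)) {
      if (gt_taken[j]) next
      v <- iou(d, gt_boxes[[j]])
      if (v > best) { best <- v; best_j <- j }
    }
    if (!is.na(best_j) && best >= iou_threshold) {
      tp[i] <- TRUE; matched[i] <- best_j; gt_taken[best_j] <- TRUE
    }
  }
  list(order = ord, tp = tp, matched_gt = matched,
       undetected_gt = which(!gt_taken))
}

as_box_list <- function(x) {
  if (is.list(x)) return(x)
  if (is.null(x) || length(x) == 0L) return(list())
  if (is.matrix(x)) return(lapply(seq_len(nrow(x)), function(i) x[i, ]))
  list(x)
}

#' Average precision from score-ordered TP/FP flags
#'
#' Area under the interpolated precision-recall curve: the precision envelope
#' is made monotonically non-increasing (all-point interpolation) and
#' integrated over recall.
#'
#' @param tp logical vector of TP flags in descending score order.
#' @param n_gt number of ground-truth instances of the class (> 0).
#' @return AP in `[0, 1]`; no detections give 0.
#' @export
average_precision <- function(tp, n_gt) {
  if (n_gt <= 0)
    mcp_stop("AP undefined for a class with no ground truth",
             "undefined_ap_error")
  if (length(tp) == 0L) return(0)
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / n_gt
  envelope <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * envelope)
}

#' Mean average precision over classes
#'
#' @param aps numeric vector of per-class APs; `NA` marks classes skipped for
#'   lack of ground truth.
#' @return unweighted mean of the defined APs.
#' @export
mean_ap <- function(aps) {
  ok <- aps[!is.na(aps)]
  if (length(ok) == 0L)
    mcp_stop("no class has a defined AP", "undefined_ap_error")
  mean(ok)
}

#' Confusion matrix with a background label
#'
#' Localization matching is class-agnostic (greedy by score, IoU >= threshold,
#' per image) so class swaps land in off-diagonal cells. Each matched pair
#' increments (gt class, predicted class); undetected ground truth increments
#' (gt class, background); unmatched detections increment (background,
#' predicted class).
#'
#' @param detections data frame: `image_id`, `category_id`, `x`, `y`, `w`,
#'   `h`, `score`.
#' @param gt data frame: `image_id`, `category_id`, `x`, `y`, `w`, `h`.
#' @param categories data frame with `id`, `name` (class universe).
#' @param iou_threshold IoU acceptance threshold.
#' @return `(M+1) x (M+1)` integer matrix, rows = ground truth, columns =
#'   prediction, last row/column named `"background"`.
#' @export
confusion_with_background <- function(detections, gt, categories,
                                      iou_threshold = 0.5) {
  labels <- c(categories$name, "background")
  m <- length(labels)
  cm <- matrix(0L, m, m, dimnames = list(truth = labels, prediction = labels))
  name_of <- stats::setNames(categories$name, as.character(categories$id))
  for (img in unique(c(detections$image_id, gt$image_id))) {
    d <- detections[detections$image_id == img, , drop = FALSE]
    g <- gt[gt$image_id == img, , drop = FALSE]
    res <- match_detections(as.matrix(d[, c("x", "y", "w", "h")]), d$score,
                            as.matrix(g[, c("x", "y", "w", "h")]),
                            iou_threshold)
    for (i in seq_along(res$order)) {
      pred_cls <- name_of[[as.character(d$category_id[res$order[i]])]]
      if (res$tp[i]) {
        true_cls <- name_of[[as.character(g$category_id[res$matched_gt[i]])]]
        cm[true_cls, pred_cls] <- cm[true_cls, pred_cls] + 1L
      } else {
        cm["background", pred_cls] <- cm["background", pred_cls] + 1L
      }
    }
    for (j in res$undetected_gt) {
      true_cls <- name_of[[as.character(g$category_id[j])]]
      cm[true_cls, "background"] <- cm[true_cls, "background"] + 1L
    }
  }
  cm
}

#' Per-class and overall balanced accuracy from a confusion matrix
#'
#' One-vs-rest per class: sensitivity `TP / (TP + FN)`, specificity
#' `TN / (TN + FP)`, balanced accuracy their mean; overall is the unweighted
#' mean over classes. With `include_background = FALSE` the background
#' row/column is removed first, so only classification of detected objects is
#' scored.
#'
#' @param cm square confusion matrix (rows = truth, cols = prediction); a
#'   background row/column, if present, must be last.
#' @param include_background keep the background row/column (default `TRUE`)?
#' @return list with `per_class` (named vector; `NA` for classes absent from
#'   both axes), `sensitivity`, `specificity`, and `overall`.
#' @export
balanced_accuracy <- function(cm, include_background = TRUE) {
  if (nrow(cm) != ncol(cm)) mcp_stop("confusion matrix must be square",
                                     "shape_error")
  if (!include_background) {
    keep <- seq_len(nrow(cm) - 1L)
    cm <- cm[keep, keep, drop = FALSE]
  }
  total <- sum(cm)
  labels <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  sens <- spec <- ba <- stats::setNames(rep(NA_real_, nrow(cm)), labels)
  for (c in seq_len(nrow(cm))) {
    tp <- cm[c, c]; fn <- sum(cm[c, ]) - tp; fp <- sum(cm[, c]) - tp
    tn <- total - tp - fn - fp
    if (tp + fn == 0 && fp == 0) next  # class absent from both axes
    sens[c] <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec[c] <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ba[c] <- mean(c(sens[c], spec[c]), na.rm = TRUE)
  }
  if (anyNA(ba))
    mcp_warn("class(es) with no ground truth and no predictions excluded",
             "undefined_class_warning")
  list(per_class = ba, sensitivity = sens, specificity = spec,
       overall = mean(ba, na.rm = TRUE))
}

#' Detection sensitivity (single merged class)
#'
#' Fraction of all ground-truth nuclei that were detected, regardless of
#' class — the detection-only view of performance.
#'
#' @param tp_count number of matched (true positive) detections.
#' @param n_gt total ground-truth instances (> 0).
#' @return scalar `tp_count / n_gt`.
#' @export
detection_sensitivity <- function(tp_count, n_gt) {
  if (n_gt <= 0) mcp_stop("sensitivity undefined with no ground truth",
                          "empty_dataset_error")
  tp_count / n_gt
}

#' Full detection evaluation report
#'
#' Per-class AP at the given IoU threshold (per-class matching), mAP,
#' class-agnostic confusion matrix with background, balanced accuracies with
#' and without background, and overall detection sensitivity.
#'
#' @inheritParams confusion_with_background
#' @return list: `per_class_ap`, `map`, `confusion`, `balanced_accuracy`,
#'   `balanced_accuracy_no_background`, `sensitivity`, `n_gt`, `n_detections`.
#' @export
evaluate_detections <- function(detections, gt, categories,
                                iou_threshold = 0.5) {
  aps <- stats::setNames(rep(NA_real_, nrow(categories)), categories$name)
  for (k in seq_len(nrow(categories))) {
    cid <- categories$id[k]
    g <- gt[gt$category_id == cid, , drop = FALSE]
    if (nrow(g) == 0L) next
    d <- detections[detections$category_id == cid, , drop = FALSE]
    # match per image, then rank all of the class's detections globally
    sc <- numeric(0); fl <- logical(0)
    for (img in unique(d$image_id)) {
      di <- d[d$image_id == img, , drop = FALSE]
      gi <- g[g$image_id == img, , drop = FALSE]
      res <- match_detections(as.matrix(di[, c("x", "y", "w", "h")]),
                              di$score,
                              as.matrix(gi[, c("x", "y", "w", "h")]),
                              iou_threshold)
      sc <- c(sc, di$score[res$order]); fl <- c(fl, res$tp)
    }
    aps[k] <- average_precision(fl[order(-sc)], nrow(g))
  }
  cm <- confusion_with_background(detections, gt, categories, iou_threshold)
  n_gt <- nrow(gt)
  tp_total <- n_gt - sum(cm[seq_len(nrow(cm) - 1L), "background"])
  list(per_class_ap = aps, map = mean_ap(aps), confusion = cm,
       balanced_accuracy = balanced_accuracy(cm, TRUE),
       balanced_accuracy_no_background = balanced_accuracy(cm, FALSE),
       sensitivity = detection_sensitivity(tp_total, n_gt),
       n_gt = n_gt, n_detections = nrow(detections))
}
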
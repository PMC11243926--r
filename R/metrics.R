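# Object-detection evaluation: IoU box overlap, confusion counts under the
# greedy confidence-ordered matching convention, precision/recall/F1, and
# average precision as the area under the monotone precision envelope.

#' Intersection over union of two boxes
#'
#' Ratio of the intersection area to the union area, in pixels squared.
#' Disjoint boxes give 0, identical boxes 1.
#'
#' @param a,b [rect()]s (or `[x, y, w, h]` vectors).
#' @return A value in \[0, 1\].
#' @export
iou <- function(a, b) {
  a <- as_rect(a); b <- as_rect(b)
  iw <- max(0, min(a$x + a$width, b$x + b$width) - max(a$x, b$x))
  ih <- max(0, min(a$y + a$height, b$y + b$height) - max(a$y, b$y))
  inter <- as.numeric(iw) * ih
  union <- rect_area(a) + rect_area(b) - inter
  inter / union
}

#' Confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integers. `tn` is kept for completeness
#'   but is always 0 in detection evaluation (the background is not a
#'   countable negative class).
#' @return An object of class `lt_confusion`.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L, tn = 0L) {
  if (any(c(tp, fp, fn, tn) < 0L)) lt_value_error("counts must be >= 0")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "lt_confusion")
}

#' Match predictions to ground truth and count TP/FP/FN
#'
#' Per class, predictions are taken in order of descending confidence; each
#' claims the unmatched ground-truth box of the same class with the highest
#' IoU, provided that IoU reaches the threshold (a true positive), and is a
#' false positive otherwise. Ground-truth boxes left unmatched are false
#' negatives. This is the greedy matching convention of the YOLO ecosystem.
#'
#' @param preds An [detections()] table.
#' @param gts A data frame with columns `label`, `x`, `y`, `width`,
#'   `height` (ground-truth boxes).
#' @param iou_threshold Minimum IoU for a match (default 0.5).
#' @return An [confusion_counts()]; always satisfies
#'   `tp + fn == nrow(gts)` and `tp + fp == nrow(preds)`.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  if (iou_threshold < 0 || iou_threshold > 1) {
    lt_value_error("iou_threshold must lie in [0, 1]")
  }
  m <- match_pairs(preds, gts, iou_threshold)
  confusion_counts(tp = sum(m$matched), fp = sum(!m$matched),
                   fn = nrow(gts) - sum(m$matched))
}

# greedy per-class matching; returns, in descending-confidence order, a
# data frame of predictions with their matched flag and confidence
match_pairs <- function(preds, gts, iou_threshold) {
  n <- nrow(preds)
  ord <- if (n > 0L) order(-preds$confidence) else integer()
  matched <- logical(n)
  gt_taken <- logical(nrow(gts))
  for (k in ord) {
    cls <- preds$label[k]
    cand <- which(!gt_taken & gts$label == cls)
    if (length(cand) == 0L) next
    ious <- vapply(cand, function(j) {
      iou(det_box(preds, k), rect(gts$x[j], gts$y[j], gts$width[j], gts$height[j]))
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched[k] <- TRUE
      gt_taken[cand[best]] <- TRUE
    }
  }
  data.frame(order = ord, matched = matched[ord],
             confidence = preds$confidence[ord])
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR / (P + R)`. A zero denominator yields 0 for that quantity and
#' sets the `degenerate` flag rather than raising.
#'
#' @param counts An [confusion_counts()].
#' @return A list with `precision`, `recall`, `f1` and logical `degenerate`.
#' @export
precision_recall_f1 <- function(counts) {
  degenerate <- FALSE
  precision <- if (counts$tp + counts$fp > 0L) {
    counts$tp / (counts$tp + counts$fp)
  } else {
    degenerate <- TRUE; 0
  }
  recall <- if (counts$tp + counts$fn > 0L) {
    counts$tp / (counts$tp + counts$fn)
  } else {
    degenerate <- TRUE; 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    degenerate <- TRUE; 0
  }
  list(precision = precision, recall = recall, f1 = f1,
       degenerate = degenerate)
}

#' Average precision from a set of precision-recall points
#'
#' The precision curve is first made monotone non-increasing in recall (the
#' envelope `p_env(r) = max{p_j : r_j >= r}`), then integrated exactly over
#' recall in \[0, 1\] (all-point interpolation). Recall not covered by any
#' point contributes zero area beyond the largest recall; the first
#' precision extends down to recall 0.
#'
#' @param points A data frame with columns `recall` and `precision` (an
#'   optional `threshold` column is ignored here).
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(points) {
  if (is.null(points) || nrow(points) == 0L) {
    lt_value_error("average_precision requires at least one PR point")
  }
  if (any(points$recall < 0 | points$recall > 1 |
          points$precision < 0 | points$precision > 1)) {
    lt_value_error("PR points must lie in [0, 1]")
  }
  o <- order(points$recall, points$precision)
  r <- points$recall[o]
  p <- points$precision[o]
  penv <- rev(cummax(rev(p)))
  keep <- !duplicated(r)   # first occurrence carries the suffix max
  r <- r[keep]; penv <- penv[keep]
  sum(diff(c(0, r)) * penv)
}

#' Precision-recall curve for one class
#'
#' Sweeps the confidence threshold over the predictions (descending),
#' cumulating true and false positives under the same greedy matching as
#' [match_detections()], yielding one PR point per prediction.
#'
#' @inheritParams match_detections
#' @return A data frame with columns `recall`, `precision`, `threshold`.
#' @export
pr_curve <- function(preds, gts, iou_threshold = 0.5) {
  m <- match_pairs(preds, gts, iou_threshold)
  if (nrow(m) == 0L || nrow(gts) == 0L) {
    return(data.frame(recall = numeric(), precision = numeric(),
                      threshold = numeric()))
  }
  tp_cum <- cumsum(m$matched)
  fp_cum <- cumsum(!m$matched)
  data.frame(recall = tp_cum / nrow(gts),
             precision = tp_cum / (tp_cum + fp_cum),
             threshold = m$confidence)
}

#' Mean average precision over classes
#'
#' The arithmetic mean of per-class AP values.
#'
#' @param aps A named numeric vector (or list) of per-class APs.
#' @return mAP in \[0, 1\].
#' @export
mean_average_precision <- function(aps) {
  aps <- unlist(aps)
  if (length(aps) == 0L) lt_value_error("mean_average_precision requires >= 1 class")
  mean(aps)
}

#' Per-class AP at one IoU threshold
#'
#' @inheritParams match_detections
#' @param classes Classes to evaluate (default: those present in `gts`).
#' @return Named numeric vector of APs; a class with ground truth but no
#'   predictions scores 0.
#' @export
ap_by_class <- function(preds, gts, iou_threshold = 0.5,
                        classes = sort(unique(gts$label))) {
  vapply(classes, function(cls) {
    g <- gts[gts$label == cls, , drop = FALSE]
    p <- preds[preds$label == cls, , drop = FALSE]
    if (nrow(g) == 0L) return(NA_real_)
    pts <- pr_curve(p, g, iou_threshold)
    if (nrow(pts) == 0L) return(0)
    average_precision(pts)
  }, numeric(1))
}

#' Detection evaluation summary table
#'
#' Per-class precision, recall, AP at IoU 0.5 and AP averaged over IoU
#' thresholds 0.50 to 0.95 in steps of 0.05, plus an ALL row with the means
#' (mAP). Precision and recall are computed at the given confidence and IoU
#' thresholds.
#'
#' @inheritParams match_detections
#' @param conf_threshold Confidence cut for the P/R columns (default 0.5).
#' @return A data frame with columns `class`, `n_gt`, `precision`,
#'   `recall`, `ap50`, `ap50_95`.
#' @export
evaluate_detections <- function(preds, gts, conf_threshold = 0.5,
                                iou_threshold = 0.5) {
  classes <- sort(unique(gts$label))
  kept <- filter_detections(preds, conf_threshold)
  thr_range <- seq(0.5, 0.95, by = 0.05)
  rows <- lapply(classes, function(cls) {
    g <- gts[gts$label == cls, , drop = FALSE]
    p <- kept[kept$label == cls, , drop = FALSE]
    prf <- precision_recall_f1(match_detections(p, g, iou_threshold))
    p_all <- preds[preds$label == cls, , drop = FALSE]
    ap50 <- ap_by_class(p_all, g, 0.5, cls)
    ap_multi <- mean(vapply(thr_range, function(t) {
      ap_by_class(p_all, g, t, cls)
    }, numeric(1)))
    data.frame(class = cls, n_gt = nrow(g), precision = prf$precision,
               recall = prf$recall, ap50 = unname(ap50),
               ap50_95 = ap_multi, stringsAsFactors = FALSE)
  })
  tbl <- do.call(rbind, rows)
  all_row <- data.frame(class = "ALL", n_gt = sum(tbl$n_gt),
                        precision = mean(tbl$precision),
                        recall = mean(tbl$recall),
                        ap50 = mean(tbl$ap50),
                        ap50_95 = mean(tbl$ap50_95),
                        stringsAsFactors = FALSE)
  rbind(tbl, all_row)
}
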
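#' Object-detection evaluation: IoU, precision/recall, interpolated mAP
#'
#' Implements the standard detection metrics: intersection over union of
#' half-open integer boxes, greedy confidence-ordered matching against
#' ground truth at an IoU threshold (one ground truth matches at most one
#' prediction, VOC-style), precision interpolated as the suffix-maximum
#' over a 101-point recall grid (0.00 to 1.00 in steps of 0.01), average
#' precision as the grid mean, and the aggregate mAP at 0.5 and averaged
#' over thresholds 0.50:0.95 in steps of 0.05 (COCO-style).
#'
#' @name detection-metrics
NULL

#' Construct a detection
#'
#' @param box a [bbox()]
#' @param confidence score in `[0, 1]`
#' @param class class label (default `"plant"`)
#' @return object of class `detection`
#' @export
detection <- function(box, confidence, class = "plant") {
  stopifnot(inherits(box, "bbox"), confidence >= 0, confidence <= 1)
  structure(list(box = box, confidence = confidence,
                 class = as.character(class)), class = "detection")
}

#' Intersection over union of two boxes
#'
#' Areas follow the half-open convention: a box `[x0,x1) x [y0,y1)` covers
#' `(x1-x0)*(y1-y0)` pixels. Disjoint boxes have IoU 0.
#'
#' @param a,b [bbox()] objects
#' @return fraction in `[0, 1]`
#' @export
iou <- function(a, b) {
  iw <- min(a$x1, b$x1) - max(a$x0, b$x0)
  ih <- min(a$y1, b$y1) - max(a$y0, b$y0)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- as.numeric(iw) * ih
  inter / (bbox_area(a) + bbox_area(b) - inter)
}

#' Greedily match predictions to ground-truth boxes
#'
#' Predictions are taken in order of descending confidence (ties broken by
#' input order); each is matched to the not-yet-matched ground truth with
#' the highest IoU, provided that IoU is at least the threshold. Matched
#' predictions are true positives, the rest false positives; unmatched
#' ground truths are false negatives.
#'
#' @param preds list of [detection()]s
#' @param gts list of ground-truth [bbox()]s
#' @param iou_threshold matching threshold in `(0, 1)`
#' @return list of class `match_result`: `tp`, `fp`, `fn` counts;
#'   `pred_matched` (per-prediction logical, confidence-sorted order);
#'   `order` (the confidence sort permutation); `pairs` (data.frame of
#'   matched pred/gt indices and IoU)
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold < 1)
  np <- length(preds)
  ng <- length(gts)
  if (np == 0L) {
    return(structure(list(tp = 0L, fp = 0L, fn = ng,
                          pred_matched = logical(0), order = integer(0),
                          pairs = data.frame(pred = integer(0),
                                             gt = integer(0),
                                             iou = numeric(0))),
                     class = "match_result"))
  }
  conf <- vapply(preds, function(p) p$confidence, numeric(1))
  ord <- order(-conf)
  gt_taken <- rep(FALSE, ng)
  matched <- logical(np)
  pairs <- list()
  for (i in seq_len(np)) {
    p <- preds[[ord[i]]]
    best <- 0L
    best_iou <- -1
    for (j in seq_len(ng)) {
      if (gt_taken[j]) next
      v <- iou(p$box, gts[[j]])
      if (v >= iou_threshold && v > best_iou) {
        best <- j
        best_iou <- v
      }
    }
    if (best > 0L) {
      gt_taken[best] <- TRUE
      matched[i] <- TRUE
      pairs[[length(pairs) + 1L]] <- data.frame(pred = ord[i], gt = best,
                                                iou = best_iou)
    }
  }
  structure(list(
    tp = sum(matched), fp = sum(!matched), fn = sum(!gt_taken),
    pred_matched = matched, order = ord,
    pairs = if (length(pairs)) do.call(rbind, pairs) else
      data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  ), class = "match_result")
}

#' The 101-point recall grid used for precision interpolation
#'
#' @return numeric vector `0.00, 0.01, ..., 1.00` (101 values)
#' @export
recall_grid <- function() seq(0, 1, by = 0.01)

#' Interpolated precision over a recall grid
#'
#' At each grid recall `r`, the interpolated precision is the maximum
#' precision among observed points whose recall is at least `r` (0 when
#' there is none), which makes the precision-recall curve monotone
#' non-increasing.
#'
#' @param pr_points data.frame with columns `recall` and `precision`
#' @param grid recall grid (default [recall_grid()])
#' @return numeric vector of interpolated precision, one per grid value
#' @export
interpolated_precision <- function(pr_points, grid = recall_grid()) {
  vapply(grid, function(r) {
    keep <- pr_points$recall >= r - 1e-12
    if (!any(keep)) 0 else max(pr_points$precision[keep])
  }, numeric(1))
}

# PR staircase: one (recall, precision) point per prediction prefix in
# confidence order, using greedy matching of the full prediction set
pr_curve <- function(preds, gts, iou_threshold) {
  m <- match_detections(preds, gts, iou_threshold)
  ng <- length(gts)
  if (length(m$pred_matched) == 0L || ng == 0L) {
    return(data.frame(recall = numeric(0), precision = numeric(0)))
  }
  tp_cum <- cumsum(m$pred_matched)
  k <- seq_along(tp_cum)
  data.frame(recall = tp_cum / ng, precision = tp_cum / k)
}

#' Average precision at one IoU threshold
#'
#' Mean of the interpolated precision over the 101-point recall grid.
#' With no ground truths and no predictions the value is defined as 0
#' (with a warning).
#'
#' @inheritParams match_detections
#' @return AP in `[0, 1]`
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5) {
  if (length(gts) == 0L && length(preds) == 0L) {
    warning("no ground truths and no predictions: AP defined as 0")
    return(0)
  }
  pr <- pr_curve(preds, gts, iou_threshold)
  mean(interpolated_precision(pr))
}

#' The COCO threshold sweep 0.50, 0.55, ..., 0.95
#' @return numeric vector of 10 thresholds
#' @export
coco_thresholds <- function() seq(0.5, 0.95, by = 0.05)

#' Full detection evaluation report
#'
#' Computes AP at each requested IoU threshold, `map50` (AP at 0.5),
#' `map5095` (mean AP over the 0.50:0.95 sweep), and the operating-point
#' precision and recall using all predictions at IoU 0.5.
#'
#' @inheritParams match_detections
#' @param thresholds IoU thresholds (default [coco_thresholds()])
#' @return list of class `eval_report` with fields `precision`, `recall`,
#'   `ap_by_threshold`, `map50`, `map5095`, `n_pred`, `n_gt`
#' @export
evaluate <- function(preds, gts, thresholds = coco_thresholds()) {
  stopifnot(length(thresholds) >= 1L)
  ap <- vapply(thresholds, function(t) {
    suppressWarnings(average_precision(preds, gts, t))
  }, numeric(1))
  names(ap) <- sprintf("%.2f", thresholds)
  m50 <- match_detections(preds, gts, 0.5)
  precision <- if (m50$tp + m50$fp > 0L) m50$tp / (m50$tp + m50$fp) else 0
  recall <- if (m50$tp + m50$fn > 0L) m50$tp / (m50$tp + m50$fn) else 0
  map50 <- if ("0.50" %in% names(ap)) unname(ap["0.50"]) else
    suppressWarnings(average_precision(preds, gts, 0.5))
  structure(list(
    precision = precision, recall = recall, ap_by_threshold = ap,
    map50 = map50, map5095 = mean(ap),
    n_pred = length(preds), n_gt = length(gts)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(format_eval_report(x), sep = "\n")
  invisible(x)
}

#' Format an evaluation report as a plain-text table
#'
#' @param x an `eval_report`
#' @param dataset row label (default `"-"`)
#' @return character vector of lines
#' @export
format_eval_report <- function(x, dataset = "-") {
  c(sprintf("%-20s %9s %9s %9s %12s", "Dataset", "Precision", "Recall",
            "mAP@0.5", "mAP@0.5:0.95"),
    sprintf("%-20s %9.3f %9.3f %9.3f %12.3f", dataset, x$precision,
            x$recall, x$map50, x$map5095))
}

#' Serialize an evaluation report to JSON
#'
#' @param x an `eval_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_eval_report <- function(x, path) {
  jsonlite::write_json(list(
    precision = x$precision, recall = x$recall,
    ap_by_threshold = as.list(x$ap_by_threshold),
    map50 = x$map50, map5095 = x$map5095,
    n_pred = x$n_pred, n_gt = x$n_gt
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
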
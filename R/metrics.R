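# Detection and counting evaluation.
#
# Detection metrics follow the COCO conventions: greedy score-ordered
# matching at a fixed IoU threshold, 101-point interpolated average
# precision, AP averaged over IoU 0.50..0.95 (step 0.05), and
# size-stratified AP with ignore semantics for out-of-class matches.
# Counting metrics are the standard stand-count regression quantities:
#   R^2   = 1 - sum((m - p)^2) / sum((m - mean(m))^2)
#   RMSE  = sqrt(mean((m - p)^2))
#   MAE   = mean(|m - p|)
#   MAPE  = mean(|m - p| / m) * 100

#' Size-class thresholds and classification
#'
#' Small objects have box area at most `32^2 = 1024` px^2; medium objects
#' up to `96^2 = 9216` px^2; anything larger is large. The partition is
#' exhaustive and mutually exclusive for every positive-area box.
#'
#' @param areas Numeric vector of box areas (px^2), or a `n x 4` box matrix
#'   whose areas are computed first.
#' @param small_max_area,medium_max_area Class boundaries (inclusive).
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
size_class <- function(areas, small_max_area = 1024, medium_max_area = 9216) {
  if (is.matrix(areas)) areas <- box_area(areas)
  if (any(areas <= 0)) stop("box areas must be positive")
  cls <- ifelse(areas <= small_max_area, "small",
                ifelse(areas <= medium_max_area, "medium", "large"))
  factor(cls, levels = c("small", "medium", "large"))
}

#' Match detections against ground truth at one IoU threshold
#'
#' Detections are processed in descending score order; each is matched to
#' the not-yet-matched ground-truth box of highest IoU provided that IoU
#' reaches the threshold, otherwise it is a false positive. Unmatched
#' ground truths are false negatives.
#'
#' @param truth_boxes `n x 4` matrix of ground-truth boxes.
#' @param dets A [detection_set()].
#' @param iou_threshold Threshold in `(0, 1)`.
#' @return Object of class `match_result`: `list(TP, FP, FN, matched,
#'   matched_truth)` where `matched` flags each detection in score order and
#'   `matched_truth` gives the matched truth index (NA for false positives).
#' @export
match_detections <- function(truth_boxes, dets, iou_threshold = 0.5) {
  truth_boxes <- matrix(as.numeric(truth_boxes), ncol = 4)
  if (iou_threshold <= 0 || iou_threshold >= 1) {
    stop("iou_threshold must lie in (0, 1)")
  }
  if (nrow(truth_boxes) > 0 &&
      (any(truth_boxes[, 3] <= truth_boxes[, 1]) ||
       any(truth_boxes[, 4] <= truth_boxes[, 2]))) {
    stop("invalid ground-truth box")
  }
  nd <- length(dets); nt <- nrow(truth_boxes)
  matched <- logical(nd); matched_truth <- rep(NA_integer_, nd)
  if (nd > 0 && nt > 0) {
    iou <- box_iou(dets$boxes, truth_boxes)
    used <- logical(nt)
    for (i in seq_len(nd)) {          # dets already score-sorted
      cand <- which(!used & iou[i, ] >= iou_threshold)
      if (length(cand)) {
        best <- cand[which.max(iou[i, cand])]
        matched[i] <- TRUE
        matched_truth[i] <- best
        used[best] <- TRUE
      }
    }
  }
  tp <- sum(matched)
  structure(list(TP = tp, FP = nd - tp, FN = nt - tp,
                 matched = matched, matched_truth = matched_truth,
                 n_truth = nt),
            class = "match_result")
}

# AP from score-ordered TP flags and a ground-truth count.
# interpolation: "coco101" (101-point interpolated mean) or "trapezoid"
# (area under the precision envelope).
ap_from_flags <- function(flags, n_truth, interpolation = "coco101") {
  if (n_truth == 0) {
    warning("no ground-truth objects: recall undefined, AP reported as 0")
    return(list(ap = 0, curve = data.frame(recall = numeric(0),
                                           precision = numeric(0))))
  }
  if (length(flags) == 0) {
    return(list(ap = 0,
                curve = data.frame(recall = 0, precision = 0)))
  }
  ctp <- cumsum(flags)
  recall <- ctp / n_truth
  precision <- ctp / seq_along(flags)
  # ceiling-to-the-right envelope: p_env(r) = max_{r' >= r} precision(r')
  p_env <- rev(cummax(rev(precision)))
  grid <- seq(0, 1, by = 0.01)
  p_at <- vapply(grid, function(r) {
    idx <- which(recall >= r)
    if (length(idx)) p_env[idx[1]] else 0
  }, numeric(1))
  ap <- if (interpolation == "coco101") {
    mean(p_at)
  } else {
    rr <- c(0, recall); pp <- c(p_env[1], p_env)
    sum(diff(rr) * pp[-1])
  }
  list(ap = ap, curve = data.frame(recall = grid, precision = p_at))
}

#' Precision-recall curve and average precision
#'
#' @param truth_boxes `n x 4` ground-truth box matrix.
#' @param dets A [detection_set()].
#' @param iou_threshold Matching threshold.
#' @param interpolation `"coco101"` (default; 101-point interpolated mean)
#'   or `"trapezoid"` (raw area under the precision envelope).
#' @return `list(ap, recall, precision, curve)`: `recall`/`precision` are the
#'   endpoint values TP/(TP+FN) and TP/(TP+FP); `curve` the interpolated PR
#'   curve on the recall grid 0, 0.01, ..., 1.
#' @export
pr_and_ap <- function(truth_boxes, dets, iou_threshold = 0.5,
                      interpolation = c("coco101", "trapezoid")) {
  interpolation <- match.arg(interpolation)
  mr <- match_detections(truth_boxes, dets, iou_threshold)
  res <- ap_from_flags(mr$matched, mr$n_truth, interpolation)
  nd <- length(mr$matched)
  list(ap = res$ap,
       recall = if (mr$n_truth > 0) mr$TP / (mr$TP + mr$FN) else NA_real_,
       precision = if (nd > 0) mr$TP / (mr$TP + mr$FP) else NA_real_,
       curve = res$curve)
}

#' Average precision over the IoU threshold sweep 0.50 to 0.95
#'
#' @param ap_by_threshold Numeric vector of exactly 10 AP values at IoU
#'   0.50, 0.55, ..., 0.95.
#' @return Their arithmetic mean.
#' @export
ap_range <- function(ap_by_threshold) {
  if (length(ap_by_threshold) != 10L) {
    stop("expected exactly 10 AP values (IoU 0.50 to 0.95, step 0.05)")
  }
  mean(ap_by_threshold)
}

#' Full AP sweep for one image set
#'
#' @param truth_boxes Ground-truth boxes (one pooled matrix).
#' @param dets A [detection_set()].
#' @param thresholds IoU thresholds (default the COCO sweep).
#' @return `list(ap50_95, by_threshold)`.
#' @export
ap_sweep <- function(truth_boxes, dets,
                     thresholds = seq(0.5, 0.95, by = 0.05)) {
  aps <- vapply(thresholds, function(th) {
    pr_and_ap(truth_boxes, dets, th)$ap
  }, numeric(1))
  list(ap50_95 = mean(aps), by_threshold = stats::setNames(aps, thresholds))
}

#' Size-stratified average precision
#'
#' AP restricted to ground truths of one size class, with COCO ignore
#' semantics: a detection matched to an out-of-class ground truth is
#' removed from the ranking (neither TP nor FP) rather than penalised.
#'
#' @param truth_boxes `n x 4` ground-truth box matrix.
#' @param dets A [detection_set()].
#' @param iou_threshold Matching threshold (default 0.5).
#' @param interpolation See [pr_and_ap()].
#' @return `list(AP_S, AP_M)`; a class with no ground truths yields `NA` for
#'   that entry (flagged via a message attribute rather than a fake zero).
#' @export
ap_by_size <- function(truth_boxes, dets, iou_threshold = 0.5,
                       interpolation = "coco101") {
  truth_boxes <- matrix(as.numeric(truth_boxes), ncol = 4)
  cls <- size_class(truth_boxes)
  mr <- match_detections(truth_boxes, dets, iou_threshold)
  one_class <- function(kls) {
    in_class <- cls == kls
    if (!any(in_class)) return(NA_real_)
    # drop detections matched to out-of-class truths (ignored); every
    # remaining matched detection is then matched to an in-class truth
    ignored <- !is.na(mr$matched_truth) & !in_class[mr$matched_truth]
    flags <- mr$matched[!ignored]
    ap_from_flags(flags, sum(in_class), interpolation)$ap
  }
  list(AP_S = one_class("small"), AP_M = one_class("medium"))
}

#' Stand-count regression metrics
#'
#' @param truth Integer vector of per-image true counts `m_i`.
#' @param predicted Integer vector of per-image predicted counts `p_i`.
#' @return `list(R2, RMSE, MAE, MAPE)`. `R2` is `NA` when all true counts
#'   are equal (zero variance); `MAPE` is `NA` when any true count is zero.
#'   MAPE is reported in percent.
#' @export
count_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted) || length(truth) < 1) {
    stop("truth and predicted must be equal-length, non-empty vectors")
  }
  if (any(truth < 0) || any(predicted < 0)) stop("counts must be non-negative")
  err <- truth - predicted
  n <- length(truth)
  rmse <- sqrt(sum(err^2) / n)
  mae <- sum(abs(err)) / n
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot == 0) {
    warning("all true counts equal: R^2 undefined")
    NA_real_
  } else 1 - sum(err^2) / ss_tot
  mape <- if (any(truth == 0)) {
    warning("zero true count present: MAPE undefined")
    NA_real_
  } else mean(abs(err) / truth) * 100
  list(R2 = r2, RMSE = rmse, MAE = mae, MAPE = mape)
}

#' Assemble a one-row metrics report
#'
#' Mirrors the usual benchmark-table layout (recall, AP50:95, size-stratified
#' AP, counting metrics) for one evaluated model.
#'
#' @param truth_boxes,dets Detection evaluation inputs (pooled over images).
#' @param truth_counts,predicted_counts Per-image counting series (optional).
#' @return One-row data.frame.
#' @export
metrics_report <- function(truth_boxes, dets, truth_counts = NULL,
                           predicted_counts = NULL) {
  sw <- ap_sweep(truth_boxes, dets)
  pr <- pr_and_ap(truth_boxes, dets, 0.5)
  sz <- ap_by_size(truth_boxes, dets)
  row <- data.frame(recall = pr$recall, AP50 = sw$by_threshold[["0.5"]],
                    AP50_95 = sw$ap50_95, AP_S = sz$AP_S, AP_M = sz$AP_M)
  if (!is.null(truth_counts)) {
    cm <- count_metrics(truth_counts, predicted_counts)
    row <- cbind(row, data.frame(R2 = cm$R2, RMSE = cm$RMSE, MAE = cm$MAE,
                                 MAPE = cm$MAPE))
  }
  row
}
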
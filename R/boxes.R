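# Axis-aligned boxes and detection sets.
#
# Boxes are (x_min, y_min, x_max, y_max) in pixels, 0-based, half-open:
# a box covers pixel columns x_min .. x_max-1.  Widths/heights are therefore
# x_max - x_min, and a 32x32-pixel object has area exactly 1024.

#' Construct a set of scored detections for one image
#'
#' @param boxes Numeric matrix `n x 4` of `(x_min, y_min, x_max, y_max)`
#'   pixel coordinates (0-based, half-open). `n = 0` is allowed.
#' @param scores Numeric vector of length `n`, values in `[0, 1]`.
#' @return Object of class `detection_set`, boxes sorted by descending score.
#' @export
detection_set <- function(boxes = matrix(numeric(0), 0, 4), scores = numeric(0)) {
  boxes <- matrix(as.numeric(boxes), ncol = 4)
  if (nrow(boxes) != length(scores)) stop("one score per box required")
  if (nrow(boxes) > 0) {
    if (any(boxes[, 3] <= boxes[, 1]) || any(boxes[, 4] <= boxes[, 2])) {
      stop("degenerate box: x_max must exceed x_min and y_max exceed y_min")
    }
    if (any(scores < 0 | scores > 1) || any(!is.finite(scores))) {
      stop("scores must lie in [0, 1]")
    }
    ord <- order(scores, decreasing = TRUE)
    boxes <- boxes[ord, , drop = FALSE]
    scores <- scores[ord]
  }
  colnames(boxes) <- c("x_min", "y_min", "x_max", "y_max")
  structure(list(boxes = boxes, scores = as.numeric(scores)),
            class = "detection_set")
}

#' @export
length.detection_set <- function(x) nrow(x$boxes)

#' @export
print.detection_set <- function(x, ...) {
  cat("<detection_set>", nrow(x$boxes), "boxes")
  if (nrow(x$boxes)) {
    cat(", scores [", round(min(x$scores), 3), ",",
        round(max(x$scores), 3), "]")
  }
  cat("\n")
  invisible(x)
}

box_area <- function(boxes) {
  (boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2])
}

#' Pairwise intersection-over-union of two box sets
#'
#' @param a,b Matrices `n x 4` and `m x 4`.
#' @return `n x m` matrix of IoU values in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(numeric(0), n, m))
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  union <- outer(box_area(a), box_area(b), `+`) - inter
  out <- ifelse(union > 0, inter / union, 0)
  matrix(out, n, m)
}

# score-greedy duplicate suppression; returns indices (in input order) kept
greedy_suppress <- function(boxes, scores, iou_threshold) {
  n <- length(scores)
  if (n == 0) return(integer(0))
  ord <- order(scores, decreasing = TRUE)
  keep <- integer(0)
  iou <- box_iou(boxes, boxes)
  for (i in ord) {
    if (length(keep) == 0 || all(iou[i, keep] <= iou_threshold)) {
      keep <- c(keep, i)
    }
  }
  keep
}

clip_boxes <- function(boxes, width, height) {
  boxes[, 1] <- pmax(0, pmin(boxes[, 1], width))
  boxes[, 3] <- pmax(0, pmin(boxes[, 3], width))
  boxes[, 2] <- pmax(0, pmin(boxes[, 2], height))
  boxes[, 4] <- pmax(0, pmin(boxes[, 4], height))
  boxes
}
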
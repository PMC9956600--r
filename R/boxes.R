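# Axis-aligned box utilities.  All boxes are (x1, y1, x2, y2) in pixel
# units, 0-based, half-open: x1 <= x < x2, so the area is
# (x2 - x1) * (y2 - y1).

#' Intersection-over-union of two boxes
#'
#' @param boxA,boxB Numeric length-4 vectors (x1, y1, x2, y2).
#' @return IoU in \[0, 1\]; degenerate (zero-area) boxes give 0 with a
#'   warning.
#' @export
compute_iou <- function(boxA, boxB) {
  aA <- (boxA[3] - boxA[1]) * (boxA[4] - boxA[2])
  aB <- (boxB[3] - boxB[1]) * (boxB[4] - boxB[2])
  if (aA <= 0 || aB <= 0) {
    warning("degenerate box: IoU set to 0")
    return(0)
  }
  iw <- min(boxA[3], boxB[3]) - max(boxA[1], boxB[1])
  ih <- min(boxA[4], boxB[4]) - max(boxA[2], boxB[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (aA + aB - inter)
}

# Pairwise IoU matrix (n x m) for box matrices.
box_iou_matrix <- function(A, B) {
  if (!is.matrix(A)) A <- matrix(A, ncol = 4L)
  if (!is.matrix(B)) B <- matrix(B, ncol = 4L)
  n <- nrow(A)
  m <- nrow(B)
  if (n == 0L || m == 0L) return(matrix(0, n, m))
  aA <- (A[, 3] - A[, 1]) * (A[, 4] - A[, 2])
  aB <- (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
  iw <- pmax(0, outer(A[, 3], B[, 3], pmin) - outer(A[, 1], B[, 1], pmax))
  ih <- pmax(0, outer(A[, 4], B[, 4], pmin) - outer(A[, 2], B[, 2], pmax))
  inter <- iw * ih
  un <- outer(aA, aB, "+") - inter
  ifelse(un > 0, inter / un, 0)
}

#' Non-maximum suppression
#'
#' Greedy by descending score; ties broken by input order.
#' @param boxes n x 4 matrix; `scores` length-n; `iou_thr` overlap
#'   threshold above which the lower-scored box is suppressed.
#' @param scores,iou_thr Scores and suppression threshold.
#' @return Integer indices of the kept boxes, ordered by score.
#' @export
nms <- function(boxes, scores, iou_thr = 0.5) {
  n <- nrow(boxes)
  if (n == 0L) return(integer(0))
  ord <- order(-scores, seq_len(n))
  keep <- integer(0)
  alive <- rep(TRUE, n)
  iou <- box_iou_matrix(boxes, boxes)
  for (i in ord) {
    if (!alive[i]) next
    keep <- c(keep, i)
    alive[iou[i, ] > iou_thr] <- FALSE
    alive[i] <- FALSE
  }
  keep
}

# Encode boxes relative to anchors as (dx, dy, dw, dh).
box_encode <- function(boxes, anchors) {
  wa <- anchors[, 3] - anchors[, 1]
  ha <- anchors[, 4] - anchors[, 2]
  xa <- anchors[, 1] + wa / 2
  ya <- anchors[, 2] + ha / 2
  w <- boxes[, 3] - boxes[, 1]
  h <- boxes[, 4] - boxes[, 2]
  x <- boxes[, 1] + w / 2
  y <- boxes[, 2] + h / 2
  cbind((x - xa) / wa, (y - ya) / ha, log(w / wa), log(h / ha))
}

# Decode (dx, dy, dw, dh) deltas against anchors; deltas are clamped so
# exp() cannot overflow.
box_decode <- function(deltas, anchors) {
  wa <- anchors[, 3] - anchors[, 1]
  ha <- anchors[, 4] - anchors[, 2]
  xa <- anchors[, 1] + wa / 2
  ya <- anchors[, 2] + ha / 2
  dw <- pmin(deltas[, 3], 4)
  dh <- pmin(deltas[, 4], 4)
  x <- deltas[, 1] * wa + xa
  y <- deltas[, 2] * ha + ya
  w <- exp(dw) * wa
  h <- exp(dh) * ha
  cbind(x - w / 2, y - h / 2, x + w / 2, y + h / 2)
}

clip_boxes <- function(boxes, width, height) {
  boxes[, 1] <- pmin(pmax(boxes[, 1], 0), width)
  boxes[, 2] <- pmin(pmax(boxes[, 2], 0), height)
  boxes[, 3] <- pmin(pmax(boxes[, 3], 0), width)
  boxes[, 4] <- pmin(pmax(boxes[, 4], 0), height)
  boxes
}

# Anchor grid for one pyramid level: one scale (scale_mult * stride),
# three aspect ratios, centred on token centres.
level_anchors <- function(h, w, stride, ratios = c(0.5, 1, 2),
                          scale_mult = 8) {
  s <- scale_mult * stride
  cx <- (rep(seq_len(w), times = h) - 0.5) * stride
  cy <- (rep(seq_len(h), each = w) - 0.5) * stride
  out <- matrix(0, h * w * length(ratios), 4L)
  for (k in seq_along(ratios)) {
    bw <- s * sqrt(ratios[k])
    bh <- s / sqrt(ratios[k])
    idx <- seq.int((k - 1L) * h * w + 1L, k * h * w)
    out[idx, ] <- cbind(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2)
  }
  out
}

#' Elementwise smooth-L1 value
#'
#' `0.5 x^2 / beta` for `|x| < beta`, `|x| - 0.5 beta` otherwise:
#' continuous with continuous first derivative at the transition.
#' @param x Numeric residuals.
#' @param beta Transition point (> 0); the dynamic-loss update moves it
#'   during training.
#' @return Numeric loss values, same shape as `x`.
#' @export
smooth_l1 <- function(x, beta = 1) {
  stopifnot(beta > 0)
  ax <- abs(x)
  ifelse(ax < beta, 0.5 * ax^2 / beta, ax - 0.5 * beta)
}
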
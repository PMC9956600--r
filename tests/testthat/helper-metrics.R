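# Independent brute-force recomputation of the detection metrics,
# written in plain double loops (no shared code with the package
# implementation beyond base R).

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (un <= 0) 0 else inter / un
}

# detections: data.frame(image_id, x1..y2, score); gt: named list of
# box matrices.  Returns TP flags in global descending-score order.
oracle_sweep <- function(detections, gt, thr) {
  ord <- order(-detections$score, seq_len(nrow(detections)))
  det <- detections[ord, , drop = FALSE]
  used <- lapply(gt, function(g) rep(FALSE, NROW(g)))
  tp <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    g <- gt[[as.character(det$image_id[i])]]
    if (is.null(g) || NROW(g) == 0) next
    best <- -1
    bj <- 0
    for (j in seq_len(NROW(g))) {
      if (used[[as.character(det$image_id[i])]][j]) next
      v <- oracle_iou(as.numeric(det[i, c("x1", "y1", "x2", "y2")]), g[j, ])
      if (v >= thr && v > best) {
        best <- v
        bj <- j
      }
    }
    if (bj > 0) {
      used[[as.character(det$image_id[i])]][bj] <- TRUE
      tp[i] <- TRUE
    }
  }
  tp
}

oracle_ap <- function(detections, gt, thr) {
  ngt <- 0
  for (g in gt) ngt <- ngt + NROW(g)
  if (ngt == 0) return(NA_real_)
  tp <- oracle_sweep(detections, gt, thr)
  n <- length(tp)
  rec <- numeric(n)
  prec <- numeric(n)
  ctp <- 0
  for (i in seq_len(n)) {
    ctp <- ctp + tp[i]
    rec[i] <- ctp / ngt
    prec[i] <- ctp / i
  }
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    # interpolated precision: the best precision at any recall >= r
    best <- 0
    for (i in seq_len(n)) {
      if (rec[i] >= r - 1e-12 && prec[i] > best) best <- prec[i]
    }
    total <- total + best
  }
  total / 101
}

oracle_prf <- function(TP, FP, FN) {
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(100 * P, 100 * R, 100 * F1)
}
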
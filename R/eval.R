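# COCO-style detection metrics.
#
# Matching is greedy: detections in descending score order, each
# consuming the unmatched ground-truth box of highest IoU above the
# threshold.  The precision-recall curve sweeps the score threshold over
# all detections pooled across the dataset; AP is the 101-point average
# of the monotone (right-envelope) interpolated precision (an all-point
# integral is available behind a flag).  Size-stratified AP restricts
# the ground truth to an area class (thresholds 32^2 and 96^2 px^2) and
# ignores detections that match an out-of-class box.

#' Greedy matching of detections against ground truth
#'
#' @param detections data.frame with x1, y1, x2, y2, score (any order;
#'   sorted internally by descending score).
#' @param gt_boxes m x 4 matrix of ground-truth boxes.
#' @param iou_thr Match threshold (default 0.5).
#' @return list(TP, FP, FN, det_is_tp (in score order), det_order,
#'   matched_gt): counts satisfy TP + FP = detections and
#'   TP + FN = ground truth; each ground-truth box matches at most once.
#' @export
match_detections <- function(detections, gt_boxes, iou_thr = 0.5) {
  nd <- nrow(detections)
  ng <- NROW(gt_boxes)
  ord <- if (nd > 0L) order(-detections$score, seq_len(nd)) else integer(0)
  det_is_tp <- logical(nd)
  matched_gt <- integer(nd)
  gt_used <- rep(FALSE, ng)
  if (nd > 0L && ng > 0L) {
    D <- as.matrix(detections[ord, c("x1", "y1", "x2", "y2")])
    iou <- box_iou_matrix(D, gt_boxes)
    for (i in seq_len(nd)) {
      cand <- which(!gt_used & iou[i, ] >= iou_thr)
      if (length(cand) > 0L) {
        j <- cand[which.max(iou[i, cand])]
        gt_used[j] <- TRUE
        det_is_tp[i] <- TRUE
        matched_gt[i] <- j
      }
    }
  }
  TP <- sum(det_is_tp)
  list(TP = TP, FP = nd - TP, FN = ng - TP, det_is_tp = det_is_tp,
       det_order = ord, matched_gt = matched_gt)
}

#' Precision, recall and F1 from match counts
#'
#' P = TP / (TP + FP), R = TP / (TP + FN), F1 = 2 P R / (P + R),
#' reported in percent.  Zero denominators give 0 with a
#' `"zero_denominator"` attribute flag.
#' @param TP,FP,FN Non-negative counts.
#' @return Named numeric c(precision, recall, f1) in percent.
#' @export
precision_recall_f1 <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  flag <- character(0)
  P <- if (TP + FP > 0) TP / (TP + FP) else {
    flag <- c(flag, "precision"); 0
  }
  R <- if (TP + FN > 0) TP / (TP + FN) else {
    flag <- c(flag, "recall"); 0
  }
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else {
    flag <- c(flag, "f1"); 0
  }
  out <- c(precision = 100 * P, recall = 100 * R, f1 = 100 * F1)
  if (length(flag)) attr(out, "zero_denominator") <- flag
  out
}

#' F1 score from precision and recall percentages
#'
#' The harmonic mean 2 P R / (P + R), on the percent scale.
#' @param precision,recall Percentages in \[0, 100\].
#' @return F1 in percent.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall <= 0) return(0)
  2 * precision * recall / (precision + recall)
}

# Pooled sweep over a dataset: detections data.frame must carry
# image_id; gt is a named list image_id -> m x 4 matrix.  Returns
# per-detection TP flags in global descending score order plus nGT.
sweep_matches <- function(detections, gt, iou_thr) {
  ngt <- sum(vapply(gt, NROW, 0L))
  nd <- nrow(detections)
  if (nd == 0L) return(list(tp = logical(0), scores = numeric(0), ngt = ngt))
  ord <- order(-detections$score, seq_len(nd))
  det <- detections[ord, , drop = FALSE]
  used <- lapply(gt, function(g) rep(FALSE, NROW(g)))
  tp <- logical(nd)
  for (i in seq_len(nd)) {
    gid <- as.character(det$image_id[i])
    g <- gt[[gid]]
    if (is.null(g) || NROW(g) == 0L) next
    iou <- box_iou_matrix(as.matrix(det[i, c("x1", "y1", "x2", "y2")]), g)[1L, ]
    cand <- which(!used[[gid]] & iou >= iou_thr)
    if (length(cand) > 0L) {
      j <- cand[which.max(iou[cand])]
      used[[gid]][j] <- TRUE
      tp[i] <- TRUE
    }
  }
  list(tp = tp, scores = det$score, ngt = ngt)
}

#' Precision-recall curve and average precision over a dataset
#'
#' @param detections data.frame(image_id, x1, y1, x2, y2, score),
#'   scores comparable across images.
#' @param gt Named list: image_id -> m x 4 ground-truth box matrix.
#' @param iou_thr Match threshold (default 0.5).
#' @param interpolation "coco101" (101-point envelope average, default)
#'   or "all_points" (exact area under the envelope).
#' @return list(points = data.frame(recall, precision, score),
#'   ap in \[0, 1\]).  Zero ground truth gives ap = NA with a flag.
#' @export
pr_curve_and_ap <- function(detections, gt, iou_thr = 0.5,
                            interpolation = c("coco101", "all_points")) {
  interpolation <- match.arg(interpolation)
  sw <- sweep_matches(detections, gt, iou_thr)
  if (sw$ngt == 0L) {
    out <- list(points = data.frame(recall = numeric(0), precision = numeric(0),
                                    score = numeric(0)), ap = NA_real_)
    attr(out, "flag") <- "no ground truth"
    return(out)
  }
  ctp <- cumsum(sw$tp)
  cfp <- cumsum(!sw$tp)
  rec <- ctp / sw$ngt
  prec <- ctp / (ctp + cfp)
  # monotone precision envelope from the right
  env <- rev(cummax(rev(prec)))
  ap <- if (length(rec) == 0L) 0 else if (interpolation == "coco101") {
    rs <- seq(0, 1, by = 0.01)
    pr_at <- vapply(rs, function(r) {
      i <- which(rec >= r - 1e-12)
      if (length(i) == 0L) 0 else env[i[1L]]
    }, 0)
    mean(pr_at)
  } else {
    # exact integral of the step-wise envelope
    dr <- diff(c(0, rec))
    sum(env * dr)
  }
  list(points = data.frame(recall = rec, precision = prec, score = sw$scores),
       ap = ap)
}

# AP restricted to a ground-truth area class.  Detections matching an
# out-of-class ground-truth box (at iou_thr) are ignored.
ap_size_class <- function(detections, gt, iou_thr, lo = 0, hi = Inf) {
  area <- function(g) (g[, 3] - g[, 1]) * (g[, 4] - g[, 2])
  gt_in <- lapply(gt, function(g) {
    if (NROW(g) == 0L) return(g)
    g[area(g) > lo & area(g) <= hi, , drop = FALSE]
  })
  gt_out <- lapply(gt, function(g) {
    if (NROW(g) == 0L) return(g)
    g[!(area(g) > lo & area(g) <= hi), , drop = FALSE]
  })
  if (sum(vapply(gt_in, NROW, 0L)) == 0L) return(NA_real_)
  keep <- rep(TRUE, nrow(detections))
  if (nrow(detections) > 0L) {
    for (i in seq_len(nrow(detections))) {
      g <- gt_out[[as.character(detections$image_id[i])]]
      if (!is.null(g) && NROW(g) > 0L) {
        iou <- box_iou_matrix(as.matrix(detections[i, c("x1", "y1", "x2", "y2")]),
                              g)[1L, ]
        if (max(iou) >= iou_thr) keep[i] <- FALSE
      }
    }
  }
  pr_curve_and_ap(detections[keep, , drop = FALSE], gt_in, iou_thr)$ap
}

#' Full evaluation report
#'
#' AP at IoU 0.5, recall and F1 at the score threshold maximising F1
#' (the operating point is printed in the report), and size-stratified
#' AP averaged over IoU 0.50:0.05:0.95 (area classes at 32^2 and
#' 96^2 px^2).
#' @param detections data.frame(image_id, x1, y1, x2, y2, score).
#' @param gt Named list image_id -> m x 4 matrix; every detection
#'   image_id must appear in `gt`.
#' @param iou_thr Threshold for the headline AP/recall/F1 (default 0.5).
#' @return An `eval_report` list: ap50, recall50, f1 (percent),
#'   op_threshold, ap_small / ap_medium / ap_large (percent, IoU
#'   0.5:0.95), counts, pr_curve.
#' @export
evaluate_dataset <- function(detections, gt, iou_thr = 0.5) {
  if (nrow(detections) > 0L) {
    missing_ids <- setdiff(unique(as.character(detections$image_id)), names(gt))
    if (length(missing_ids) > 0L) {
      stop("detection image ids missing from ground truth: ",
           paste(missing_ids, collapse = ", "))
    }
  }
  pr <- pr_curve_and_ap(detections, gt, iou_thr)
  # operating point: score threshold (over observed scores) maximising F1
  sw <- sweep_matches(detections, gt, iou_thr)
  best <- list(f1 = -1, thr = NA_real_, P = 0, R = 0, TP = 0L, FP = 0L, FN = 0L)
  if (length(sw$scores) > 0L) {
    ctp <- cumsum(sw$tp)
    cfp <- cumsum(!sw$tp)
    for (i in seq_along(sw$scores)) {
      prf <- precision_recall_f1(ctp[i], cfp[i], sw$ngt - ctp[i])
      if (prf[["f1"]] > best$f1 + 1e-12) {
        best <- list(f1 = prf[["f1"]], thr = sw$scores[i],
                     P = prf[["precision"]], R = prf[["recall"]],
                     TP = ctp[i], FP = cfp[i], FN = sw$ngt - ctp[i])
      }
    }
  }
  iou_grid <- seq(0.5, 0.95, by = 0.05)
  ap_band <- function(lo, hi) {
    aps <- vapply(iou_grid, function(th) {
      ap_size_class(detections, gt, th, lo, hi)
    }, 0)
    if (all(is.na(aps))) NA_real_ else 100 * mean(aps, na.rm = TRUE)
  }
  rep <- list(ap50 = 100 * pr$ap,
              recall50 = best$R, f1 = best$f1, precision50 = best$P,
              op_threshold = best$thr,
              ap_small = ap_band(0, 32^2),
              ap_medium = ap_band(32^2, 96^2),
              ap_large = ap_band(96^2, Inf),
              counts = c(TP = best$TP, FP = best$FP, FN = best$FN,
                         n_gt = sw$ngt, n_det = nrow(detections)),
              pr_curve = pr$points)
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Detection evaluation\n")
  cat(sprintf("  AP50     %6.1f %%\n", x$ap50))
  cat(sprintf("  R50      %6.1f %%  (at score threshold %.3f)\n",
              x$recall50, x$op_threshold))
  cat(sprintf("  F1       %6.1f %%\n", x$f1))
  cat(sprintf("  AP small %6.1f %%   medium %6.1f %%   large %6.1f %%  (IoU 0.5:0.95)\n",
              x$ap_small %||% NA, x$ap_medium %||% NA, x$ap_large %||% NA))
  cat(sprintf("  counts: TP %d  FP %d  FN %d  (GT %d, detections %d)\n",
              x$counts[["TP"]], x$counts[["FP"]], x$counts[["FN"]],
              x$counts[["n_gt"]], x$counts[["n_det"]]))
  invisible(x)
}

#' Write an evaluation report and its P-R curve to disk
#' @param report An `eval_report`; `path_json`/`path_csv` outputs.
#' @param path_json,path_csv Output file paths (NULL to skip).
#' @export
write_eval_report <- function(report, path_json = NULL, path_csv = NULL) {
  if (!is.null(path_json)) {
    out <- report
    out$pr_curve <- NULL
    class(out) <- NULL
    out$counts <- as.list(out$counts)
    jsonlite::write_json(out, path_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  if (!is.null(path_csv)) {
    utils::write.csv(report$pr_curve, path_csv, row.names = FALSE)
  }
  invisible(report)
}
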
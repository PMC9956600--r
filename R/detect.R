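# Two-stage detection head on the enhanced pyramid P1..P4.
#
# A shared region-proposal network (3x3 neighbourhood gather + linear,
# GELU, then objectness and box-delta layers) scores one anchor scale
# (8 x stride) at three aspect ratios per position.  Decoded proposals
# are pooled with RoI-Align (bilinear sub-bin sampling, averaged), and a
# small fully connected head classifies snag vs background and regresses
# the box.  Training uses the dynamic assignment threshold T_now
# (starting at 0.5) and the dynamic smooth-L1 transition beta_now
# (starting at 1), both updated at fixed iteration intervals from
# recorded proposal-quality statistics.

#' Detection-head hyper-parameters
#'
#' @param ratios Anchor aspect ratios (default 0.5, 1, 2).
#' @param anchor_scale Anchor side = `anchor_scale * stride` (default 8).
#' @param rpn_pos_iou,rpn_neg_iou RPN anchor assignment thresholds
#'   (default 0.7 / 0.3; the best anchor per ground-truth box is always
#'   positive).
#' @param rpn_batch Sampled anchors per image for the RPN loss
#'   (default 256, at most half positive).
#' @param rpn_nms_thr RPN NMS overlap (default 0.7).
#' @param rpn_post_train,rpn_post_test Proposals kept after NMS
#'   (default 1000 / 300).
#' @param roi_batch Sampled proposals per image for the RoI head
#'   (default 64); `roi_pos_fraction` caps the positive share
#'   (default 0.25, i.e. a 1:3 ratio).
#' @param roi_pos_fraction Positive fraction of the RoI sample.
#' @param roi_out RoI-Align output grid side (default 7);
#'   `roi_samples` bilinear sample points per bin axis (default 2).
#' @param roi_samples Sample points per bin axis.
#' @param roi_fc_dim Width of the RoI head's fully connected layer
#'   (default 256).
#' @param rpn_dim Width of the shared RPN conv layer (default = neck D).
#' @param score_thr,nms_thr Inference score floor and per-class NMS
#'   overlap (defaults 0.05 / 0.5).
#' @return A `det_config` list.
#' @export
det_config <- function(ratios = c(0.5, 1, 2), anchor_scale = 8,
                       rpn_pos_iou = 0.7, rpn_neg_iou = 0.3,
                       rpn_batch = 256L, rpn_nms_thr = 0.7,
                       rpn_pre_train = 1000L, rpn_pre_test = 600L,
                       rpn_post_train = 1000L, rpn_post_test = 300L,
                       roi_batch = 64L, roi_pos_fraction = 0.25,
                       roi_out = 7L, roi_samples = 2L, roi_fc_dim = 256L,
                       rpn_dim = NULL, score_thr = 0.05, nms_thr = 0.5) {
  structure(list(ratios = ratios, anchor_scale = anchor_scale,
                 rpn_pos_iou = rpn_pos_iou, rpn_neg_iou = rpn_neg_iou,
                 rpn_batch = as.integer(rpn_batch), rpn_nms_thr = rpn_nms_thr,
                 rpn_pre_train = as.integer(rpn_pre_train),
                 rpn_pre_test = as.integer(rpn_pre_test),
                 rpn_post_train = as.integer(rpn_post_train),
                 rpn_post_test = as.integer(rpn_post_test),
                 roi_batch = as.integer(roi_batch),
                 roi_pos_fraction = roi_pos_fraction,
                 roi_out = as.integer(roi_out),
                 roi_samples = as.integer(roi_samples),
                 roi_fc_dim = as.integer(roi_fc_dim),
                 rpn_dim = rpn_dim, score_thr = score_thr,
                 nms_thr = nms_thr),
            class = "det_config")
}

#' Initialise detection-head parameters
#'
#' @param D Pyramid channel width; `dcfg` a [det_config()].
#' @param dcfg Detection configuration.
#' @param prefix Name prefix (default `"hd."`).
#' @return Named list of numeric arrays.
#' @export
head_init_params <- function(D, dcfg, prefix = "hd.") {
  P <- list()
  A <- length(dcfg$ratios)
  Dr <- dcfg$rpn_dim %||% D
  P[[paste0(prefix, "rpn.conv.W")]] <- rnorm_mat(9L * D, Dr, sd = 0.03)
  P[[paste0(prefix, "rpn.conv.b")]] <- numeric(Dr)
  P[[paste0(prefix, "rpn.obj.W")]] <- rnorm_mat(Dr, A, sd = 0.01)
  P[[paste0(prefix, "rpn.obj.b")]] <- rep(-2, A)   # low objectness prior
  P[[paste0(prefix, "rpn.reg.W")]] <- rnorm_mat(Dr, 4L * A, sd = 0.01)
  P[[paste0(prefix, "rpn.reg.b")]] <- numeric(4L * A)
  Fd <- dcfg$roi_fc_dim
  P[[paste0(prefix, "roi.fc1.W")]] <- rnorm_mat(dcfg$roi_out^2 * D, Fd, sd = 0.02)
  P[[paste0(prefix, "roi.fc1.b")]] <- numeric(Fd)
  P[[paste0(prefix, "roi.cls.W")]] <- rnorm_mat(Fd, 2L, sd = 0.01)
  P[[paste0(prefix, "roi.cls.b")]] <- numeric(2L)
  P[[paste0(prefix, "roi.reg.W")]] <- rnorm_mat(Fd, 4L, sd = 0.01)
  P[[paste0(prefix, "roi.reg.b")]] <- numeric(4L)
  P
}

# Shared RPN tower on one pyramid level: returns objectness-logit and
# delta nodes.
rpn_level_fwd <- function(fm, P, prefix = "hd.") {
  ic <- ix_conv3(fm$h, fm$w)
  gat <- ag_cbind(lapply(seq_len(9L), function(j) ag_rows(fm$node, ic[, j])))
  hmid <- ag_gelu(ag_linear(gat, P[[paste0(prefix, "rpn.conv.W")]],
                            P[[paste0(prefix, "rpn.conv.b")]]))
  list(obj = ag_linear(hmid, P[[paste0(prefix, "rpn.obj.W")]],
                       P[[paste0(prefix, "rpn.obj.b")]]),
       reg = ag_linear(hmid, P[[paste0(prefix, "rpn.reg.W")]],
                       P[[paste0(prefix, "rpn.reg.b")]]))
}

# Anchor matrix for a pyramid (list of fm with h, w, stride).
pyramid_anchors <- function(Pl, dcfg) {
  do.call(rbind, lapply(Pl, function(fm) {
    level_anchors(fm$h, fm$w, fm$stride, dcfg$ratios, dcfg$anchor_scale)
  }))
}

# Flatten per-level RPN outputs (n x A and n x 4A) to per-anchor
# vectors/matrices aligned with pyramid_anchors() ordering:
# level-major, then ratio-major, then position.
rpn_flatten <- function(rpn_outs) {
  obj <- ag_rbind(lapply(rpn_outs, function(o) {
    A <- ncol(o$obj$val)
    ag_rbind(lapply(seq_len(A), function(k) ag_cols(o$obj, k)))
  }))
  reg <- ag_rbind(lapply(rpn_outs, function(o) {
    A <- ncol(o$obj$val)
    ag_rbind(lapply(seq_len(A), function(k) {
      ag_cols(o$reg, ((k - 1L) * 4L + 1L):(k * 4L))
    }))
  }))
  list(obj = obj, reg = reg)
}

# Decode, clip, filter, NMS.  Returns data.frame of proposals.
decode_proposals <- function(obj_logits, deltas, anchors, img_w, img_h,
                             dcfg, training = FALSE) {
  scores <- 1 / (1 + exp(-obj_logits))
  boxes <- clip_boxes(box_decode(deltas, anchors), img_w, img_h)
  wh <- cbind(boxes[, 3] - boxes[, 1], boxes[, 4] - boxes[, 2])
  ok <- wh[, 1] > 1 & wh[, 2] > 1
  boxes <- boxes[ok, , drop = FALSE]
  scores <- scores[ok]
  if (nrow(boxes) == 0L) {
    return(data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0)))
  }
  pre <- if (training) dcfg$rpn_pre_train else dcfg$rpn_pre_test
  if (nrow(boxes) > pre) {
    top <- order(-scores)[seq_len(pre)]
    boxes <- boxes[top, , drop = FALSE]
    scores <- scores[top]
  }
  keep <- nms(boxes, scores, dcfg$rpn_nms_thr)
  post <- if (training) dcfg$rpn_post_train else dcfg$rpn_post_test
  keep <- keep[seq_len(min(length(keep), post))]
  data.frame(x1 = boxes[keep, 1], y1 = boxes[keep, 2],
             x2 = boxes[keep, 3], y2 = boxes[keep, 4],
             score = scores[keep])
}

#' Generate region proposals from pyramid features
#'
#' @param Pl Named list P1..P4 (values/h/w/stride) from [run_neck()].
#' @param params Flat parameter list containing the `hd.rpn.*` entries.
#' @param dcfg A [det_config()].
#' @param image_size c(width, height) in pixels for box clipping.
#' @return data.frame (x1, y1, x2, y2, score) sorted by score.
#' @export
generate_proposals <- function(Pl, params, dcfg, image_size) {
  if (length(Pl) == 0L) stop("empty pyramid")
  P <- bind_params(params, trainable = FALSE)
  outs <- lapply(lapply(Pl, fm_wrap), rpn_level_fwd, P = P)
  fl <- rpn_flatten(outs)
  anchors <- pyramid_anchors(Pl, dcfg)
  decode_proposals(as.vector(fl$obj$val), fl$reg$val, anchors,
                   image_size[1L], image_size[2L], dcfg)
}

# Assign proposals to pyramid levels by matching sqrt(area) to the
# level anchor scale; returns integer level index 1..nlev.
roi_levels <- function(boxes, strides, anchor_scale = 8) {
  side <- sqrt(pmax((boxes[, 3] - boxes[, 1]) * (boxes[, 4] - boxes[, 2]), 1))
  k <- floor(log2(side / (anchor_scale * strides[1L])) + 0.5) + 1
  pmin(pmax(k, 1), length(strides))
}

# RoI-Align + fc head for given boxes (plain matrix).  Returns nodes:
# cls logits (n x 2), reg (n x 4), in the order of `boxes`.
roi_head_fwd <- function(Pl, boxes, P, dcfg, prefix = "hd.") {
  strides <- vapply(Pl, function(f) f$stride, 0L)
  lev <- roi_levels(boxes, strides, dcfg$anchor_scale)
  n <- nrow(boxes)
  feats <- vector("list", length(Pl))
  order_idx <- integer(0)
  for (li in seq_along(Pl)) {
    sel <- which(lev == li)
    if (length(sel) == 0L) next
    fm <- Pl[[li]]
    S <- mk_roi_sampler(fm$h, fm$w, boxes[sel, , drop = FALSE] / fm$stride,
                        out = dcfg$roi_out, samples = dcfg$roi_samples)
    pooled <- ag_sparse_linear(S, fm$node)
    fb <- ix_flatten_blocks(length(sel), dcfg$roi_out^2, ncol(fm$node$val))
    feats[[li]] <- ag_permute_elems(pooled, fb$perm, fb$dims)
    order_idx <- c(order_idx, sel)
  }
  x <- ag_rbind(feats[!vapply(feats, is.null, FALSE)])
  # restore input order
  inv <- integer(n)
  inv[order_idx] <- seq_len(n)
  x <- ag_rows(x, inv)
  h1 <- ag_gelu(ag_linear(x, P[[paste0(prefix, "roi.fc1.W")]],
                          P[[paste0(prefix, "roi.fc1.b")]]))
  list(cls = ag_linear(h1, P[[paste0(prefix, "roi.cls.W")]],
                       P[[paste0(prefix, "roi.cls.b")]]),
       reg = ag_linear(h1, P[[paste0(prefix, "roi.reg.W")]],
                       P[[paste0(prefix, "roi.reg.b")]]))
}

#' RoI-Align pooling of one box from one feature map
#'
#' Bilinear sampling at `samples`^2 regular points per bin, averaged.
#' @param fm list(values, h, w, stride) pyramid level.
#' @param box Length-4 box in image pixels; `output_size` the pooled
#'   grid side.
#' @param output_size,samples Grid side and per-bin sample points.
#' @return Array (output_size, output_size, channels).
#' @export
roi_align_pool <- function(fm, box, output_size = 7L, samples = 2L) {
  if ((box[3] - box[1]) <= 0 || (box[4] - box[2]) <= 0) {
    stop("degenerate box")
  }
  stride <- fm$stride %||% 1L
  S <- mk_roi_sampler(fm$h, fm$w, matrix(box / stride, 1L), out = output_size,
                      samples = samples)
  pooled <- as.matrix(S %*% fm$values)
  out <- array(0, c(output_size, output_size, ncol(pooled)))
  for (ch in seq_len(ncol(pooled))) {
    out[, , ch] <- matrix(pooled[, ch], output_size, output_size, byrow = TRUE)
  }
  out
}

# ---- dynamic training state ------------------------------------------------

#' Dynamic training state
#'
#' Holds the evolving assignment threshold `T_now` (initial 0.5) and
#' smooth-L1 transition `beta_now` (initial 1), the per-iteration
#' recorded statistics that drive their updates, and the update policy:
#' every `interval` iterations `T_now` becomes the mean of the recorded
#' IoU statistics (clamped to `t_bounds`) and `beta_now` the median of
#' the recorded error statistics.
#'
#' @param iou_quantile Per-iteration IoU statistic: the k-th largest
#'   proposal-vs-ground-truth IoU with k = ceiling(n * (1 - iou_quantile))
#'   (default 0.75).
#' @param k_beta Rank of the recorded regression-error statistic: the
#'   k_beta-th smallest per-proposal centre error (default 10).
#' @param interval Iterations between updates (default 100).
#' @param t_bounds Clamp range for `T_now` (default c(0.4, 0.9)).
#' @return A `dyn_state` list.
#' @export
dynamic_state <- function(iou_quantile = 0.75, k_beta = 10L,
                          interval = 100L, t_bounds = c(0.4, 0.9)) {
  structure(list(T_now = 0.5, beta_now = 1,
                 iou_record = numeric(0), error_record = numeric(0),
                 iou_quantile = iou_quantile, k_beta = as.integer(k_beta),
                 interval = as.integer(interval), t_bounds = t_bounds,
                 iter = 0L),
            class = "dyn_state")
}

#' Record one iteration's proposal statistics
#'
#' Appends the k-th largest max-IoU and the k_beta-th smallest centre
#' regression error of this iteration to the state's records.
#' @param state A [dynamic_state()].
#' @param max_ious Per-proposal max IoU against ground truth.
#' @param reg_errors Per-positive-proposal centre regression errors
#'   (mean of |dx| and |dy|).
#' @return Updated state.
#' @export
record_dynamic_stats <- function(state, max_ious, reg_errors = numeric(0)) {
  if (length(max_ious) > 0L) {
    k <- max(1L, ceiling(length(max_ious) * (1 - state$iou_quantile)))
    state$iou_record <- c(state$iou_record,
                          sort(max_ious, decreasing = TRUE)[k])
  }
  if (length(reg_errors) > 0L) {
    kb <- min(state$k_beta, length(reg_errors))
    state$error_record <- c(state$error_record, sort(reg_errors)[kb])
  }
  state$iter <- state$iter + 1L
  state
}

#' Apply the periodic dynamic-training update
#'
#' `T_now` becomes the mean of the recorded IoU statistics (clamped);
#' `beta_now` the median of the recorded error statistics.  Records are
#' cleared.  With empty records the state is returned unchanged with a
#' warning.
#' @param state A [dynamic_state()].
#' @return Updated state.
#' @export
update_dynamic_state <- function(state) {
  if (length(state$iou_record) == 0L && length(state$error_record) == 0L) {
    warning("dynamic update requested with empty records; state unchanged")
    return(state)
  }
  if (length(state$iou_record) > 0L) {
    state$T_now <- min(max(mean(state$iou_record), state$t_bounds[1L]),
                       state$t_bounds[2L])
  }
  if (length(state$error_record) > 0L) {
    state$beta_now <- max(stats::median(state$error_record), 1e-3)
  }
  state$iou_record <- numeric(0)
  state$error_record <- numeric(0)
  state
}

#' Positive/negative labels under the current IoU threshold
#'
#' A proposal is positive iff its best IoU over the ground-truth boxes
#' reaches `T_now` (ties inclusive).
#' @param proposals n x 4 box matrix.
#' @param gt_boxes m x 4 box matrix (m may be 0: all negative).
#' @param state A [dynamic_state()] (or any list with `T_now`).
#' @return Integer vector of 1 (positive) / 0 (negative).
#' @export
assign_training_labels <- function(proposals, gt_boxes, state) {
  if (!is.matrix(proposals)) proposals <- matrix(proposals, ncol = 4L)
  if (is.null(gt_boxes) || NROW(gt_boxes) == 0L) {
    return(integer(nrow(proposals)))
  }
  iou <- box_iou_matrix(proposals, gt_boxes)
  mx <- apply(iou, 1L, max)
  as.integer(mx >= state$T_now)
}
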
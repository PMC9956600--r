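# Full detector: backbone -> neck -> RPN -> RoI head, plus the
# per-image training loss with dynamic assignment and dynamic smooth-L1.

#' Create an untrained snag detector
#'
#' Bundles backbone, neck and head configurations, initialises all
#' parameters and the dynamic-training state.
#' @param swin_cfg A [swin_config()]; `neck_cfg` a [neck_config()];
#'   `det_cfg` a [det_config()]; `dyn` a [dynamic_state()].
#' @param neck_cfg,det_cfg,dyn Remaining configuration blocks.
#' @param seed Integer seed for parameter initialisation.
#' @return A `snag_model` object.
#' @export
snag_model <- function(swin_cfg = swin_config(), neck_cfg = neck_config(),
                       det_cfg = det_config(), dyn = dynamic_state(),
                       seed = 1L) {
  old <- .Random.seed__save()
  set.seed(seed)
  params <- c(swin_init_params(swin_cfg),
              neck_init_params(swin_cfg, neck_cfg),
              head_init_params(neck_cfg$D, det_cfg))
  .Random.seed__restore(old)
  structure(list(params = params,
                 cfg = list(swin = swin_cfg, neck = neck_cfg, det = det_cfg),
                 dyn = dyn, log = NULL, epochs_run = 0L, seed = seed),
            class = "snag_model")
}

#' Reduced detector profile for CPU-scale experiments
#'
#' Backbone C = 24, depths (1, 1, 2, 1), window 4; neck D = 32 with one
#' block per neck path; smaller RPN/RoI sampling budgets.  Intended for
#' 128 x 128 tiles.
#' @param seed Parameter seed.
#' @return A `snag_model`.
#' @export
snag_model_tiny <- function(seed = 1L) {
  snag_model(
    swin_cfg = swin_config_tiny(),
    neck_cfg = neck_config(D = 32L, lateral_blocks = 1L, expand_blocks = 1L,
                           fuse_blocks = 1L),
    det_cfg = det_config(roi_fc_dim = 128L, roi_batch = 32L,
                         rpn_batch = 128L, rpn_pre_train = 400L,
                         rpn_post_train = 200L, rpn_pre_test = 300L,
                         rpn_post_test = 100L),
    dyn = dynamic_state(interval = 50L),
    seed = seed)
}

.Random.seed__save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed__restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# Pad an image array up to multiples of 32 (zero padding bottom/right).
pad_image32 <- function(img) {
  d <- dim(img)
  ph <- as.integer(ceiling(d[1L] / 32) * 32)
  pw <- as.integer(ceiling(d[2L] / 32) * 32)
  if (ph == d[1L] && pw == d[2L]) return(img)
  out <- array(0, c(ph, pw, d[3L]))
  out[seq_len(d[1L]), seq_len(d[2L]), ] <- img
  out
}

pyramid_fwd <- function(img, P, cfg) {
  us <- swin_backbone_fwd(img, P, cfg$swin)
  neck_fwd(us, P, cfg$swin, cfg$neck)
}

#' Run the detector on an image
#'
#' Full forward pass (backbone, neck, RPN, RoI head), class softmax,
#' score filtering and per-class NMS.
#' @param image H x W x 3 array with values in \[0, 1\] (padded
#'   internally to multiples of 32; boxes are clipped back).
#' @param model A `snag_model`.
#' @param score_thr,nms_thr Overrides of the model's inference
#'   thresholds.
#' @return data.frame (x1, y1, x2, y2, score, category) sorted by
#'   descending score.
#' @export
detect <- function(image, model, score_thr = NULL, nms_thr = NULL) {
  dcfg <- model$cfg$det
  score_thr <- score_thr %||% dcfg$score_thr
  nms_thr <- nms_thr %||% dcfg$nms_thr
  d0 <- dim(image)
  img <- pad_image32(image)
  P <- bind_params(model$params, trainable = FALSE)
  Pl <- pyramid_fwd(img, P, model$cfg)
  empty <- data.frame(x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), score = numeric(0),
                      category = character(0))
  outs <- lapply(Pl, rpn_level_fwd, P = P)
  fl <- rpn_flatten(outs)
  anchors <- pyramid_anchors(Pl, dcfg)
  props <- decode_proposals(as.vector(fl$obj$val), fl$reg$val, anchors,
                            dim(img)[2L], dim(img)[1L], dcfg,
                            training = FALSE)
  if (nrow(props) == 0L) return(empty)
  boxes <- as.matrix(props[, 1:4])
  heads <- roi_head_fwd(Pl, boxes, P, dcfg)
  z <- heads$cls$val
  ez <- exp(z - apply(z, 1L, max))
  prob <- ez / rowSums(ez)
  score <- prob[, 2L]
  refined <- clip_boxes(box_decode(heads$reg$val, boxes),
                        dim(img)[2L], dim(img)[1L])
  ok <- score >= score_thr &
    (refined[, 3] - refined[, 1]) > 1 & (refined[, 4] - refined[, 2]) > 1
  if (!any(ok)) return(empty)
  refined <- refined[ok, , drop = FALSE]
  score <- score[ok]
  keep <- nms(refined, score, nms_thr)
  refined <- clip_boxes(refined[keep, , drop = FALSE], d0[2L], d0[1L])
  data.frame(x1 = refined[, 1], y1 = refined[, 2], x2 = refined[, 3],
             y2 = refined[, 4], score = score[keep], category = "sdt")
}

# ---- training loss ---------------------------------------------------------

# Sample at most `want` indices uniformly without replacement.
sample_idx <- function(idx, want) {
  if (length(idx) <= want) return(idx)
  idx[sample.int(length(idx), want)]
}

# Per-image loss.  `P` are bound parameter nodes; `dyn` the dynamic
# state.  Returns loss node plus recorded statistics.
image_loss_fwd <- function(img, gt, P, cfg, dyn, record = TRUE) {
  dcfg <- cfg$det
  Pl <- pyramid_fwd(img, P, cfg)
  img_h <- dim(img)[1L]
  img_w <- dim(img)[2L]
  outs <- lapply(Pl, rpn_level_fwd, P = P)
  fl <- rpn_flatten(outs)
  anchors <- pyramid_anchors(Pl, dcfg)
  ng <- NROW(gt)

  # --- RPN assignment and loss
  iou <- box_iou_matrix(anchors, gt)
  mx <- if (ng > 0L) apply(iou, 1L, max) else numeric(nrow(anchors))
  pos <- mx >= dcfg$rpn_pos_iou
  if (ng > 0L) {
    for (j in seq_len(ng)) {       # best anchor per ground-truth box
      bi <- which.max(iou[, j])
      if (iou[bi, j] > 1e-3) pos[bi] <- TRUE
    }
  }
  neg <- mx < dcfg$rpn_neg_iou & !pos
  pos_idx <- sample_idx(which(pos), dcfg$rpn_batch %/% 2L)
  neg_idx <- sample_idx(which(neg), dcfg$rpn_batch - length(pos_idx))
  samp <- c(pos_idx, neg_idx)
  tgt <- c(rep(1, length(pos_idx)), rep(0, length(neg_idx)))
  obj_s <- ag_rows(fl$obj, samp)
  loss_rpn_obj <- ag_sigmoid_bce(obj_s, tgt)
  if (length(pos_idx) > 0L) {
    amax <- max.col(iou[pos_idx, , drop = FALSE], ties.method = "first")
    enc <- box_encode(gt[amax, , drop = FALSE],
                      anchors[pos_idx, , drop = FALSE])
    reg_s <- ag_rows(fl$reg, pos_idx)
    loss_rpn_reg <- ag_smooth_l1_loss(reg_s, enc, beta = 1,
                                      denom = length(samp))
  } else {
    loss_rpn_reg <- ag_const(0)
  }

  # --- proposals (no gradient through the boxes)
  props <- decode_proposals(as.vector(fl$obj$val), fl$reg$val, anchors,
                            img_w, img_h, dcfg, training = TRUE)
  prop_boxes <- as.matrix(props[, 1:4])
  iou_stat <- if (ng > 0L && nrow(prop_boxes) > 0L) {
    apply(box_iou_matrix(prop_boxes, gt), 1L, max)
  } else numeric(0)
  if (ng > 0L) prop_boxes <- rbind(prop_boxes, gt)

  # --- RoI assignment under T_now, 1:3 sampling
  labels <- assign_training_labels(prop_boxes, gt, dyn)
  pos_r <- which(labels == 1L)
  neg_r <- which(labels == 0L)
  npos <- min(length(pos_r), round(dcfg$roi_batch * dcfg$roi_pos_fraction))
  pos_r <- sample_idx(pos_r, npos)
  neg_r <- sample_idx(neg_r, dcfg$roi_batch - length(pos_r))
  roi_idx <- c(pos_r, neg_r)
  roi_boxes <- prop_boxes[roi_idx, , drop = FALSE]
  roi_lab <- c(rep(2L, length(pos_r)), rep(1L, length(neg_r)))
  heads <- roi_head_fwd(Pl, roi_boxes, P, dcfg)
  loss_roi_cls <- ag_softmax_ce(heads$cls, roi_lab)
  reg_errors <- numeric(0)
  if (length(pos_r) > 0L) {
    gi <- max.col(box_iou_matrix(prop_boxes[pos_r, , drop = FALSE], gt),
                  ties.method = "first")
    enc <- box_encode(gt[gi, , drop = FALSE],
                      prop_boxes[pos_r, , drop = FALSE])
    reg_p <- ag_rows(heads$reg, seq_along(pos_r))
    loss_roi_reg <- ag_smooth_l1_loss(reg_p, enc, beta = dyn$beta_now,
                                      denom = length(roi_idx))
    derr <- abs(reg_p$val[, 1:2, drop = FALSE] - enc[, 1:2, drop = FALSE])
    reg_errors <- rowMeans(derr)   # centre coordinates only, averaged
  } else {
    loss_roi_reg <- ag_const(0)
  }

  total <- ag_add(ag_add(loss_rpn_obj, loss_rpn_reg),
                  ag_add(loss_roi_cls, loss_roi_reg))
  list(total = total,
       parts = c(rpn_obj = loss_rpn_obj$val, rpn_reg = loss_rpn_reg$val,
                 roi_cls = loss_roi_cls$val, roi_reg = loss_roi_reg$val),
       iou_stat = iou_stat, reg_errors = reg_errors)
}

# Validation loss (no tape, frozen parameters).
dataset_loss <- function(scenes, params, cfg, dyn) {
  P <- bind_params(params, trainable = FALSE)
  tot <- 0
  for (sc in scenes) {
    l <- image_loss_fwd(sc$pixels, sc$boxes, P, cfg, dyn, record = FALSE)
    tot <- tot + l$total$val
  }
  tot / max(length(scenes), 1L)
}
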
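# Detection core: anchors, box coding, NMS, RoI-Align against a
# brute-force bilinear sampler, dynamic-training updates and the
# smooth-L1 loss shape.

set.seed(21)

test_that("box coding round-trips and zero deltas return the anchor", {
  anchors <- matrix(c(10, 20, 50, 60,
                      0, 0, 32, 64), 2, 4, byrow = TRUE)
  expect_equal(box_decode(matrix(0, 2, 4), anchors), anchors)
  boxes <- matrix(c(12, 25, 55, 58,
                    3, 1, 30, 70), 2, 4, byrow = TRUE)
  enc <- box_encode(boxes, anchors)
  expect_equal(box_decode(enc, anchors), boxes, tolerance = 1e-6)
})

test_that("NMS suppresses duplicates and ignores input order", {
  b <- matrix(c(0, 0, 10, 10,
                0, 0, 10, 10,
                20, 20, 30, 30), 3, 4, byrow = TRUE)
  keep <- nms(b, c(0.9, 0.8, 0.7), iou_thr = 0.7)
  expect_equal(sort(keep), c(1L, 3L))

  set.seed(3)
  boxes <- cbind(runif(20, 0, 50), runif(20, 0, 50), 0, 0)
  boxes[, 3] <- boxes[, 1] + runif(20, 5, 20)
  boxes[, 4] <- boxes[, 2] + runif(20, 5, 20)
  scores <- seq(0.95, 0.05, length.out = 20)   # distinct
  k1 <- nms(boxes, scores, 0.5)
  perm <- sample(20)
  k2 <- nms(boxes[perm, ], scores[perm], 0.5)
  expect_setequal(perm[k2], k1)
})

test_that("anchor grids have one scale per level and three ratios", {
  Pl <- list(list(h = 2L, w = 2L, stride = 4L),
             list(h = 1L, w = 1L, stride = 8L))
  A <- pyramid_anchors(Pl, det_config())
  expect_equal(nrow(A), 15L)  # (4 + 1) positions x 3 ratios
  # the ratio-1 anchor at stride 4 has side 32 centred on the cell
  a <- level_anchors(1L, 1L, 4L)[2L, ]
  expect_equal(a, c(2 - 16, 2 - 16, 2 + 16, 2 + 16))
  # ratio anchors preserve area
  la <- level_anchors(1L, 1L, 4L)
  areas <- (la[, 3] - la[, 1]) * (la[, 4] - la[, 2])
  expect_equal(areas, rep(32^2, 3), tolerance = 1e-9)
})

test_that("RoI-Align matches a brute-force bilinear sampler", {
  # constant map -> constant pooled patch
  fmc <- list(values = matrix(3.5, 16, 2), h = 4L, w = 4L, stride = 1L)
  out <- roi_align_pool(fmc, c(0.7, 0.3, 3.2, 3.9), output_size = 3L)
  expect_equal(as.vector(out), rep(3.5, 18), tolerance = 1e-12)

  # ramp map, unit-ish box, 2x2 output vs an independent sampler
  vals <- matrix(seq_len(16), 16, 1) / 4   # token t value t/4
  fm <- list(values = vals, h = 4L, w = 4L, stride = 1L)
  box <- c(0.5, 1.0, 2.5, 3.0)
  got <- roi_align_pool(fm, box, output_size = 2L, samples = 2L)
  sample_pt <- function(x, y) {
    # bilinear at continuous (x, y), grid centres at integer + 0.5
    xx <- min(max(x - 0.5, 0), 3)
    yy <- min(max(y - 0.5, 0), 3)
    x0 <- floor(xx); y0 <- floor(yy)
    fx <- xx - x0;  fy <- yy - y0
    x1 <- min(x0 + 1, 3); y1 <- min(y0 + 1, 3)
    v <- function(r, c) vals[r * 4 + c + 1, 1]
    (1 - fy) * ((1 - fx) * v(y0, x0) + fx * v(y0, x1)) +
      fy * ((1 - fx) * v(y1, x0) + fx * v(y1, x1))
  }
  bw <- (box[3] - box[1]) / 2
  bh <- (box[4] - box[2]) / 2
  expected <- array(0, c(2, 2, 1))
  for (by in 1:2) for (bx in 1:2) {
    acc <- 0
    for (sy in c(0.25, 0.75)) for (sx in c(0.25, 0.75)) {
      acc <- acc + sample_pt(box[1] + (bx - 1 + sx) * bw,
                             box[2] + (by - 1 + sy) * bh)
    }
    expected[by, bx, 1] <- acc / 4
  }
  expect_equal(got, expected, tolerance = 1e-10)

  # full-map box, output = map size, one sample per bin: recovers the map
  full <- roi_align_pool(fm, c(0, 0, 4, 4), output_size = 4L, samples = 1L)
  expect_equal(as.vector(t(full[, , 1])), as.vector(vals), tolerance = 1e-10)

  expect_error(roi_align_pool(fm, c(1, 1, 1, 3)), "degenerate")
})

test_that("label assignment follows the dynamic IoU threshold inclusively", {
  st <- dynamic_state()
  gt <- matrix(c(0, 0, 10, 10), 1, 4)
  # IoU of (0,0,10,6) with gt = 60/100 = 0.6
  p <- matrix(c(0, 0, 10, 6), 1, 4)
  expect_equal(assign_training_labels(p, gt, st), 1L)
  st$T_now <- 0.7
  expect_equal(assign_training_labels(p, gt, st), 0L)
  # exactly at the threshold: positive
  st$T_now <- 0.6
  expect_equal(assign_training_labels(p, gt, st), 1L)
  # no ground truth: all negative
  expect_equal(assign_training_labels(p, NULL, st), 0L)
  expect_equal(assign_training_labels(p, matrix(0, 0, 4), st), 0L)
})

test_that("dynamic state starts at the defaults and updates by mean/median", {
  st <- dynamic_state()
  expect_equal(st$T_now, 0.5)
  expect_equal(st$beta_now, 1)

  st$iou_record <- c(0.55, 0.65)
  st$error_record <- c(0.4, 0.2, 0.3)
  st2 <- update_dynamic_state(st)
  expect_equal(st2$T_now, 0.60)
  expect_equal(st2$beta_now, 0.3)
  expect_length(st2$iou_record, 0)
  expect_length(st2$error_record, 0)

  # clamping of T_now
  st$iou_record <- c(0.95, 0.97)
  expect_equal(update_dynamic_state(st)$T_now, 0.9)
  st$iou_record <- c(0.1, 0.2)
  expect_equal(update_dynamic_state(st)$T_now, 0.4)

  # empty records: unchanged with a warning
  st3 <- dynamic_state()
  expect_warning(st4 <- update_dynamic_state(st3), "empty")
  expect_equal(st4$T_now, 0.5)
})

test_that("recorded statistics equal a spreadsheet-style oracle", {
  st <- dynamic_state(iou_quantile = 0.75, k_beta = 3L, interval = 4L)
  streams <- list(seq(0.2, 0.6, length.out = 20),
                  seq(0.3, 0.7, length.out = 10),
                  rep(0.5, 8), sort(runif(30)))
  errs <- list(runif(12), runif(5), runif(2), runif(9))
  for (i in 1:4) st <- record_dynamic_stats(st, streams[[i]], errs[[i]])
  # oracle: k-th largest IoU with k = ceiling(n/4); k_beta-th smallest
  # error (or the largest available)
  exp_iou <- vapply(streams, function(s) {
    sort(s, decreasing = TRUE)[max(1, ceiling(length(s) * 0.25))]
  }, 0)
  exp_err <- vapply(errs, function(e) sort(e)[min(3, length(e))], 0)
  expect_equal(st$iou_record, exp_iou)
  expect_equal(st$error_record, exp_err)
  st <- update_dynamic_state(st)
  expect_equal(st$T_now, min(max(mean(exp_iou), 0.4), 0.9))
  expect_equal(st$beta_now, stats::median(exp_err))
})

test_that("smooth-L1 matches the printed piecewise values and is continuous", {
  expect_equal(smooth_l1(0.5, beta = 1), 0.125)
  expect_equal(smooth_l1(2, beta = 1), 1.5)
  expect_equal(smooth_l1(0.25, beta = 0.5), 0.0625)
  # continuity and C1 joint at |x| = beta for a grid of betas
  for (beta in c(0.1, 0.5, 1, 2)) {
    eps <- 1e-7
    expect_lt(abs(smooth_l1(beta + eps, beta) - smooth_l1(beta - eps, beta)),
              1e-6)
    dplus <- (smooth_l1(beta + 2 * eps, beta) - smooth_l1(beta + eps, beta)) / eps
    dminus <- (smooth_l1(beta - eps, beta) - smooth_l1(beta - 2 * eps, beta)) / eps
    expect_lt(abs(dplus - dminus), 1e-5)
  }
  expect_error(smooth_l1(1, beta = 0))
})

test_that("proposal generation and detection keep their output contracts", {
  m <- snag_model_tiny(seed = 9L)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  P <- bind_params(m$params, trainable = FALSE)
  Pl <- lapply(pyramid_fwd(img, P, m$cfg), fm_unwrap)
  props <- generate_proposals(Pl, m$params, m$cfg$det, c(64, 64))
  expect_true(all(props$score >= 0 & props$score <= 1))
  expect_true(all(props$x1 >= 0 & props$x2 <= 64 &
                    props$y1 >= 0 & props$y2 <= 64))
  expect_true(all(props$x2 > props$x1 & props$y2 > props$y1))
  expect_error(generate_proposals(list(), m$params, m$cfg$det, c(64, 64)),
               "empty")

  d <- detect(img, m, score_thr = 0)
  if (nrow(d) > 0) {
    expect_true(all(d$score >= 0 & d$score <= 1))
    expect_true(all(d$x2 > d$x1 & d$y2 > d$y1))
    expect_true(all(d$x1 >= 0 & d$x2 <= 64 & d$y1 >= 0 & d$y2 <= 64))
    expect_equal(d$score, sort(d$score, decreasing = TRUE))
    # per-class NMS leaves no pair above the suppression threshold
    if (nrow(d) > 1) {
      iou <- box_iou_matrix(as.matrix(d[, 1:4]), as.matrix(d[, 1:4]))
      diag(iou) <- 0
      expect_lt(max(iou), m$cfg$det$nms_thr + 1e-9)
    }
  }
})

test_that("the end-to-end loss gradient agrees with finite differences", {
  m <- snag_model_tiny(seed = 4L)
  sc <- generate_scene(scene_config_easy(seed = 3L, image_size = 64L))
  loss_at <- function(params) {
    set.seed(99)   # freeze the loss's internal sampling
    P <- bind_params(params, trainable = FALSE)
    image_loss_fwd(sc$tile$pixels, sc$boxes, P, m$cfg, m$dyn)$total$val
  }
  set.seed(99)
  ag_tape_start()
  P <- bind_params(m$params, trainable = TRUE)
  l <- image_loss_fwd(sc$tile$pixels, sc$boxes, P, m$cfg, m$dyn)
  ag_backward(l$total)
  ag_tape_stop()
  for (nm in c("bb.pe.W", "nk.nl.theta.W", "hd.roi.fc1.W", "bb.st2.bl1.qkv.W")) {
    g <- P[[nm]]$grad
    expect_false(is.null(g))
    idx <- which(abs(g) == max(abs(g)))[1L]
    eps <- 1e-4
    pp <- m$params
    pp[[nm]][idx] <- pp[[nm]][idx] + eps
    up <- loss_at(pp)
    pp[[nm]][idx] <- pp[[nm]][idx] - 2 * eps
    dn <- loss_at(pp)
    expect_equal(g[idx], (up - dn) / (2 * eps), tolerance = 5e-3)
  }
})
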
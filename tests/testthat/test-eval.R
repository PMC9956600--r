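# Metric suite: IoU, greedy matching, precision/recall/F1 (including
# the published worked examples), P-R curve and AP under the 101-point
# envelope convention, size-stratified AP, and agreement with the
# independent brute-force oracle.

set.seed(31)

test_that("IoU matches hand values and handles edge cases", {
  expect_equal(compute_iou(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1.0)
  expect_equal(compute_iou(c(0, 0, 2, 2), c(5, 5, 7, 7)), 0.0)
  expect_equal(compute_iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_warning(v <- compute_iou(c(0, 0, 0, 2), c(0, 0, 2, 2)), "degenerate")
  expect_equal(v, 0)
})

test_that("greedy matching resolves the canonical cases", {
  gt1 <- matrix(c(0, 0, 10, 10), 1, 4)
  d1 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, score = 0.9)
  m1 <- match_detections(d1, gt1)
  expect_equal(c(m1$TP, m1$FP, m1$FN), c(1L, 0L, 0L))

  # two detections on the same ground truth: one TP, one FP
  d2 <- rbind(d1, data.frame(x1 = 1, y1 = 0, x2 = 10, y2 = 10, score = 0.8))
  m2 <- match_detections(d2, gt1)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(1L, 1L, 0L))

  # 3 GT, detections scored [hit, miss, hit]
  gt3 <- matrix(c(0, 0, 10, 10,
                  20, 0, 30, 10,
                  40, 0, 50, 10), 3, 4, byrow = TRUE)
  d3 <- data.frame(x1 = c(0, 60, 40), y1 = c(0, 0, 0),
                   x2 = c(10, 70, 50), y2 = c(10, 10, 10),
                   score = c(0.9, 0.8, 0.7))
  m3 <- match_detections(d3, gt3)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(2L, 1L, 1L))
  # exhaustive check: no assignment beats the greedy one here
  best <- 0
  for (p1 in 0:1) for (p2 in 0:1) for (p3 in 0:1) {
    ok <- (p1 == 0 || compute_iou(as.numeric(d3[1, 1:4]), gt3[1, ]) >= 0.5) &&
      (p2 == 0 || max(box_iou_matrix(as.matrix(d3[2, 1:4]), gt3)) >= 0.5) &&
      (p3 == 0 || compute_iou(as.numeric(d3[3, 1:4]), gt3[3, ]) >= 0.5)
    if (ok) best <- max(best, p1 + p2 + p3)
  }
  expect_equal(m3$TP, best)
})

test_that("matching counts always partition detections and ground truth", {
  for (rep in 1:10) {
    ng <- sample(0:5, 1)
    nd <- sample(0:6, 1)
    gt <- if (ng > 0) {
      cbind(runif(ng, 0, 40), runif(ng, 0, 40), 0, 0) +
        cbind(0, 0, runif(ng, 4, 12), runif(ng, 4, 12))
    } else matrix(0, 0, 4)
    if (ng > 0) gt[, 3] <- gt[, 1] + pmax(gt[, 3] - gt[, 1], 4)
    det <- data.frame(x1 = runif(nd, 0, 40), y1 = runif(nd, 0, 40))
    det$x2 <- det$x1 + runif(nd, 4, 12)
    det$y2 <- det$y1 + runif(nd, 4, 12)
    det$score <- runif(nd)
    m <- match_detections(det, gt)
    expect_equal(m$TP + m$FP, nd)
    expect_equal(m$TP + m$FN, ng)
    expect_true(all(table(m$matched_gt[m$matched_gt > 0]) == 1))
  }
})

test_that("F1 arithmetic reproduces the published worked examples", {
  # proposed method: P 95.9, R 92.1 -> printed F1 93.9
  expect_lt(abs(f1_score(95.9, 92.1) - 93.9), 0.1)
  # Grid-RCNN: P 94.6, R 90.3 -> printed 92.4
  expect_lt(abs(f1_score(94.6, 90.3) - 92.4), 0.1)
  # P = R -> F1 = P
  expect_equal(f1_score(77.7, 77.7), 77.7)
  # counts interface agrees with the direct formula
  prf <- precision_recall_f1(90, 10, 10)
  expect_equal(prf[["f1"]], f1_score(prf[["precision"]], prf[["recall"]]))
  # zero denominators flagged
  z <- precision_recall_f1(0, 0, 0)
  expect_equal(as.numeric(z), c(0, 0, 0))
  expect_true("precision" %in% attr(z, "zero_denominator"))
})

test_that("AP is 1 for a perfect detector and 0 for pure false positives", {
  gt <- list(`1` = matrix(c(0, 0, 10, 10, 20, 20, 30, 30), 2, 4, byrow = TRUE))
  perfect <- data.frame(image_id = 1, x1 = c(0, 20), y1 = c(0, 20),
                        x2 = c(10, 30), y2 = c(10, 30), score = c(0.9, 0.8))
  expect_equal(pr_curve_and_ap(perfect, gt)$ap, 1.0)
  junk <- data.frame(image_id = 1, x1 = c(50, 70), y1 = c(50, 70),
                     x2 = c(60, 80), y2 = c(60, 80), score = c(0.9, 0.8))
  expect_equal(pr_curve_and_ap(junk, gt)$ap, 0.0)
  # zero ground truth: flagged undefined
  res <- pr_curve_and_ap(perfect, list(`1` = matrix(0, 0, 4)))
  expect_true(is.na(res$ap))
})

test_that("AP under ranked outcomes [TP, FP, TP] matches the hand value", {
  gt <- list(`1` = matrix(c(0, 0, 10, 10, 20, 20, 30, 30), 2, 4, byrow = TRUE))
  det <- data.frame(image_id = 1,
                    x1 = c(0, 50, 20), y1 = c(0, 50, 20),
                    x2 = c(10, 60, 30), y2 = c(10, 60, 30),
                    score = c(0.9, 0.8, 0.7))
  # precision after each rank: 1, 1/2, 2/3; recall: 1/2, 1/2, 1
  # envelope: precision 1 for r <= 0.5 (51 grid points), 2/3 above (50)
  expect_equal(pr_curve_and_ap(det, gt)$ap, (51 + 50 * 2 / 3) / 101,
               tolerance = 1e-12)
  # and the independent oracle agrees
  expect_equal(pr_curve_and_ap(det, gt)$ap, oracle_ap(det, gt, 0.5),
               tolerance = 1e-12)
})

test_that("AP is invariant to dataset duplication; extra FPs never help", {
  gt <- list(`1` = matrix(c(0, 0, 10, 10, 30, 0, 44, 12), 2, 4, byrow = TRUE),
             `2` = matrix(c(5, 5, 18, 20), 1, 4))
  det <- data.frame(image_id = c(1, 1, 2, 2),
                    x1 = c(0, 31, 5, 60), y1 = c(1, 0, 6, 60),
                    x2 = c(10, 44, 18, 70), y2 = c(10, 12, 19, 70),
                    score = c(0.9, 0.6, 0.75, 0.4))
  ap0 <- pr_curve_and_ap(det, gt)$ap
  det_dup <- rbind(det, transform(det, image_id = image_id + 10))
  gt_dup <- c(gt, stats::setNames(gt, c("11", "12")))
  expect_equal(pr_curve_and_ap(det_dup, gt_dup)$ap, ap0, tolerance = 1e-12)

  worst <- rbind(det, data.frame(image_id = 1, x1 = 80, y1 = 80, x2 = 90,
                                 y2 = 90, score = 0.01))
  expect_lte(pr_curve_and_ap(worst, gt)$ap, ap0 + 1e-12)

  # adding a true positive never lowers recall at the operating point
  r0 <- evaluate_dataset(det, gt)$recall50
  more <- rbind(det, data.frame(image_id = 2, x1 = 5, y1 = 5, x2 = 18,
                                y2 = 20, score = 0.95))
  gt2 <- gt
  gt2$`2` <- rbind(gt$`2`, c(5, 5, 18, 20))
  expect_gte(evaluate_dataset(more, gt2)$recall50, r0 - 1e-9)
})

test_that("a detector that echoes the ground truth scores perfect metrics", {
  gt <- list(a = matrix(c(0, 0, 10, 10), 1, 4),
             b = matrix(c(5, 5, 40, 40, 50, 50, 90, 96), 2, 4, byrow = TRUE))
  det <- do.call(rbind, lapply(names(gt), function(id) {
    g <- gt[[id]]
    data.frame(image_id = id, x1 = g[, 1], y1 = g[, 2], x2 = g[, 3],
               y2 = g[, 4], score = 0.99)
  }))
  rep <- evaluate_dataset(det, gt)
  expect_equal(rep$ap50, 100)
  expect_equal(rep$recall50, 100)
  expect_equal(rep$f1, 100)
  # only the small box (area 100 < 32^2) feeds ap_small
  expect_equal(rep$ap_small, 100)
  # no small ground truth -> ap_small undefined
  gt_big <- list(b = gt$b)
  rep2 <- evaluate_dataset(det[det$image_id == "b", ], gt_big)
  expect_true(is.na(rep2$ap_small))
  # unknown image ids are an error
  expect_error(evaluate_dataset(det, gt["a"]), "missing from ground truth")
})

test_that("the metric suite agrees with the brute-force oracle on random data", {
  for (rep in 1:5) {
    nimg <- 4
    gt <- list()
    det <- NULL
    for (i in seq_len(nimg)) {
      ng <- sample(1:4, 1)
      g <- cbind(runif(ng, 0, 80), runif(ng, 0, 80))
      g <- cbind(g, g[, 1] + runif(ng, 6, 25), g[, 2] + runif(ng, 6, 25))
      gt[[as.character(i)]] <- g
      nd <- sample(1:5, 1)
      jit <- g[sample(ng, nd, replace = TRUE), , drop = FALSE] +
        matrix(rnorm(nd * 4, 0, 4), nd, 4)
      jit[, 3] <- pmax(jit[, 3], jit[, 1] + 2)
      jit[, 4] <- pmax(jit[, 4], jit[, 2] + 2)
      det <- rbind(det, data.frame(image_id = i, x1 = jit[, 1], y1 = jit[, 2],
                                   x2 = jit[, 3], y2 = jit[, 4],
                                   score = runif(nd)))
    }
    expect_equal(pr_curve_and_ap(det, gt)$ap, oracle_ap(det, gt, 0.5),
                 tolerance = 1e-6)
    expect_equal(pr_curve_and_ap(det, gt, iou_thr = 0.75)$ap,
                 oracle_ap(det, gt, 0.75), tolerance = 1e-6)
  }
})
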
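test_that("match_detections follows the greedy COCO convention", {
  gts <- rbind(c(0, 0, 10, 10), c(20, 0, 30, 10))
  perfect <- list(boxes = gts, scores = c(0.9, 0.8))
  m <- match_detections(perfect, gts, 0.5)
  expect_true(all(m$tp))
  expect_equal(m$fn, 0)
  # duplicate detections of one ground truth: 1 TP + 1 FP
  dup <- list(boxes = rbind(c(0, 0, 10, 10), c(0.5, 0, 10.5, 10)),
              scores = c(0.9, 0.8))
  m2 <- match_detections(dup, gts[1, , drop = FALSE], 0.5)
  expect_equal(sum(m2$tp), 1L)
  expect_equal(sum(!m2$tp), 1L)
  expect_equal(m2$fn, 0)
  # empty detections
  m3 <- match_detections(list(boxes = NULL, scores = numeric()), gts, 0.5)
  expect_equal(m3$fn, 2)
})

test_that("greedy matching agrees with a loop re-implementation on random scenes", {
  set.seed(61)
  for (rep in 1:25) {
    gts <- t(vapply(1:3, function(i) rand_box(40, 3), numeric(4)))
    dets <- list(boxes = t(vapply(1:5, function(i) rand_box(40, 3), numeric(4))),
                 scores = runif(5))
    ours <- match_detections(dets, gts, 0.3)
    # oracle: same rule, independent code
    ord <- order(dets$scores, decreasing = TRUE)
    taken <- rep(FALSE, 3)
    exp_tp <- logical(5)
    for (k in seq_along(ord)) {
      i <- ord[k]
      best <- 0; bi <- 0
      for (g in 1:3) {
        if (taken[g]) next
        v <- raster_iou_cont(dets$boxes[i, ], gts[g, ])
        if (v > best) { best <- v; bi <- g }
      }
      if (best >= 0.3) { exp_tp[k] <- TRUE; taken[bi] <- TRUE }
    }
    expect_equal(ours$tp, exp_tp)
  }
})

test_that("average_precision reproduces hand-enumerated envelopes", {
  # all ground truths found, no false positives
  gt <- list(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)))
  det_perfect <- list(list(boxes = gt[[1]], scores = c(0.9, 0.8)))
  expect_equal(average_precision(pr_curve(det_perfect, gt, 0.5)), 1)
  # no detections at all
  expect_equal(average_precision(pr_curve(list(list(boxes = NULL, scores = numeric())),
                                          gt, 0.5)), 0)
  # no ground truths: undefined
  expect_true(is.nan(average_precision(pr_curve(det_perfect,
                                                list(matrix(numeric(), 0, 4)), 0.5))))
  # 2 GTs, one TP@0.9 then one FP@0.8: precision envelope gives AP = 0.5
  det <- list(list(boxes = rbind(c(0, 0, 10, 10), c(50, 50, 60, 60)),
                   scores = c(0.9, 0.8)))
  expect_equal(average_precision(pr_curve(det, gt, 0.5)), 0.5, tolerance = 1e-2)
})

test_that("threshold sweep: IoU 0.72 counts as TP up to 0.70 and FP above", {
  gt <- c(0, 0, 10, 10)
  # shift a 10x10 box to hit IoU ~0.72: overlap width w: w*10 /(200-10w)=0.72
  s <- 10 - 2 * 10 * 0.72 / (1 + 0.72)
  det_box <- c(s, 0, 10 + s, 10)
  v <- iou(det_box, gt)
  expect_equal(v, 0.72, tolerance = 1e-9)
  dl <- list(list(boxes = rbind(det_box), scores = 0.9))
  gl <- list(rbind(gt))
  r <- ap_range(dl, gl)
  for (thr in seq(0.5, 0.95, 0.05)) {
    ap <- r$per_threshold[[sprintf("ap%g", thr * 100)]]
    if (thr <= 0.70) expect_equal(ap, 1) else expect_equal(ap, 0)
  }
  expect_equal(r$ap_range, mean(r$per_threshold))
  expect_lte(r$ap75, r$ap50)
})

test_that("AP depends on score ranks only", {
  fx <- random_eval_fixture(8, seed = 62)
  base <- ap_range(fx$dets, fx$gts)$ap_range
  squashed <- lapply(fx$dets, function(d) {
    d$scores <- 1 / (1 + exp(-5 * d$scores))  # monotone transform
    d
  })
  expect_equal(ap_range(squashed, fx$gts)$ap_range, base, tolerance = 1e-12)
})

test_that("evaluator agrees with the independent reference implementation", {
  fx <- random_eval_fixture(12, seed = 63)
  for (thr in c(0.5, 0.75)) {
    ours <- average_precision(pr_curve(fx$dets, fx$gts, thr))
    expect_equal(ours, ref_ap(fx$dets, fx$gts, thr), tolerance = 1e-6)
  }
})

test_that("evaluate_detections stratifies by the dense-subset rule", {
  set.seed(64)
  anns <- list(
    annotated_image("sparse", 100, 100, rbind(c(0, 0, 10, 10))),
    annotated_image("dense", 3000, 20,
                    do.call(rbind, lapply(1:45, function(i)
                      c(i * 6, 0, i * 6 + 12, 12)))))
  gt_list <- lapply(anns, `[[`, "boxes")
  det_list <- lapply(gt_list, function(g) list(boxes = g, scores = runif(nrow(g), 0.5, 1)))
  r <- evaluate_detections(det_list, gt_list, anns = anns, min_objects = 40)
  expect_equal(r$n_dense, 1L)
  expect_equal(r$all$ap50, 1)
  expect_equal(r$dense_subset$ap50, 1)
})
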
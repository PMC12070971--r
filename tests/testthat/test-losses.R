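test_that("ciou_loss matches arithmetic oracles", {
  expect_equal(ciou_loss(c(0, 0, 2, 2), c(0, 0, 2, 2)), 0)
  expect_equal(ciou_loss(c(-1, -1, 1, 1), c(-2, -2, 2, 2)), 0.75)
  expect_equal(ciou_loss(c(0, 0, 1, 2), c(2, 0, 3, 2)), 1 + 4 / 13)
  expect_error(ciou_loss(c(0, 0, 0, 2), c(0, 0, 1, 1)), "positive width")
})

test_that("ciou_loss analytic gradient matches finite differences", {
  set.seed(5)
  for (rep in 1:60) {
    p <- rand_box(); g <- rand_box()
    an <- ciou_loss(p, g, gradient = TRUE)
    fd <- fd_grad(function(x) ciou_loss(x, g), p)
    expect_equal(an$grad, fd, tolerance = 1e-4)
  }
})

test_that("smooth_ln matches its closed form and is C1 at sigma", {
  expect_equal(smooth_ln(0), 0)
  expect_equal(smooth_ln(0.5, 0.5), -log(0.5))
  expect_equal(smooth_ln(0.9, 0.5), 0.8 - log(0.5))
  expect_error(smooth_ln(1), "x >= 1")
  for (sigma in c(0.2, 0.5, 0.8)) {
    eps <- 1e-7
    # continuity
    expect_equal(smooth_ln(sigma - eps, sigma), smooth_ln(sigma + eps, sigma),
                 tolerance = 1e-5)
    # one-sided derivatives agree
    dl <- (smooth_ln(sigma, sigma) - smooth_ln(sigma - eps, sigma)) / eps
    dr <- (smooth_ln(sigma + eps, sigma) - smooth_ln(sigma, sigma)) / eps
    expect_equal(dl, dr, tolerance = 1e-4)
  }
})

test_that("repgt_loss follows the worked examples", {
  w <- loss_weights()
  # single ground truth: no repulsion target exists
  tab1 <- assignment_table(1L)
  expect_equal(repgt_loss(rbind(c(0, 0, 2, 2)), rbind(c(0, 0, 2, 2)), tab1, w), 0)
  # IoG with G_Rep = 0.25, sigma 0.5 -> -ln(0.75)
  preds <- rbind(c(0, 0, 2, 2))
  gts <- rbind(c(0, 0, 2, 2), c(1, 1, 3, 3))
  tab <- assignment_table(1L, rep_idx = 2L)
  expect_equal(repgt_loss(preds, gts, tab, w), -log(0.75))
  # zero IoG contributes nothing
  gts2 <- rbind(c(0, 0, 2, 2), c(5, 5, 6, 6))
  expect_equal(repgt_loss(preds, gts2, tab, w), 0)
  expect_warning(v <- repgt_loss(matrix(numeric(), 0, 4), gts,
                                 assignment_table(integer()), w), "empty")
  expect_equal(v, 0)
})

test_that("repbox_loss counts unordered cross-group overlapping pairs", {
  w <- loss_weights()
  preds <- rbind(c(0, 0, 2, 2), c(1, 1, 3, 3))
  # same group: no repulsion
  expect_equal(repbox_loss(preds, assignment_table(c(1L, 1L)), w), 0)
  # disjoint cross-group preds: numerator zero
  far <- rbind(c(0, 0, 2, 2), c(10, 10, 12, 12))
  expect_equal(repbox_loss(far, assignment_table(c(1L, 2L)), w), 0)
  # IoU = 1/7 via the geometry oracle; one overlapping pair
  v <- repbox_loss(preds, assignment_table(c(1L, 2L)), w)
  expect_equal(v, -log(1 - 1 / 7) / (1 + w$epsilon), tolerance = 1e-9)
  expect_equal(v, 0.1542, tolerance = 1e-3)
})

test_that("occlusion_loss composes its components with alpha/beta", {
  w <- loss_weights(alpha = 0.4, beta = 0.6)
  # perfect predictions, no cross overlap
  preds <- rbind(c(0, 0, 2, 2), c(5, 5, 7, 7))
  gts <- preds
  tab <- assignment_table(c(1L, 2L))
  r <- occlusion_loss(preds, gts, tab, w)
  expect_equal(r$total, 0)
  # repulsion-free scene: total = mean CIoU exactly
  preds2 <- rbind(c(0.2, 0, 2, 2), c(5, 5.3, 7, 7))
  r2 <- occlusion_loss(preds2, gts, tab, w)
  expect_equal(r2$components$repgt, 0)
  expect_equal(r2$components$repbox, 0)
  expect_equal(r2$total, r2$components$ciou)
  # arithmetic composition of the component oracles
  comp <- list(ciou = 0.75, repgt = -log(0.75), repbox = -log(6 / 7))
  expect_equal(comp$ciou + 0.4 * comp$repgt + 0.6 * comp$repbox, 0.9576,
               tolerance = 1e-3)
})

test_that("occlusion_loss with alpha=beta=0 equals mean CIoU", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:5, 1)
    gts <- t(vapply(seq_len(n), function(i) rand_box(20, 2), numeric(4)))
    preds <- gts + matrix(rnorm(4 * n, 0, 0.5), n, 4)
    preds[, 3] <- pmax(preds[, 3], preds[, 1] + 0.5)
    preds[, 4] <- pmax(preds[, 4], preds[, 2] + 0.5)
    tab <- assignment_table(seq_len(n),
                            rep_idx = c(seq_len(n)[-1], NA))
    r <- occlusion_loss(preds, gts, tab, loss_weights(alpha = 0, beta = 0))
    mean_ciou <- mean(vapply(seq_len(n), function(i)
      ciou_loss(preds[i, ], gts[i, ]), 0))
    expect_equal(r$total, mean_ciou, tolerance = 1e-12)
  }
})

test_that("repulsion losses are nonnegative and monotone in overlap", {
  w <- loss_weights()
  gts <- rbind(c(0, 0, 4, 4), c(3, 0, 7, 4))
  tab <- assignment_table(1L, rep_idx = 2L)
  vals <- vapply(seq(0, 2.5, by = 0.5), function(shift) {
    repgt_loss(rbind(c(0 + shift, 0, 4 + shift, 4)), gts, tab, w)
  }, 0)
  expect_true(all(vals >= 0))
  expect_true(all(diff(vals) >= -1e-12))  # moving toward G_Rep increases IoG
  tab2 <- assignment_table(c(1L, 2L))
  vals2 <- vapply(seq(4, 0, by = -1), function(gap) {
    repbox_loss(rbind(c(0, 0, 4, 4), c(gap, 0, gap + 4, 4)), tab2, w)
  }, 0)
  expect_true(all(vals2 >= 0))
  expect_true(all(diff(vals2) >= -1e-12))
})

test_that("occlusion_loss gradient matches finite differences on random scenes", {
  set.seed(13)
  w <- loss_weights()
  for (rep in 1:12) {
    n <- sample(2:4, 1)
    gts <- t(vapply(seq_len(n), function(i) rand_box(15, 2), numeric(4)))
    preds <- gts + matrix(rnorm(4 * n, 0, 0.8), n, 4)
    preds[, 3] <- pmax(preds[, 3], preds[, 1] + 1)
    preds[, 4] <- pmax(preds[, 4], preds[, 2] + 1)
    rep_idx <- vapply(seq_len(n), function(i) {
      others <- setdiff(seq_len(n), i)
      ious <- vapply(others, function(g) iou(preds[i, ], gts[g, ]), 0)
      if (max(ious) > 0) others[which.max(ious)] else NA_integer_
    }, 0L)
    tab <- assignment_table(seq_len(n), rep_idx = rep_idx)
    an <- occlusion_loss(preds, gts, tab, w, gradient = TRUE)
    f <- function(flat) {
      p <- matrix(flat, n, 4)
      occlusion_loss(p, gts, tab, w)$total
    }
    fd <- fd_grad(f, as.vector(preds))
    expect_equal(as.vector(an$grad), fd, tolerance = 1e-4)
  }
})

test_that("classification_loss is a symmetric stable mean BCE", {
  expect_lt(classification_loss(c(20, -20), c(1, 0)), 1e-6)
  expect_equal(classification_loss(0, 1), log(2))
  set.seed(3)
  l <- rnorm(10); t <- runif(10)
  expect_equal(classification_loss(l, t), classification_loss(-l, 1 - t))
  expect_error(classification_loss(c(1, 2), c(1)), "shape")
})
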
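test_that("iou matches trivial and rasterized examples", {
  expect_equal(iou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 / 7)
  expect_warning(v <- iou(c(1, 1, 1, 1), c(2, 2, 2, 2)), "degenerate")
  expect_equal(v, 0)
})

test_that("iog matches examples and rejects degenerate ground truth", {
  expect_equal(iog(c(-1, -1, 5, 5), c(0, 0, 2, 2)), 1)     # p contains g
  expect_equal(iog(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iog(c(0, 0, 2, 2), c(1, 1, 3, 3)), 0.25)
  expect_error(iog(c(0, 0, 1, 1), c(2, 2, 2, 3)), "degenerate")
})

test_that("iou/iog invariants hold on random pairs", {
  set.seed(42)
  for (i in 1:200) {
    a <- rand_box(); b <- rand_box()
    expect_equal(iou(a, b), iou(b, a))
    expect_lte(iou(a, b), min(iog(a, b), iog(b, a)) + 1e-12)
  }
})

test_that("overlap_ratio matches the worked examples", {
  t <- c(0, 0, 4, 4)
  expect_equal(overlap_ratio(t, matrix(numeric(), 0, 4)), 0)
  expect_equal(overlap_ratio(t, rbind(c(-1, -1, 5, 5))), 1)
  expect_equal(overlap_ratio(t, rbind(c(2, 0, 6, 4), c(0, 2, 4, 6))), 0.75)
  expect_error(overlap_ratio(c(1, 1, 1, 3), rbind(t)), "zero area")
})

test_that("overlap_ratio agrees with the rasterized-union oracle", {
  set.seed(7)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    boxes <- t(vapply(seq_len(n), function(i) rand_int_box(10L), numeric(4)))
    or <- overlap_ratio(boxes[1, ], boxes[-1, , drop = FALSE])
    expect_equal(or, raster_or(boxes[1, ], boxes[-1, , drop = FALSE]),
                 tolerance = 1e-9)
  }
})

test_that("overlap_ratio is bounded by the pairwise sum and is monotone", {
  set.seed(8)
  for (rep in 1:50) {
    t <- rand_box(); n <- sample(1:5, 1)
    others <- t(vapply(seq_len(n), function(i) rand_box(), numeric(4)))
    or_all <- overlap_ratio(t, others)
    pair_sum <- sum(vapply(seq_len(n), function(j) {
      int <- sddetect:::intersect_box(t, others[j, ])
      if (is.null(int)) 0 else box_area(int) / box_area(t)
    }, 0))
    expect_lte(or_all, min(1, pair_sum) + 1e-12)
    # adding a neighbour can only increase OR
    extra <- rand_box()
    expect_gte(overlap_ratio(t, rbind(others, extra)), or_all - 1e-12)
  }
})

test_that("image_or averages per-box values and handles empty images", {
  img0 <- annotated_image("e", 10, 10, matrix(numeric(), 0, 4))
  expect_equal(image_or(img0)$image_or, 0)
  two <- annotated_image("d", 10, 10, rbind(c(0, 0, 2, 2), c(5, 5, 7, 7)))
  expect_equal(image_or(two)$image_or, 0)
  same <- annotated_image("s", 10, 10, rbind(c(1, 1, 3, 3), c(1, 1, 3, 3)))
  r <- image_or(same)
  expect_equal(r$per_box_or, c(1, 1))
  expect_equal(r$image_or, 1)
  # mean of per-box rasterized values on a 3-box scene
  boxes <- rbind(c(0, 0, 4, 4), c(2, 0, 6, 4), c(0, 2, 4, 6))
  img <- annotated_image("m", 8, 8, boxes)
  r <- image_or(img)
  per <- vapply(1:3, function(i) raster_or(boxes[i, ], boxes[-i, , drop = FALSE]), 0)
  expect_equal(r$per_box_or, per, tolerance = 1e-9)
  expect_equal(r$image_or, mean(per), tolerance = 1e-9)
})

test_that("dense_subset applies both thresholds strictly", {
  mk <- function(n, or_like) {
    # n identical-ish boxes: pairwise-overlapping grid tuned by or_like
    if (or_like > 0) {
      boxes <- do.call(rbind, lapply(seq_len(n), function(i)
        c(0, 0, 10, 10) + (i %% 2) * 2))
    } else {
      boxes <- do.call(rbind, lapply(seq_len(n), function(i)
        c(20 * i, 0, 20 * i + 10, 10)))
    }
    annotated_image(paste0("img", n, "_", or_like), 2000, 50, boxes)
  }
  dense41 <- mk(41, 1)   # OR > 0.5, 41 objects
  dense40 <- mk(40, 1)   # OR > 0.5, but only 40 objects
  sparse50 <- mk(50, 0)  # 50 objects, OR = 0
  expect_gt(image_or(dense41)$image_or, 0.5)
  out <- dense_subset(list(dense41, dense40, sparse50))
  expect_length(out, 1)
  expect_identical(out[[1]]$image_id, dense41$image_id)
  # boundary: OR exactly 0.5 must be excluded -> emulate via thresholds
  expect_length(dense_subset(list(dense41), or_thr = image_or(dense41)$image_or), 0)
  # order invariance and idempotence
  out2 <- dense_subset(list(sparse50, dense40, dense41))
  expect_identical(out2[[1]]$image_id, dense41$image_id)
  expect_identical(dense_subset(out), out)
})

test_that("annotated_image clips boxes to the frame", {
  a <- annotated_image("c", 10, 8, rbind(c(-2, -1, 5, 4), c(6, 3, 14, 12)))
  expect_true(all(a$boxes[, c(1, 3)] >= 0 & a$boxes[, c(1, 3)] <= 10))
  expect_true(all(a$boxes[, c(2, 4)] >= 0 & a$boxes[, c(2, 4)] <= 8))
  expect_error(annotated_image("b", 10, 8, rbind(c(0, 0, 1, 1)), class_ids = -1L),
               "nonnegative")
})
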
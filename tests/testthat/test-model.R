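test_that("model forward emits three level maps at strides 8/16/32", {
  cfg <- toy_model_config(input_size = 96L)
  m <- build_model(cfg)
  x <- array(0.5, dim = c(96, 96, 3))
  out <- m$forward(x)
  sddetect:::clear_caches(m)
  expect_equal(dim(out[[1]]$cls)[1:2], c(12L, 12L))
  expect_equal(dim(out[[2]]$cls)[1:2], c(6L, 6L))
  expect_equal(dim(out[[3]]$cls)[1:2], c(3L, 3L))
  expect_equal(dim(out[[1]]$reg)[3], 4L * 17L)
})

test_that("build is deterministic given a seed and monotone across variants", {
  c1 <- toy_model_config(seed = 5L)
  m1 <- build_model(c1); m2 <- build_model(c1)
  expect_equal(sddetect:::param_checksum(m1), sddetect:::param_checksum(m2))
  m3 <- build_model(toy_model_config(seed = 6L))
  expect_false(isTRUE(all.equal(sddetect:::param_checksum(m1),
                                sddetect:::param_checksum(m3))))
  # n < s < m in parameters and FLOPs (full-width builds)
  pn <- count_params(build_model(model_config("n")))
  ps <- count_params(build_model(model_config("s")))
  pm <- count_params(build_model(model_config("m")))
  expect_lt(pn, ps); expect_lt(ps, pm)
  # s-variant total brackets the published baseline-vs-modified pair
  # (11.2 M -> 9.0 M); our wavelet block follows the documented single-path
  # 1x1 design and is ~0.5 M lighter than the published one, so the lower
  # edge sits below 9 M
  expect_gt(ps, 8); expect_lt(ps, 11.5)
})

test_that("parameter accounting is consistent and OPAM removal reduces it", {
  cfg <- toy_model_config()
  m <- build_model(cfg)
  expect_equal(sddetect:::n_params(m$head),
               count_head_params(m$hcfg, sddetect:::channel_plan(cfg)$ch[3:5]))
  m_no_opam <- build_model(toy_model_config(opam = list(enabled = FALSE)))
  expect_lt(count_params(m_no_opam), count_params(m))
})

test_that("full-size ablation builds reproduce the published parameter column", {
  tab <- benchmark_table("component_ablation")
  for (r in c(1, 3, 4, 5, 9)) {  # one row per distinct module combination
    cfg <- model_config("s", seed = r,
                        weconv = list(enabled = tab$weconv[r] == 1),
                        opam = list(enabled = tab$opam[r] == 1),
                        head = list(ls = tab$ls_head[r] == 1))
    got <- count_params(build_model(cfg))
    if (tab$weconv[r] == 1) {
      # our single-path 1x1 wavelet block is documented as lighter than the
      # published variant; never heavier, at most ~0.9 M lighter
      expect_lte(got, tab$params_m[r] + 0.1)
      expect_gte(got, tab$params_m[r] - 0.9)
    } else {
      expect_equal(got, tab$params_m[r], tolerance = 0.25 / tab$params_m[r])
    }
  }
})

test_that("estimate_flops follows the conv scaling law and closed form", {
  cfg <- toy_model_config(input_size = 64L)
  m <- build_model(cfg)
  f64 <- estimate_flops(m, 64)
  f128 <- estimate_flops(m, 128)
  expect_equal(f128 / f64, 4, tolerance = 0.05)
  # single conv layer: 2 * k^2 * cin * cout * H * W
  conv <- sddetect:::new_conv_block(4, 8, k = 3, stride = 1)
  sddetect:::prof_start()
  conv$forward(array(0, dim = c(10, 10, 4)))
  macs <- sddetect:::prof_stop()
  sddetect:::clear_caches(conv)
  expect_equal(2 * macs, 2 * 9 * 4 * 8 * 10 * 10)
})

test_that("assign_targets matches the exhaustive oracle on a toy grid", {
  grid <- anchor_grid(32, strides = 8L)  # 4x4 single-level grid
  set.seed(51)
  gts <- rbind(c(2, 2, 14, 14), c(18, 18, 30, 30))
  pred_boxes <- t(vapply(seq_len(nrow(grid$points)), function(i)
    c(grid$points[i, 1] - 5, grid$points[i, 2] - 5,
      grid$points[i, 1] + 5, grid$points[i, 2] + 5), numeric(4)))
  scores <- runif(nrow(pred_boxes), 0.1, 0.9)
  asg <- assign_targets(gts, grid, pred_boxes, scores, topk = 3)
  # brute-force alignment enumeration
  eps <- 1e-9
  for (g in 1:2) {
    inside <- which(grid$points[, 1] > gts[g, 1] & grid$points[, 1] < gts[g, 3] &
                      grid$points[, 2] > gts[g, 2] & grid$points[, 2] < gts[g, 4])
    al <- vapply(inside, function(i)
      (scores[i] + eps)^0.5 * (iou(pred_boxes[i, ], gts[g, ]) + eps)^6, 0)
    expect_top <- inside[order(al, decreasing = TRUE)][1:min(3, length(inside))]
    got <- asg$pos_idx[asg$table$attr_idx == g]
    expect_setequal(got, expect_top)
  }
  # disjoint ground truths -> positives partition into two groups
  expect_setequal(unique(asg$table$group), c(1L, 2L))
  # single centred GT has at least one positive
  asg1 <- assign_targets(rbind(c(8, 8, 24, 24)), grid, pred_boxes, scores)
  expect_gte(length(asg1$pos_idx), 1L)
  # zero ground truths -> all negative
  asg0 <- assign_targets(matrix(numeric(), 0, 4), grid, pred_boxes, scores)
  expect_length(asg0$pos_idx, 0L)
})

test_that("decode_and_nms deduplicates and matches the reference NMS", {
  set.seed(52)
  boxes <- t(vapply(1:50, function(i) rand_box(60, 2), numeric(4)))
  scores <- runif(50)
  for (thr in c(0.3, 0.5, 0.65)) {
    expect_equal(sort(nms(boxes, scores, thr)), sort(ref_nms(boxes, scores, thr)))
  }
  # identical candidates collapse to one, disjoint ones all survive
  two <- rbind(c(0, 0, 4, 4), c(0, 0, 4, 4))
  expect_length(nms(two, c(0.9, 0.8), 0.65), 1L)
  far <- rbind(c(0, 0, 4, 4), c(10, 10, 14, 14), c(20, 0, 24, 4))
  expect_length(nms(far, c(0.9, 0.8, 0.7), 0.65), 3L)
})

test_that("the ablation grid of module on/off combinations builds and steps", {
  sc <- suppressWarnings(generate_scene(scene_spec(
    n_objects = 5, image_size = 64, size_range = c(10, 20),
    target_or = 0.3, seed = 77)))
  combos <- expand.grid(occl = c(TRUE, FALSE), weconv = c(TRUE, FALSE),
                        opam = c(TRUE, FALSE), ls = c(TRUE, FALSE))
  # 8 of the 16 rows mirror the published ablation grid; run all 16 cheaply
  for (r in seq_len(nrow(combos))) {
    cfg <- toy_model_config(seed = r,
                            weconv = list(enabled = combos$weconv[r]),
                            opam = list(enabled = combos$opam[r]),
                            head = list(ls = combos$ls[r]))
    m <- build_model(cfg)
    w <- if (combos$occl[r]) loss_weights() else loss_weights(alpha = 0, beta = 0)
    log <- train_loop(list(list(image = sc$image, ann = sc$annotations)),
                      m, iters = 1L, batch = 1L, w = w, seed = 1L)
    expect_true(is.finite(log$total[1]))
  }
})

test_that("training reduces the loss and honours configuration conservation", {
  set.seed(53)
  ds <- lapply(1:8, function(i) {
    sc <- suppressWarnings(generate_scene(scene_spec(
      n_objects = 6, image_size = 64, size_range = c(10, 20),
      target_or = 0.25, seed = 600 + i)))
    list(image = sc$image, ann = sc$annotations)
  })
  m <- build_model(toy_model_config(seed = 2L))
  log <- train_loop(ds, m, iters = 20L, batch = 4L, seed = 3L)
  expect_lt(mean(utils::tail(log$total, 5)), mean(utils::head(log$total, 5)))
  # component bookkeeping: gains-weighted parts sum to the logged total
  g <- list(box = 7.5, cls = 0.5, dfl = 1.5)
  w <- loss_weights()
  recomposed <- g$box * (log$ciou + w$alpha * log$repgt + w$beta * log$repbox) +
    g$cls * log$cls + g$dfl * log$dfl
  expect_equal(log$total, recomposed, tolerance = 1e-6)
  # alpha = beta = 0 reproduces a CIoU-only trajectory bit for bit
  m1 <- build_model(toy_model_config(seed = 9L))
  l1 <- train_loop(ds[1:2], m1, iters = 3L, batch = 2L,
                   w = loss_weights(alpha = 0, beta = 0), seed = 4L)
  m2 <- build_model(toy_model_config(seed = 9L))
  l2 <- train_loop(ds[1:2], m2, iters = 3L, batch = 2L,
                   w = loss_weights(alpha = 0, beta = 0,
                                    sigma_repgt = 0.9, sigma_repbox = 0.9),
                   seed = 4L)
  expect_identical(l1$total, l2$total)
  expect_identical(sddetect:::param_checksum(m1), sddetect:::param_checksum(m2))
})

test_that("checkpoints round-trip through save/load", {
  m <- build_model(toy_model_config(seed = 12L))
  path <- tempfile(fileext = ".rds")
  save_weights(m, path)
  m2 <- load_weights(path)
  expect_equal(sddetect:::param_checksum(m), sddetect:::param_checksum(m2))
  x <- array(0.3, dim = c(64, 64, 3))
  o1 <- m$forward(x); o2 <- m2$forward(x)
  expect_equal(o1[[1]]$cls, o2[[1]]$cls, tolerance = 1e-12)
  unlink(path)
})
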
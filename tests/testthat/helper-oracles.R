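# Independent oracles used across the suite. These deliberately use naive
# algorithms (rasterized counting, O(n^2) loops, direct enumeration) and must
# stay independent of the package's production code paths.

# Rasterized union-of-intersections Overlap Ratio on integer-coordinate
# boxes: count unit grid cells of `target` covered by any neighbour.
raster_or <- function(target, others) {
  xs <- (target[1] + 1):target[3] - 0.5
  ys <- (target[2] + 1):target[4] - 0.5
  if (length(xs) == 0L || length(ys) == 0L) stop("degenerate target")
  covered <- 0L
  for (cx in xs) for (cy in ys) {
    for (k in seq_len(nrow(others))) {
      o <- others[k, ]
      if (cx > o[1] && cx < o[3] && cy > o[2] && cy < o[4]) {
        covered <- covered + 1L
        break
      }
    }
  }
  covered / (length(xs) * length(ys))
}

# Rasterized IoU / IoG oracles on integer boxes.
raster_count <- function(b) max(0, b[3] - b[1]) * max(0, b[4] - b[2])

raster_iou <- function(a, b) {
  inter <- c(max(a[1], b[1]), max(a[2], b[2]), min(a[3], b[3]), min(a[4], b[4]))
  ia <- if (inter[3] > inter[1] && inter[4] > inter[2]) raster_count(inter) else 0
  ia / (raster_count(a) + raster_count(b) - ia)
}

# O(n^2) reference NMS.
ref_nms <- function(boxes, scores, thr) {
  n <- nrow(boxes)
  ord <- order(scores, decreasing = TRUE)
  suppressed <- rep(FALSE, n)
  keep <- integer()
  for (ii in seq_len(n)) {
    i <- ord[ii]
    if (suppressed[i]) next
    keep <- c(keep, i)
    for (jj in seq_len(n)) {
      j <- ord[jj]
      if (j == i || suppressed[j]) next
      if (scores[j] > scores[i]) next
      inter <- c(max(boxes[i, 1], boxes[j, 1]), max(boxes[i, 2], boxes[j, 2]),
                 min(boxes[i, 3], boxes[j, 3]), min(boxes[i, 4], boxes[j, 4]))
      ia <- if (inter[3] > inter[1] && inter[4] > inter[2])
        (inter[3] - inter[1]) * (inter[4] - inter[2]) else 0
      un <- (boxes[i, 3] - boxes[i, 1]) * (boxes[i, 4] - boxes[i, 2]) +
        (boxes[j, 3] - boxes[j, 1]) * (boxes[j, 4] - boxes[j, 2]) - ia
      if (ia / un > thr) suppressed[j] <- TRUE
    }
  }
  keep
}

# Independent COCO-style AP: greedy matching re-implemented with plain loops
# and 101-point interpolation done by direct max-filtering (no cummax).
ref_ap <- function(det_list, gt_list, iou_thr) {
  recs <- list()
  n_gt <- 0L
  for (i in seq_along(det_list)) {
    d <- det_list[[i]]
    g <- gt_list[[i]]
    n_gt <- n_gt + nrow(g)
    if (length(d$scores) == 0L) next
    ord <- order(d$scores, decreasing = TRUE)
    taken <- rep(FALSE, nrow(g))
    for (k in ord) {
      best <- 0; bi <- 0L
      if (nrow(g) > 0) for (gi in seq_len(nrow(g))) {
        if (taken[gi]) next
        v <- raster_iou_cont(d$boxes[k, ], g[gi, ])
        if (v > best) { best <- v; bi <- gi }
      }
      hit <- best >= iou_thr
      if (hit) taken[bi] <- TRUE
      recs[[length(recs) + 1L]] <- c(d$scores[k], hit)
    }
  }
  if (n_gt == 0L) return(NaN)
  if (length(recs) == 0L) return(0)
  m <- do.call(rbind, recs)
  m <- m[order(m[, 1], decreasing = TRUE), , drop = FALSE]
  tp <- cumsum(m[, 2]); fp <- cumsum(1 - m[, 2])
  prec <- tp / (tp + fp); rec <- tp / n_gt
  mean(vapply(seq(0, 1, 0.01), function(r) {
    sel <- rec >= r
    if (any(sel)) max(prec[sel]) else 0
  }, 0))
}

# continuous IoU used by the reference evaluator (kept local on purpose)
raster_iou_cont <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  ia <- if (iw > 0 && ih > 0) iw * ih else 0
  un <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - ia
  if (un <= 0) 0 else ia / un
}

# Random valid box with integer corners inside [0, s]^2.
rand_int_box <- function(s = 12L, min_side = 1L) {
  repeat {
    x <- sort(sample(0:s, 2)); y <- sort(sample(0:s, 2))
    if (x[2] - x[1] >= min_side && y[2] - y[1] >= min_side)
      return(c(x[1], y[1], x[2], y[2]))
  }
}

# Random continuous box.
rand_box <- function(lim = 10, min_side = 0.5) {
  repeat {
    x <- sort(runif(2, 0, lim)); y <- sort(runif(2, 0, lim))
    if (x[2] - x[1] >= min_side && y[2] - y[1] >= min_side)
      return(c(x[1], y[1], x[2], y[2]))
  }
}

# Central finite-difference gradient of f at x (vector-valued x).
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, 0)
}

# Tiny toy detector config shared by the model-level tests.
toy_model_config <- function(seed = 1L, input_size = 64L, weconv = list(),
                             opam = list(), head = list()) {
  model_config("s", width_mult = 0.125, input_size = input_size, seed = seed,
               weconv = weconv, opam = opam,
               head = utils::modifyList(list(middle_channel = 32L), head))
}

# Small random detection fixture (independent of the generator/model).
random_eval_fixture <- function(n_images = 20L, seed = 99L) {
  set.seed(seed)
  gt_list <- list(); det_list <- list()
  for (i in seq_len(n_images)) {
    ng <- sample(2:8, 1)
    gts <- t(vapply(seq_len(ng), function(j) rand_box(50, 3), numeric(4)))
    dets <- list(boxes = matrix(0, 0, 4), scores = numeric())
    for (j in seq_len(ng)) {
      # jittered true positives with varying quality, plus clutter
      if (runif(1) < 0.85) {
        jit <- rnorm(4, 0, runif(1, 0.2, 3))
        dets$boxes <- rbind(dets$boxes, gts[j, ] + jit)
        dets$scores <- c(dets$scores, runif(1, 0.3, 1))
      }
    }
    for (k in seq_len(sample(0:3, 1))) {
      dets$boxes <- rbind(dets$boxes, rand_box(50, 2))
      dets$scores <- c(dets$scores, runif(1, 0, 0.6))
    }
    # clip to valid boxes
    dets$boxes[, 3] <- pmax(dets$boxes[, 3], dets$boxes[, 1] + 0.1)
    dets$boxes[, 4] <- pmax(dets$boxes[, 4], dets$boxes[, 2] + 0.1)
    gt_list[[i]] <- gts
    det_list[[i]] <- dets
  }
  list(dets = det_list, gts = gt_list)
}
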
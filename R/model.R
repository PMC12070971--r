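# Full detector assembly: backbone (wavelet-enhanced downsampling + C2f +
# SPPF), PAN-style neck with occlusion-perceptual fusion of the stride-4
# detail features, and the lightweight shared head; plus target assignment,
# box decoding, NMS, parameter/FLOP accounting and a CPU training loop.

#' Model configuration
#'
#' Variants follow the usual n/s/m scaling: depth multiplier scales the
#' number of C2f bottlenecks, width multiplier the channel plan (base
#' channels 64/128/256/512/1024, capped at `max_channels`).
#'
#' @param variant One of "n", "s", "m".
#' @param depth_mult,width_mult Override the variant defaults.
#' @param max_channels Channel cap before width scaling.
#' @param input_size Square input resolution, divisible by 32.
#' @param weconv List: `enabled`, `levels`, `kernel`, `stages` (which of the
#'   four stride-2 stage transitions use the wavelet block; default 2:5).
#' @param opam List: `enabled`, `reduction`, `shared_gate`, `gate_kernel`.
#' @param head List: `ls` (shared head vs decoupled), `middle_channel`,
#'   `use_dfl`, `reg_max`.
#' @param num_classes Number of classes (single-class default).
#' @param seed Seed governing weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(variant = c("s", "n", "m"),
                         depth_mult = NULL, width_mult = NULL,
                         max_channels = NULL, input_size = 256L,
                         weconv = list(), opam = list(), head = list(),
                         num_classes = 1L, seed = 0L) {
  variant <- match.arg(variant)
  defaults <- list(n = c(0.33, 0.25, 1024), s = c(0.33, 0.50, 1024),
                   m = c(0.67, 0.75, 768))[[variant]]
  if (is.null(depth_mult)) depth_mult <- defaults[1]
  if (is.null(width_mult)) width_mult <- defaults[2]
  if (is.null(max_channels)) max_channels <- defaults[3]
  if (input_size %% 32L != 0L) stop("input_size must be divisible by 32")
  weconv <- utils::modifyList(list(enabled = TRUE, levels = 1L, kernel = 5L,
                                   stages = 2:5), weconv)
  opam <- utils::modifyList(list(enabled = TRUE, reduction = 16L,
                                 shared_gate = FALSE, gate_kernel = 7L), opam)
  head <- utils::modifyList(list(ls = TRUE, middle_channel = 128L,
                                 use_dfl = TRUE, reg_max = 16L), head)
  structure(list(variant = variant, depth_mult = depth_mult,
                 width_mult = width_mult, max_channels = max_channels,
                 input_size = as.integer(input_size), weconv = weconv,
                 opam = opam, head = head, num_classes = as.integer(num_classes),
                 seed = as.integer(seed)),
            class = "model_config")
}

# Channel plan and stage depths for a config.
channel_plan <- function(cfg) {
  base <- c(64L, 128L, 256L, 512L, 1024L)
  ch <- vapply(base, function(b) {
    v <- min(b, cfg$max_channels) * cfg$width_mult
    max(2L, 2L * as.integer(ceiling(v / 2)))  # even, >= 2
  }, 0L)
  depths <- vapply(c(3L, 6L, 6L, 3L), function(n)
    max(1L, as.integer(round(n * cfg$depth_mult))), 0L)
  list(ch = ch, depths = depths,
       neck_depth = max(1L, as.integer(round(3L * cfg$depth_mult))))
}

# -- building blocks ----------------------------------------------------------

new_bottleneck <- function(c, shortcut = TRUE) {
  m <- new_module("bottleneck")
  m$b1 <- new_conv_block(c, c, 3L)
  m$b2 <- new_conv_block(c, c, 3L)
  m$shortcut <- shortcut
  m$children <- list(m$b1, m$b2)
  m$forward <- function(x) {
    y <- m$b2$forward(m$b1$forward(x))
    if (m$shortcut) y + x else y
  }
  m$backward <- function(dy) {
    dx <- m$b1$backward(m$b2$backward(dy))
    if (m$shortcut) dx + dy else dx
  }
  m
}

new_c2f <- function(cin, cout, n = 1L, shortcut = TRUE) {
  if (cout %% 2L != 0L) stop("c2f output channels must be even")
  m <- new_module("c2f")
  c <- cout %/% 2L
  m$c <- c; m$n <- as.integer(n)
  m$cv1 <- new_conv_block(cin, cout, 1L)
  m$blocks <- lapply(seq_len(n), function(i) new_bottleneck(c, shortcut))
  m$cv2 <- new_conv_block((2L + n) * c, cout, 1L)
  m$children <- c(list(m$cv1, m$cv2), m$blocks)
  m$forward <- function(x) {
    y <- m$cv1$forward(x)
    d <- fm_dims(y)
    parts <- list(y[, , seq_len(m$c), drop = FALSE],
                  y[, , m$c + seq_len(m$c), drop = FALSE])
    for (b in m$blocks) parts[[length(parts) + 1L]] <- b$forward(parts[[length(parts)]])
    z <- array(0, dim = c(d[1], d[2], (2L + m$n) * m$c))
    for (i in seq_along(parts)) z[, , (i - 1L) * m$c + seq_len(m$c)] <- parts[[i]]
    m$cv2$forward(z)
  }
  m$backward <- function(dy) {
    dz <- m$cv2$backward(dy)
    dparts <- lapply(seq_len(2L + m$n), function(i)
      dz[, , (i - 1L) * m$c + seq_len(m$c), drop = FALSE])
    dcur <- dparts[[2L + m$n]]
    for (i in rev(seq_len(m$n))) {
      dprev <- m$blocks[[i]]$backward(dcur)
      dcur <- dparts[[i + 1L]] + dprev
    }
    dfull <- cat_channels(dparts[[1L]], dcur)
    m$cv1$backward(dfull)
  }
  m
}

new_sppf <- function(cin, cout) {
  m <- new_module("sppf")
  c_ <- max(2L, cin %/% 2L)
  m$cv1 <- new_conv_block(cin, c_, 1L)
  m$mp <- new_maxpool(5L, 1L, 2L)
  m$cv2 <- new_conv_block(4L * c_, cout, 1L)
  m$c_ <- c_
  m$children <- list(m$cv1, m$mp, m$cv2)
  m$forward <- function(x) {
    y0 <- m$cv1$forward(x)
    y1 <- m$mp$forward(y0); y2 <- m$mp$forward(y1); y3 <- m$mp$forward(y2)
    d <- fm_dims(y0)
    z <- array(0, dim = c(d[1], d[2], 4L * m$c_))
    z[, , seq_len(m$c_)] <- y0
    z[, , m$c_ + seq_len(m$c_)] <- y1
    z[, , 2L * m$c_ + seq_len(m$c_)] <- y2
    z[, , 3L * m$c_ + seq_len(m$c_)] <- y3
    m$cv2$forward(z)
  }
  m$backward <- function(dy) {
    dz <- m$cv2$backward(dy)
    dp <- lapply(0:3, function(i) dz[, , i * m$c_ + seq_len(m$c_), drop = FALSE])
    dy2 <- dp[[3]] + m$mp$backward(dp[[4]])
    dy1 <- dp[[2]] + m$mp$backward(dy2)
    dy0 <- dp[[1]] + m$mp$backward(dy1)
    m$cv1$backward(dy0)
  }
  m
}

# -- model assembly -----------------------------------------------------------

#' Build a detector from a configuration
#'
#' Construction is deterministic given `cfg$seed`. The returned model is an
#' `sdd_module` whose `forward(x)` takes an `(H, W, 3)` image array and
#' returns per-level head outputs, and whose `backward(dout)` backpropagates
#' gradients into all parameters.
#'
#' @param cfg A [model_config].
#' @return An `sdd_module` of type "sdd_model".
#' @export
build_model <- function(cfg = model_config()) {
  plan <- channel_plan(cfg)
  ch <- plan$ch; nd <- plan$depths
  with_seed(cfg$seed, {
    m <- new_module("sdd_model")
    m$cfg <- cfg
    m$ch <- ch
    down <- function(stage, cin, cout) {
      if (cfg$weconv$enabled && stage %in% cfg$weconv$stages)
        new_weconv(cin, cout, cfg$weconv$levels, cfg$weconv$kernel)
      else new_conv_block(cin, cout, 3L, stride = 2L)
    }
    m$stem <- new_conv_block(3L, ch[1], 3L, stride = 2L)
    m$down2 <- down(2L, ch[1], ch[2]); m$c2f2 <- new_c2f(ch[2], ch[2], nd[1])
    m$down3 <- down(3L, ch[2], ch[3]); m$c2f3 <- new_c2f(ch[3], ch[3], nd[2])
    m$down4 <- down(4L, ch[3], ch[4]); m$c2f4 <- new_c2f(ch[4], ch[4], nd[3])
    m$down5 <- down(5L, ch[4], ch[5]); m$c2f5 <- new_c2f(ch[5], ch[5], nd[4])
    m$sppf <- new_sppf(ch[5], ch[5])
    ndn <- plan$neck_depth
    m$c2f_n1 <- new_c2f(ch[5] + ch[4], ch[4], ndn, shortcut = FALSE)
    m$c2f_n2 <- new_c2f(ch[4] + ch[3], ch[3], ndn, shortcut = FALSE)
    if (cfg$opam$enabled)
      m$opam <- new_opam(ch[2], ch[3], ch[3], cfg$opam$reduction,
                         cfg$opam$shared_gate, cfg$opam$gate_kernel)
    m$down_p3 <- new_conv_block(ch[3], ch[3], 3L, stride = 2L)
    m$c2f_n3 <- new_c2f(ch[3] + ch[4], ch[4], ndn, shortcut = FALSE)
    m$down_p4 <- new_conv_block(ch[4], ch[4], 3L, stride = 2L)
    m$c2f_n4 <- new_c2f(ch[4] + ch[5], ch[5], ndn, shortcut = FALSE)
    hcfg <- head_config(middle_channel = cfg$head$middle_channel,
                        reg_max = cfg$head$reg_max, use_dfl = cfg$head$use_dfl,
                        num_classes = cfg$num_classes,
                        gn_groups = gn_groups_for(cfg$head$middle_channel, 16L))
    m$hcfg <- hcfg
    m$head <- if (cfg$head$ls) new_ls_head(ch[3:5], hcfg)
              else new_decoupled_head(ch[3:5], hcfg)
    m$children <- Filter(Negate(is.null),
      list(m$stem, m$down2, m$c2f2, m$down3, m$c2f3, m$down4, m$c2f4,
           m$down5, m$c2f5, m$sppf, m$c2f_n1, m$c2f_n2, m$opam,
           m$down_p3, m$c2f_n3, m$down_p4, m$c2f_n4, m$head))
    m$forward <- function(x) {
      C1 <- m$stem$forward(x)
      C2 <- m$c2f2$forward(m$down2$forward(C1))
      C3 <- m$c2f3$forward(m$down3$forward(C2))
      C4 <- m$c2f4$forward(m$down4$forward(C3))
      C5 <- m$sppf$forward(m$c2f5$forward(m$down5$forward(C4)))
      F4 <- m$c2f_n1$forward(cat_channels(upsample2x(C5), C4))
      F3 <- m$c2f_n2$forward(cat_channels(upsample2x(F4), C3))
      P3 <- if (!is.null(m$opam)) m$opam$forward(C2, F3) else F3
      P4 <- m$c2f_n3$forward(cat_channels(m$down_p3$forward(P3), F4))
      P5 <- m$c2f_n4$forward(cat_channels(m$down_p4$forward(P4), C5))
      m$head$forward(list(P3, P4, P5))
    }
    m$backward <- function(dout) {
      ch <- m$ch
      dlev <- m$head$backward(dout)
      dcat4 <- m$c2f_n4$backward(dlev[[3]])
      sp <- split_channels_bw(dcat4, ch[4]); dd4 <- sp[[1]]; dC5 <- sp[[2]]
      dP4 <- dlev[[2]] + m$down_p4$backward(dd4)
      dcat3 <- m$c2f_n3$backward(dP4)
      sp <- split_channels_bw(dcat3, ch[3]); dd3 <- sp[[1]]; dF4 <- sp[[2]]
      dP3 <- dlev[[1]] + m$down_p3$backward(dd3)
      if (!is.null(m$opam)) {
        dop <- m$opam$backward(dP3)
        dC2 <- dop$d_low; dF3 <- dop$d_high
      } else { dC2 <- NULL; dF3 <- dP3 }
      dcat2 <- m$c2f_n2$backward(dF3)
      sp <- split_channels_bw(dcat2, ch[4]); du2 <- sp[[1]]; dC3 <- sp[[2]]
      dF4 <- dF4 + upsample2x_bw(du2)
      dcat1 <- m$c2f_n1$backward(dF4)
      sp <- split_channels_bw(dcat1, ch[5]); du1 <- sp[[1]]; dC4 <- sp[[2]]
      dC5 <- dC5 + upsample2x_bw(du1)
      dt5 <- m$c2f5$backward(m$sppf$backward(dC5))
      dC4 <- dC4 + m$down5$backward(dt5)
      dC3 <- dC3 + m$down4$backward(m$c2f4$backward(dC4))
      dC2x <- m$down3$backward(m$c2f3$backward(dC3))
      dC2 <- if (is.null(dC2)) dC2x else dC2 + dC2x
      dC1 <- m$down2$backward(m$c2f2$backward(dC2))
      m$stem$backward(dC1)
    }
    m
  })
}

#' Total learned parameters, in millions
#'
#' @param model A built model (any `sdd_module`).
#' @return Parameter count / 1e6, rounded to 2 decimals.
#' @export
count_params <- function(model) round(n_params(model) / 1e6, 2)

#' Estimate forward-pass FLOPs by layer-formula accumulation
#'
#' Multiply-accumulate operations of every convolution are counted during a
#' profiled forward pass on a zero image and doubled (normalizations and
#' activations are negligible by comparison).
#'
#' @param model A built model.
#' @param input_size Square input resolution (defaults to the model config).
#' @return GFLOPs.
#' @export
estimate_flops <- function(model, input_size = model$cfg$input_size) {
  x <- array(0, dim = c(input_size, input_size, 3L))
  prof_start()
  model$forward(x)
  macs <- prof_stop()
  clear_caches(model)
  2 * macs / 1e9
}

# -- anchors, decoding, NMS ---------------------------------------------------

#' Anchor-point grid for the three pyramid levels
#'
#' @param input_size Square input resolution.
#' @param strides Level strides (default 8/16/32).
#' @return List: `points` (n x 2 centres, pixels), `stride` (length n),
#'   `level_dims` (per-level H, W), `level_offset` (row offsets).
#' @export
anchor_grid <- function(input_size, strides = c(8L, 16L, 32L)) {
  pts <- list(); st <- list(); dims <- list(); off <- integer(length(strides))
  total <- 0L
  for (li in seq_along(strides)) {
    s <- strides[li]
    H <- input_size %/% s; W <- input_size %/% s
    g <- expand.grid(h = seq_len(H), w = seq_len(W))  # h fastest: matches matrix()
    pts[[li]] <- cbind((g$w - 0.5) * s, (g$h - 0.5) * s)
    st[[li]] <- rep(s, H * W)
    dims[[li]] <- c(H, W)
    off[li] <- total
    total <- total + H * W
  }
  list(points = do.call(rbind, pts), stride = unlist(st),
       level_dims = dims, level_offset = off)
}

flatten_head_outputs <- function(outputs) {
  cls <- do.call(rbind, lapply(outputs, function(o) {
    d <- fm_dims(o$cls); matrix(o$cls, d[1] * d[2], d[3])
  }))
  reg <- do.call(rbind, lapply(outputs, function(o) {
    d <- fm_dims(o$reg); matrix(o$reg, d[1] * d[2], d[3])
  }))
  list(cls = cls, reg = reg)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Decode flattened regression outputs to boxes. Returns boxes plus whatever
# the gradient chain needs.
decode_boxes <- function(reg, grid, use_dfl, reg_max) {
  n <- nrow(reg)
  dist <- matrix(0, n, 4)
  aux <- NULL
  if (use_dfl) {
    nb <- reg_max + 1L
    probs <- vector("list", 4L)
    bins <- 0:reg_max
    for (s in 1:4) {
      p <- softmax_rows(reg[, (s - 1L) * nb + seq_len(nb), drop = FALSE])
      probs[[s]] <- p
      dist[, s] <- as.vector(p %*% bins)
    }
    aux <- list(probs = probs, bins = bins)
  } else {
    dist <- log1p(exp(pmin(reg, 30)))  # softplus keeps distances positive
    aux <- list(sig = 1 / (1 + exp(-reg)))
  }
  ax <- grid$points[, 1]; ay <- grid$points[, 2]; s <- grid$stride
  boxes <- cbind(ax - dist[, 1] * s, ay - dist[, 2] * s,
                 ax + dist[, 3] * s, ay + dist[, 4] * s)
  list(boxes = boxes, dist = dist, aux = aux)
}

#' Greedy non-maximum suppression
#'
#' @param boxes n x 4 matrix.
#' @param scores Length-n scores.
#' @param iou_thr Suppression IoU threshold.
#' @return Indices of surviving boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thr = 0.65) {
  ord <- order(scores, decreasing = TRUE)
  keep <- integer()
  while (length(ord) > 0L) {
    i <- ord[1]
    keep <- c(keep, i)
    ord <- ord[-1]
    if (length(ord) == 0L) break
    ious <- iou_mat(boxes[i, , drop = FALSE], boxes[ord, , drop = FALSE])[1, ]
    ord <- ord[ious <= iou_thr]
  }
  keep
}

#' Decode head outputs and run non-maximum suppression
#'
#' @param outputs Per-level head outputs (as returned by the model forward).
#' @param cfg The [model_config] used to build the model.
#' @param conf_thr Confidence threshold.
#' @param iou_thr NMS IoU threshold.
#' @param input_size Image size for clipping.
#' @return Detection set: list with `boxes`, `scores`, `class_ids`, sorted by
#'   descending score.
#' @export
decode_and_nms <- function(outputs, cfg, conf_thr = 0.25, iou_thr = 0.65,
                           input_size = cfg$input_size) {
  grid <- anchor_grid(input_size)
  flat <- flatten_head_outputs(outputs)
  scores <- 1 / (1 + exp(-flat$cls))
  best_cls <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(nrow(scores)), best_cls)]
  dec <- decode_boxes(flat$reg, grid, cfg$head$use_dfl, cfg$head$reg_max)
  sel <- which(best_score >= conf_thr)
  if (length(sel) == 0L)
    return(list(boxes = matrix(numeric(), 0, 4), scores = numeric(),
                class_ids = integer()))
  boxes <- dec$boxes[sel, , drop = FALSE]
  boxes[, c(1, 3)] <- pmin(pmax(boxes[, c(1, 3)], 0), input_size)
  boxes[, c(2, 4)] <- pmin(pmax(boxes[, c(2, 4)], 0), input_size)
  sc <- best_score[sel]
  keep <- nms(boxes, sc, iou_thr)
  list(boxes = boxes[keep, , drop = FALSE], scores = sc[keep],
       class_ids = best_cls[sel][keep] - 1L)
}

#' Task-aligned target assignment
#'
#' For every ground truth, anchor points inside the box are candidates; the
#' top-k by the alignment metric `score^0.5 * IoU^6` become positives, and an
#' anchor claimed by several ground truths goes to the one with the larger
#' alignment. The repulsion ground truth of a positive is the non-assigned
#' ground truth with maximal IoU with the *prediction* (or none).
#'
#' @param gts m x 4 ground-truth boxes.
#' @param grid An [anchor_grid].
#' @param pred_boxes n x 4 decoded predictions (one per anchor).
#' @param scores Length-n classification scores in `[0, 1]`.
#' @param topk Candidates per ground truth (default 10).
#' @param alpha,beta Alignment exponents.
#' @return List: `pos_idx` (anchor rows), `table` ([assignment_table]),
#'   `quality` (IoU of each positive's prediction with its ground truth).
#' @export
assign_targets <- function(gts, grid, pred_boxes, scores, topk = 10L,
                           alpha = 0.5, beta = 6) {
  gts <- as_box_matrix(gts)
  n <- nrow(grid$points)
  if (nrow(gts) == 0L)
    return(list(pos_idx = integer(), table = assignment_table(integer()),
                quality = numeric()))
  eps <- 1e-9
  m <- nrow(gts)
  align <- matrix(0, n, m)
  im <- iou_mat(pred_boxes, gts)
  for (g in seq_len(m)) {
    gt <- gts[g, ]
    cand <- which(grid$points[, 1] > gt[1] & grid$points[, 1] < gt[3] &
                    grid$points[, 2] > gt[2] & grid$points[, 2] < gt[4])
    if (length(cand) == 0L) next
    al <- (scores[cand] + eps)^alpha * (im[cand, g] + eps)^beta
    keep <- cand[order(al, decreasing = TRUE)][seq_len(min(topk, length(cand)))]
    align[keep, g] <- al[match(keep, cand)]
  }
  pos <- which(rowSums(align > 0) > 0)
  if (length(pos) == 0L)
    return(list(pos_idx = integer(), table = assignment_table(integer()),
                quality = numeric()))
  attr_idx <- max.col(align[pos, , drop = FALSE], ties.method = "first")
  rep_idx <- rep(NA_integer_, length(pos))
  if (m > 1L) {
    imp <- im[pos, , drop = FALSE]
    imp[cbind(seq_along(pos), attr_idx)] <- -Inf
    best <- max.col(imp, ties.method = "first")
    hit <- imp[cbind(seq_along(pos), best)] > 0
    rep_idx[hit] <- best[hit]
  }
  quality <- im[cbind(pos, attr_idx)]
  list(pos_idx = pos,
       table = assignment_table(attr_idx, rep_idx, group = attr_idx),
       quality = quality)
}

# -- loss glue ----------------------------------------------------------------

# Compute the full training loss for one image and the gradients w.r.t. the
# flattened head outputs; returns per-level gradient arrays ready for the
# model backward pass.
detection_loss <- function(outputs, gts, cfg, w = loss_weights(),
                           gains = list(box = 7.5, cls = 0.5, dfl = 1.5),
                           grid = NULL) {
  if (is.null(grid)) grid <- anchor_grid(cfg$input_size)
  flat <- flatten_head_outputs(outputs)
  n <- nrow(flat$cls)
  scores <- 1 / (1 + exp(-flat$cls[, 1]))
  dec <- decode_boxes(flat$reg, grid, cfg$head$use_dfl, cfg$head$reg_max)
  gts <- as_box_matrix(gts)
  asg <- assign_targets(gts, grid, dec$boxes, scores)
  npos <- length(asg$pos_idx)

  cls_target <- numeric(n)
  dcls <- matrix(0, n, 1)
  dreg <- matrix(0, n, ncol(flat$reg))
  comps <- list(ciou = 0, repgt = 0, repbox = 0, cls = 0, dfl = 0)

  if (npos > 0L) {
    pos <- asg$pos_idx
    preds <- dec$boxes[pos, , drop = FALSE]
    occl <- occlusion_loss(preds, gts, asg$table, w, gradient = TRUE)
    comps$ciou <- occl$components$ciou
    comps$repgt <- occl$components$repgt
    comps$repbox <- occl$components$repbox
    dbox <- gains$box * occl$grad
    # chain to the distance parameterization: x1 = ax - l*s, etc.
    s <- grid$stride[pos]
    ddist <- cbind(-dbox[, 1] * s, -dbox[, 2] * s, dbox[, 3] * s, dbox[, 4] * s)

    if (cfg$head$use_dfl) {
      nb <- cfg$head$reg_max + 1L
      bins <- 0:cfg$head$reg_max
      # DFL cross-entropy toward the true (fractional) distances
      ax <- grid$points[pos, 1]; ay <- grid$points[pos, 2]
      gt_assigned <- gts[asg$table$attr_idx, , drop = FALSE]
      tgt <- cbind((ax - gt_assigned[, 1]) / s, (ay - gt_assigned[, 2]) / s,
                   (gt_assigned[, 3] - ax) / s, (gt_assigned[, 4] - ay) / s)
      tgt <- pmin(pmax(tgt, 0), cfg$head$reg_max - 0.01)
      dfl_total <- 0
      for (sd in 1:4) {
        p <- dec$aux$probs[[sd]][pos, , drop = FALSE]
        e <- dec$dist[pos, sd]
        # gradient of the expectation term
        dz_exp <- ddist[, sd] * p * (matrix(bins, npos, nb, byrow = TRUE) - e)
        # two-hot CE target
        lo <- floor(tgt[, sd]); hi <- lo + 1
        wl <- hi - tgt[, sd]; wh <- 1 - wl
        tmat <- matrix(0, npos, nb)
        tmat[cbind(seq_len(npos), lo + 1L)] <- wl
        tmat[cbind(seq_len(npos), pmin(hi, cfg$head$reg_max) + 1L)] <-
          tmat[cbind(seq_len(npos), pmin(hi, cfg$head$reg_max) + 1L)] + wh
        dfl_total <- dfl_total - sum(tmat * log(pmax(p, 1e-12))) / npos / 4
        dz_ce <- gains$dfl * (p - tmat) / npos / 4
        dreg[pos, (sd - 1L) * nb + seq_len(nb)] <-
          dreg[pos, (sd - 1L) * nb + seq_len(nb)] + dz_exp + dz_ce
      }
      comps$dfl <- dfl_total
    } else {
      dreg[pos, ] <- ddist * dec$aux$sig[pos, , drop = FALSE]
    }
    cls_target[pos] <- pmin(pmax(asg$quality, 0), 1)
  }

  # classification: stable BCE on logits, sum normalized by positives
  logit <- flat$cls[, 1]
  bce <- pmax(logit, 0) - logit * cls_target + log1p(exp(-abs(logit)))
  norm <- max(1, npos)
  comps$cls <- sum(bce) / norm
  dcls[, 1] <- gains$cls * (scores - cls_target) / norm

  total <- gains$box * (comps$ciou + w$alpha * comps$repgt + w$beta * comps$repbox) +
    gains$cls * comps$cls + gains$dfl * comps$dfl

  # unflatten gradients to per-level arrays
  dout <- vector("list", length(outputs))
  for (li in seq_along(outputs)) {
    d <- fm_dims(outputs[[li]]$cls)
    rows <- grid$level_offset[li] + seq_len(d[1] * d[2])
    dout[[li]] <- list(
      cls = array(dcls[rows, , drop = FALSE], dim = d),
      reg = array(dreg[rows, , drop = FALSE],
                  dim = c(d[1], d[2], ncol(dreg))))
  }
  list(total = total, components = comps, dout = dout, n_pos = npos,
       gains = gains)
}

# -- training -----------------------------------------------------------------

#' Train a detector on an in-memory dataset
#'
#' Full forward/backward training with AdamW, linear warm-up and the
#' occlusion loss. Deterministic given `seed`.
#'
#' @param dataset List of scenes: each `list(image = (H,W,3) array in [0,1],
#'   ann = annotated_image)`.
#' @param model A built model (see [build_model]); modified in place.
#' @param iters Number of optimizer steps.
#' @param batch Images per step (cycled deterministically).
#' @param lr,weight_decay AdamW settings.
#' @param warmup_iters Linear warm-up length.
#' @param lrf Final learning-rate fraction; the rate decays linearly from
#'   `lr` after warm-up to `lr * lrf` at the last iteration (the standard
#'   YOLO schedule).
#' @param w [loss_weights] for the occlusion loss.
#' @param gains Term gains (box/cls/dfl).
#' @param seed RNG seed for shuffling.
#' @param verbose Print a line every `verbose` steps (0 = silent).
#' @return Data frame log with one row per step (loss components and total).
#' @export
train_loop <- function(dataset, model, iters = 100L, batch = 8L,
                       lr = 2e-3, weight_decay = 5e-4, warmup_iters = 30L,
                       lrf = 0.01,
                       w = loss_weights(), gains = list(box = 7.5, cls = 0.5, dfl = 1.5),
                       seed = 0L, verbose = 0L) {
  cfg <- model$cfg
  grid <- anchor_grid(cfg$input_size)
  opt <- new_adamw(model, lr = lr, weight_decay = weight_decay)
  log <- vector("list", iters)
  with_seed(seed, {
    order_idx <- rep(sample(length(dataset)), length.out = iters * batch)
    ptr <- 0L
    for (it in seq_len(iters)) {
      zero_grads(model)
      tot <- 0; cmp <- c(ciou = 0, repgt = 0, repbox = 0, cls = 0, dfl = 0)
      for (b in seq_len(batch)) {
        ptr <- ptr + 1L
        sc <- dataset[[order_idx[ptr]]]
        out <- model$forward(sc$image)
        lg <- detection_loss(out, sc$ann$boxes, cfg, w = w, gains = gains,
                             grid = grid)
        if (!is.finite(lg$total))
          stop(sprintf("non-finite loss at iteration %d; aborting", it))
        sc1 <- function(a) lapply(a, function(p) list(cls = p$cls / batch,
                                                     reg = p$reg / batch))
        model$backward(sc1(lg$dout))
        tot <- tot + lg$total / batch
        cmp <- cmp + unlist(lg$components) / batch
      }
      lr_t <- if (it <= warmup_iters) lr * it / warmup_iters
              else lr * (1 - (1 - lrf) * (it - warmup_iters) /
                           max(1, iters - warmup_iters))
      adamw_step(opt, lr_t)
      log[[it]] <- data.frame(iter = it, lr = lr_t, total = tot,
                              ciou = cmp["ciou"], repgt = cmp["repgt"],
                              repbox = cmp["repbox"], cls = cmp["cls"],
                              dfl = cmp["dfl"], row.names = NULL)
      if (verbose > 0L && it %% verbose == 0L)
        message(sprintf("iter %4d  loss %.4f (ciou %.3f cls %.3f)",
                        it, tot, cmp["ciou"], cmp["cls"]))
    }
  })
  do.call(rbind, log)
}

#' Run inference on one image
#'
#' @param model A built model.
#' @param image `(H, W, 3)` array in `[0, 1]`.
#' @param conf_thr,iou_thr Decoding thresholds.
#' @return Detection set (see [decode_and_nms]).
#' @export
predict_image <- function(model, image, conf_thr = 0.25, iou_thr = 0.65) {
  out <- model$forward(image)
  clear_caches(model)
  decode_and_nms(out, model$cfg, conf_thr, iou_thr)
}

#' Save / load model weights
#'
#' Weights are serialized together with the builder configuration so a
#' checkpoint restores to an identical model.
#'
#' @param model A built model.
#' @param path File path.
#' @return `load_weights` returns the rebuilt model.
#' @export
save_weights <- function(model, path) {
  ps <- module_params(model)
  saveRDS(list(cfg = model$cfg, weights = lapply(ps, function(p) p$env[[p$w]])),
          path)
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  snap <- readRDS(path)
  model <- build_model(snap$cfg)
  ps <- module_params(model)
  if (length(ps) != length(snap$weights)) stop("checkpoint/model mismatch")
  for (i in seq_along(ps)) ps[[i]]$env[[ps[[i]]$w]] <- snap$weights[[i]]
  model
}
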
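# Lightweight Shared Head: per-level 1x1 reductions to a common middle
# channel, two 3x3 group-normalized convolution blocks and the prediction
# branches shared across the stride-8/16/32 levels, plus a per-level
# learnable scalar on the regression output (compensates for scale sharing).

#' Head configuration
#'
#' @param middle_channel Shared middle channel width (64/128/256 supported;
#'   default 128). Small custom widths are allowed for toy models as long as
#'   they are divisible by the normalization group count.
#' @param num_levels Number of pyramid levels (3).
#' @param reg_max Number of distribution bins minus one for DFL regression.
#' @param use_dfl Use distribution focal regression (default TRUE); when
#'   FALSE the regression branch emits 4 direct distances.
#' @param num_classes Classes (1 in single-class mode).
#' @param gn_groups Group-norm group count in the shared blocks (default 16).
#' @return Object of class `head_config`.
#' @export
head_config <- function(middle_channel = 128L, num_levels = 3L, reg_max = 16L,
                        use_dfl = TRUE, num_classes = 1L, gn_groups = 16L) {
  if (middle_channel %% gn_groups != 0L)
    stop("middle_channel must be divisible by the group-norm group count")
  structure(list(middle_channel = as.integer(middle_channel),
                 num_levels = as.integer(num_levels),
                 reg_max = as.integer(reg_max),
                 use_dfl = isTRUE(use_dfl),
                 num_classes = as.integer(num_classes),
                 gn_groups = as.integer(gn_groups)),
            class = "head_config")
}

reg_channels <- function(cfg) if (cfg$use_dfl) 4L * (cfg$reg_max + 1L) else 4L

#' Group-normalized convolution block
#'
#' 3x3 convolution, group normalization (16 groups by default) and SiLU;
#' shape preserving. Errors when the channel count is not divisible by the
#' group count. Output is independent of any other sample (the property that
#' motivates group over batch normalization).
#'
#' @param cin,channels Input/output channels.
#' @param groups Normalization groups (default 16).
#' @return An `sdd_module`.
#' @export
new_gnconv <- function(cin, channels, groups = 16L) {
  if (channels %% groups != 0L)
    stop(sprintf("gnconv: %d channels not divisible by %d groups", channels, groups))
  m <- new_module("gnconv")
  m$conv <- new_conv2d(cin, channels, 3L, bias = FALSE)
  m$gn <- new_group_norm(channels, groups)
  m$act <- new_silu()
  m$children <- list(m$conv, m$gn, m$act)
  m$forward <- function(x) m$act$forward(m$gn$forward(m$conv$forward(x)))
  m$backward <- function(dy) m$conv$backward(m$gn$backward(m$act$backward(dy)))
  m
}

#' Apply a group-normalized convolution to a feature map
#'
#' @param x `(H, W, C)` array.
#' @param channels Output channels.
#' @param groups Normalization groups.
#' @param module Optional existing [new_gnconv] module.
#' @return Feature map with `channels` channels, same spatial size.
#' @export
gnconv <- function(x, channels, groups = 16L, module = NULL) {
  d <- fm_dims(x)
  if (is.null(module)) module <- new_gnconv(d[3], channels, groups)
  y <- module$forward(x)
  clear_caches(module)
  y
}

#' Lightweight shared detection head
#'
#' @param in_channels Integer vector of per-level input channels (P3, P4, P5).
#' @param cfg A [head_config].
#' @return An `sdd_module`; forward takes the three level maps and returns a
#'   list of per-level `list(cls, reg)` outputs.
#' @export
new_ls_head <- function(in_channels, cfg = head_config()) {
  stopifnot(length(in_channels) == cfg$num_levels)
  m <- new_module("ls_head")
  mid <- cfg$middle_channel
  m$cfg <- cfg
  m$reduce <- lapply(in_channels, function(ci)
    new_conv_block(ci, mid, k = 1L, groups = gn_groups_for(mid, cfg$gn_groups)))
  m$shared1 <- new_gnconv(mid, mid, groups = gn_groups_for(mid, cfg$gn_groups))
  m$shared2 <- new_gnconv(mid, mid, groups = gn_groups_for(mid, cfg$gn_groups))
  m$cls_conv <- new_conv2d(mid, cfg$num_classes, 1L, bias = TRUE)
  m$reg_conv <- new_conv2d(mid, reg_channels(cfg), 1L, bias = TRUE)
  # detection prior: rare-positive initialisation keeps early training stable
  m$cls_conv$b[] <- -log((1 - 0.01) / 0.01)
  m$scales <- rep(1, cfg$num_levels)
  m$param_names <- "scales"
  m$children <- c(m$reduce, list(m$shared1, m$shared2, m$cls_conv, m$reg_conv))
  zero_grads(m)
  m$forward <- function(levels) {
    stopifnot(length(levels) == m$cfg$num_levels)
    raws <- vector("list", length(levels))
    out <- vector("list", length(levels))
    for (l in seq_along(levels)) {
      f <- m$shared2$forward(m$shared1$forward(m$reduce[[l]]$forward(levels[[l]])))
      cls <- m$cls_conv$forward(f)
      raw <- m$reg_conv$forward(f)
      raws[[l]] <- raw
      out[[l]] <- list(cls = cls, reg = raw * m$scales[l])
    }
    cache_push(m, list(raws = raws))
    out
  }
  m$backward <- function(dout) {
    cc <- cache_pop(m)
    dlevels <- vector("list", length(dout))
    for (l in rev(seq_along(dout))) {
      draw <- dout[[l]]$reg * m$scales[l]
      m$gscales[l] <- m$gscales[l] + sum(dout[[l]]$reg * cc$raws[[l]])
      df <- m$reg_conv$backward(draw) + m$cls_conv$backward(dout[[l]]$cls)
      dlevels[[l]] <- m$reduce[[l]]$backward(
        m$shared1$backward(m$shared2$backward(df)))
    }
    dlevels
  }
  m
}

#' Decoupled (non-shared) detection head
#'
#' Baseline-style head with level-specific classification and regression
#' towers; used for ablations and parameter comparisons.
#'
#' @inheritParams new_ls_head
#' @return An `sdd_module` with the same forward contract as [new_ls_head].
#' @export
new_decoupled_head <- function(in_channels, cfg = head_config()) {
  m <- new_module("decoupled_head")
  m$cfg <- cfg
  c2 <- max(16L, in_channels[1] %/% 4L, reg_channels(cfg))
  c3 <- max(in_channels[1], min(cfg$num_classes, 100L))
  m$reg_tower <- lapply(in_channels, function(ci) {
    t <- new_module("tower")
    t$b1 <- new_conv_block(ci, c2, 3L); t$b2 <- new_conv_block(c2, c2, 3L)
    t$out <- new_conv2d(c2, reg_channels(cfg), 1L, bias = TRUE)
    t$children <- list(t$b1, t$b2, t$out)
    t$forward <- function(x) t$out$forward(t$b2$forward(t$b1$forward(x)))
    t$backward <- function(dy) t$b1$backward(t$b2$backward(t$out$backward(dy)))
    t
  })
  m$cls_tower <- lapply(in_channels, function(ci) {
    t <- new_module("tower")
    t$b1 <- new_conv_block(ci, c3, 3L); t$b2 <- new_conv_block(c3, c3, 3L)
    t$out <- new_conv2d(c3, cfg$num_classes, 1L, bias = TRUE)
    t$out$b[] <- -log((1 - 0.01) / 0.01)
    t$children <- list(t$b1, t$b2, t$out)
    t$forward <- function(x) t$out$forward(t$b2$forward(t$b1$forward(x)))
    t$backward <- function(dy) t$b1$backward(t$b2$backward(t$out$backward(dy)))
    t
  })
  m$children <- c(m$reg_tower, m$cls_tower)
  m$forward <- function(levels) {
    lapply(seq_along(levels), function(l)
      list(cls = m$cls_tower[[l]]$forward(levels[[l]]),
           reg = m$reg_tower[[l]]$forward(levels[[l]])))
  }
  m$backward <- function(dout) {
    dlevels <- vector("list", length(dout))
    for (l in rev(seq_along(dout)))
      dlevels[[l]] <- m$cls_tower[[l]]$backward(dout[[l]]$cls) +
        m$reg_tower[[l]]$backward(dout[[l]]$reg)
    dlevels
  }
  m
}

#' Run the lightweight shared head on three pyramid levels
#'
#' @param p3,p4,p5 Feature maps at strides 8/16/32.
#' @param cfg A [head_config].
#' @param module Optional existing head module.
#' @return List of per-level `list(cls, reg)` maps.
#' @export
ls_head_forward <- function(p3, p4, p5, cfg = head_config(), module = NULL) {
  chans <- c(fm_dims(p3)[3], fm_dims(p4)[3], fm_dims(p5)[3])
  if (is.null(module)) module <- new_ls_head(chans, cfg)
  y <- module$forward(list(p3, p4, p5))
  clear_caches(module)
  y
}

#' Closed-form parameter count of the shared head
#'
#' Per-level 1x1 reductions (conv + group-norm affine), two shared 3x3
#' group-normalized blocks, shared 1x1 prediction branches with bias, and the
#' per-level regression scales.
#'
#' @param cfg A [head_config].
#' @param in_channels Per-level input channel counts.
#' @return Integer parameter count.
#' @export
count_head_params <- function(cfg, in_channels) {
  mid <- cfg$middle_channel
  rc <- reg_channels(cfg)
  reducers <- sum(vapply(in_channels, function(ci) ci * mid + 2L * mid, 0))
  shared <- 2L * (9L * mid * mid + 2L * mid)
  cls <- mid * cfg$num_classes + cfg$num_classes
  reg <- mid * rc + rc
  reducers + shared + cls + reg + cfg$num_levels
}
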
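# Orthonormal 2-D Haar analysis/synthesis and the wavelet-enhanced
# convolution blocks built on top of them.
#
# Filters use the +/- 1/2 orthonormal scaling, so analysis is an isometry
# (Parseval holds exactly) and the synthesis operator is both the inverse and
# the adjoint of analysis - which is what makes backpropagation through the
# transform a one-liner.

#' Single-level 2-D Haar analysis
#'
#' Decomposes a feature map into the four half-resolution subbands: `ll`
#' (approximation), `lh` (horizontal detail), `hl` (vertical detail) and `hh`
#' (diagonal detail). Odd spatial sizes are reflection-padded by one row or
#' column first.
#'
#' @param x `(H, W, C)` array.
#' @return Object of class `wavelet_bands`: list with `ll`, `lh`, `hl`, `hh`,
#'   each `(ceil(H/2), ceil(W/2), C)`, plus the original spatial size.
#' @export
haar_dwt2 <- function(x) {
  d <- fm_dims(x)
  orig <- d[1:2]
  if (d[1] %% 2L == 1L) x <- x[c(seq_len(d[1]), d[1]), , , drop = FALSE]
  if (d[2] %% 2L == 1L) x <- x[, c(seq_len(d[2]), d[2]), , drop = FALSE]
  d <- dim(x)
  i1 <- seq(1L, d[1], 2L); j1 <- seq(1L, d[2], 2L)
  a <- x[i1, j1, , drop = FALSE]       # x[2r-1, 2c-1]
  b <- x[i1, j1 + 1L, , drop = FALSE]  # x[2r-1, 2c]
  cc <- x[i1 + 1L, j1, , drop = FALSE] # x[2r,   2c-1]
  dd <- x[i1 + 1L, j1 + 1L, , drop = FALSE]
  structure(list(ll = (a + b + cc + dd) / 2,
                 lh = (a - b + cc - dd) / 2,
                 hl = (a + b - cc - dd) / 2,
                 hh = (a - b - cc + dd) / 2,
                 orig_size = orig),
            class = "wavelet_bands")
}

haar_synth_full <- function(bands) {
  dims <- lapply(bands[c("ll", "lh", "hl", "hh")], fm_dims)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("wavelet bands have inconsistent shapes")
  d <- dims[[1]]
  ll <- bands$ll; lh <- bands$lh; hl <- bands$hl; hh <- bands$hh
  x <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
  x[i1, j1, ] <- (ll + lh + hl + hh) / 2
  x[i1, j1 + 1L, ] <- (ll - lh + hl - hh) / 2
  x[i1 + 1L, j1, ] <- (ll + lh - hl - hh) / 2
  x[i1 + 1L, j1 + 1L, ] <- (ll - lh - hl + hh) / 2
  x
}

#' Single-level 2-D Haar synthesis
#'
#' Exact left inverse of [haar_dwt2]; reflection padding applied during
#' analysis is cropped away.
#'
#' @param bands A `wavelet_bands` object.
#' @return `(H, W, C)` array.
#' @export
haar_iwt2 <- function(bands) {
  stopifnot(inherits(bands, "wavelet_bands"))
  x <- haar_synth_full(bands)
  os <- bands$orig_size
  if (!is.null(os)) x <- x[seq_len(os[1]), seq_len(os[2]), , drop = FALSE]
  x
}

# Adjoint of the analysis operator (synthesis, with reflect-padding gradients
# folded back onto the edge row/column when the input size was odd).
dwt_adjoint <- function(dbands) {
  y <- haar_synth_full(dbands)
  os <- dbands$orig_size
  d <- dim(y)
  if (d[1] > os[1]) y[os[1], , ] <- y[os[1], , ] + y[os[1] + 1L, , ]
  if (d[2] > os[2]) y[, os[2], ] <- y[, os[2], ] + y[, os[2] + 1L, ]
  y[seq_len(os[1]), seq_len(os[2]), , drop = FALSE]
}

# Adjoint of the synthesis operator: zero-pad the (possibly cropped) output
# gradient back to the even extent, then analyse.
iwt_adjoint <- function(dx) {
  d <- fm_dims(dx)
  He <- d[1] + d[1] %% 2L; We <- d[2] + d[2] %% 2L
  if (He != d[1] || We != d[2]) {
    z <- array(0, dim = c(He, We, d[3]))
    z[seq_len(d[1]), seq_len(d[2]), ] <- dx
    dx <- z
  }
  b <- haar_dwt2(dx)
  b$orig_size <- d[1:2]
  b
}

#' Wavelet-domain depthwise convolution module
#'
#' Recursively decomposes the approximation band `levels` times, applies a
#' learned depthwise kernel to every subband at every level, reconstructs,
#' and adds a spatial-domain depthwise path on the input. Band kernels start
#' at identity (plus small noise unless `noise = 0`), the spatial path at
#' zero, so a fresh module is near pass-through.
#'
#' @param C Channel count.
#' @param levels Decomposition depth (>= 1).
#' @param kernel Depthwise kernel size (odd).
#' @param noise Init noise sd on the band kernels.
#' @return An `sdd_module`.
#' @export
new_wtconv <- function(C, levels = 1L, kernel = 5L, noise = 0.01) {
  if (levels < 1L) stop("wtconv needs levels >= 1")
  m <- new_module("wtconv")
  m$C <- C; m$levels <- as.integer(levels); m$kernel <- as.integer(kernel)
  m$band_convs <- vector("list", levels)
  for (l in seq_len(levels)) {
    m$band_convs[[l]] <- lapply(c("ll", "lh", "hl", "hh"), function(nm) {
      dc <- new_dwconv(C, kernel)
      dw_set_identity(dc)
      if (noise > 0) dc$W <- dc$W + matrix(stats::rnorm(length(dc$W), sd = noise),
                                           nrow(dc$W))
      dc
    })
    names(m$band_convs[[l]]) <- c("ll", "lh", "hl", "hh")
  }
  m$spatial <- new_dwconv(C, kernel)
  m$spatial$W[] <- if (noise > 0) stats::rnorm(length(m$spatial$W), sd = noise) else 0
  m$children <- c(unlist(m$band_convs, recursive = FALSE, use.names = FALSE),
                  list(m$spatial))
  m$forward <- function(x) {
    d <- fm_dims(x)
    if (min(d[1], d[2]) < 2^m$levels)
      stop("spatial size too small for requested wavelet levels")
    rec <- function(inp, level) {
      bands <- haar_dwt2(inp)
      conv <- m$band_convs[[level]]
      out <- list(ll = conv$ll$forward(bands$ll),
                  lh = conv$lh$forward(bands$lh),
                  hl = conv$hl$forward(bands$hl),
                  hh = conv$hh$forward(bands$hh),
                  orig_size = bands$orig_size)
      if (level < m$levels) out$ll <- out$ll + rec(bands$ll, level + 1L)
      class(out) <- "wavelet_bands"
      haar_iwt2(out)
    }
    y <- rec(x, 1L) + m$spatial$forward(x)
    cache_push(m, list())
    y
  }
  m$backward <- function(dy) {
    cache_pop(m)
    dx_spatial <- m$spatial$backward(dy)
    rec_bw <- function(dout, level) {
      db <- iwt_adjoint(dout)
      conv <- m$band_convs[[level]]
      dll_extra <- if (level < m$levels) rec_bw(db$ll, level + 1L) else 0
      dbands <- list(ll = conv$ll$backward(db$ll),
                     lh = conv$lh$backward(db$lh),
                     hl = conv$hl$backward(db$hl),
                     hh = conv$hh$backward(db$hh),
                     orig_size = db$orig_size)
      # dll_extra flows into the *input* ll of the deeper level, which is the
      # same tensor that fed this level's ll conv
      dbands$ll <- dbands$ll + dll_extra
      class(dbands) <- "wavelet_bands"
      dwt_adjoint(dbands)
    }
    rec_bw(dy, 1L) + dx_spatial
  }
  m
}

#' Apply a wavelet-domain convolution to a feature map
#'
#' Functional convenience wrapper around [new_wtconv]; supply `module` to
#' reuse trained weights.
#'
#' @param x `(H, W, C)` array.
#' @param levels,kernel See [new_wtconv].
#' @param module Optional existing wtconv module.
#' @return Feature map of the same shape as `x`.
#' @export
wtconv <- function(x, levels = 1L, kernel = 5L, module = NULL) {
  d <- fm_dims(x)
  if (is.null(module)) module <- new_wtconv(d[3], levels, kernel)
  y <- module$forward(x)
  clear_caches(module)  # functional use: discard backward caches
  y
}

#' Wavelet-enhanced downsampling block
#'
#' A stride-2 pointwise (1x1) convolution halves the resolution and sets the
#' channel count; the result is enriched by a wavelet-domain depthwise path
#' (added element-wise) and passed through group norm + SiLU.
#'
#' @param cin,cout Input/output channels.
#' @param levels,kernel Wavelet path settings.
#' @return An `sdd_module` mapping `(H, W, cin)` to `(H/2, W/2, cout)`.
#' @export
new_weconv <- function(cin, cout, levels = 1L, kernel = 5L) {
  m <- new_module("weconv")
  m$pw <- new_conv2d(cin, cout, k = 1L, stride = 2L, pad = 0L, bias = FALSE)
  m$wt <- new_wtconv(cout, levels, kernel)
  m$gn <- new_group_norm(cout)
  m$act <- new_silu()
  m$children <- list(m$pw, m$wt, m$gn, m$act)
  m$forward <- function(x) {
    y0 <- m$pw$forward(x)
    m$act$forward(m$gn$forward(y0 + m$wt$forward(y0)))
  }
  m$backward <- function(dy) {
    dfused <- m$gn$backward(m$act$backward(dy))
    dy0 <- dfused + m$wt$backward(dfused)
    m$pw$backward(dy0)
  }
  m
}

#' Run a wavelet-enhanced downsampling block on a feature map
#'
#' @param x `(H, W, C)` array.
#' @param c_out Output channel count.
#' @param module Optional existing [new_weconv] module.
#' @return Feature map of shape `(H/2, W/2, c_out)`.
#' @export
weconv_block <- function(x, c_out, module = NULL) {
  d <- fm_dims(x)
  if (is.null(module)) module <- new_weconv(d[3], c_out)
  module$forward(x)
}

#' Parameter count of a wavelet-enhanced block, in closed form
#'
#' Pointwise weights (`cin * cout`, no bias) + depthwise band kernels
#' (`4 * levels * k^2 * cout`) + spatial depthwise path (`k^2 * cout`) +
#' group-norm affine (`2 * cout`).
#'
#' @param cin,cout,levels,kernel Block hyperparameters.
#' @return Integer parameter count.
#' @export
count_weconv_params <- function(cin, cout, levels = 1L, kernel = 5L) {
  cin * cout + 4L * levels * kernel^2 * cout + kernel^2 * cout + 2L * cout
}
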
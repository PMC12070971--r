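# Occlusion Perceptual Attention Module: fuses low-level (stride-4) detail
# features with high-level semantic features through position, channel and
# pixel attention. The pixel gate g in (0,1) blends the two streams per
# position: out = low * g + proj(high) * (1 - g).

#' Position attention module
#'
#' Channel-pooled (mean and max over channels) spatial descriptor, a
#' `gate_kernel` x `gate_kernel` convolution with replicate padding, and a
#' sigmoid gate multiplying the input. Shape preserving; spatially uniform
#' inputs stay spatially uniform.
#'
#' @param gate_kernel Odd spatial kernel size (default 7).
#' @return An `sdd_module`.
#' @export
new_position_attention <- function(gate_kernel = 7L) {
  m <- new_module("position_attention")
  m$conv <- new_conv2d(2L, 1L, gate_kernel, pad_mode = "replicate")
  m$sig <- new_sigmoid()
  m$children <- list(m$conv, m$sig)
  m$forward <- function(x) {
    d <- fm_dims(x)
    mu <- array(rowMeans(matrix(x, ncol = d[3])), dim = c(d[1], d[2], 1L))
    mx_idx <- max.col(matrix(x, ncol = d[3]), ties.method = "first")
    M <- matrix(x, ncol = d[3])
    mx <- array(M[cbind(seq_len(nrow(M)), mx_idx)], dim = c(d[1], d[2], 1L))
    pooled <- cat_channels(mu, mx)
    gate <- m$sig$forward(m$conv$forward(pooled))
    g3 <- array(gate, dim = d)  # broadcast the single gate channel
    cache_push(m, list(x = x, gate = gate, mx_idx = mx_idx, d = d))
    x * g3
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    d <- cc$d
    g3 <- array(cc$gate, dim = d)
    dx <- dy * g3
    dgate <- array(rowSums(matrix(dy * cc$x, ncol = d[3])), dim = c(d[1], d[2], 1L))
    dpooled <- m$conv$backward(m$sig$backward(dgate))
    dmu <- dpooled[, , 1L]; dmx <- dpooled[, , 2L]
    dx <- dx + array(rep(as.vector(dmu) / d[3], d[3]), dim = d)
    Mdx <- matrix(dx, ncol = d[3])
    idx <- cbind(seq_len(nrow(Mdx)), cc$mx_idx)
    Mdx[idx] <- Mdx[idx] + as.vector(dmx)
    array(Mdx, dim = d)
  }
  m
}

#' Channel attention module (squeeze-and-excitation)
#'
#' Global average pooling, a two-layer bottleneck (`reduction`-fold), sigmoid
#' gates in `[0, 1]`, one per channel, constant across space.
#'
#' @param C Channel count.
#' @param reduction Bottleneck reduction factor (default 16).
#' @return An `sdd_module`.
#' @export
new_channel_attention <- function(C, reduction = 16L) {
  m <- new_module("channel_attention")
  hid <- max(1L, C %/% reduction)
  m$C <- C
  m$W1 <- matrix(stats::rnorm(hid * C, sd = sqrt(2 / C)), hid, C)
  m$b1 <- numeric(hid)
  m$W2 <- matrix(stats::rnorm(C * hid, sd = sqrt(2 / hid)), C, hid)
  m$b2 <- numeric(C)
  m$param_names <- c("W1", "b1", "W2", "b2")
  m$forward <- function(x) {
    d <- fm_dims(x)
    pooled <- colMeans(matrix(x, ncol = d[3]))
    z1 <- as.vector(m$W1 %*% pooled + m$b1)
    s1 <- 1 / (1 + exp(-z1)); a1 <- z1 * s1                 # SiLU
    z2 <- as.vector(m$W2 %*% a1 + m$b2)
    gate <- 1 / (1 + exp(-z2))
    cache_push(m, list(x = x, d = d, pooled = pooled, z1 = z1, s1 = s1,
                       a1 = a1, gate = gate))
    sweep(x, 3, gate, `*`)
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    d <- cc$d
    dx <- sweep(dy, 3, cc$gate, `*`)
    dgate <- apply(dy * cc$x, 3, sum)
    dz2 <- dgate * cc$gate * (1 - cc$gate)
    m$gW2 <- m$gW2 + outer(dz2, cc$a1)
    m$gb2 <- m$gb2 + dz2
    da1 <- as.vector(crossprod(m$W2, dz2))
    dz1 <- da1 * (cc$s1 * (1 + cc$z1 * (1 - cc$s1)))
    m$gW1 <- m$gW1 + outer(dz1, cc$pooled)
    m$gb1 <- m$gb1 + dz1
    dpooled <- as.vector(crossprod(m$W1, dz1))
    dx + array(rep(dpooled / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  }
  m
}

#' Pixel attention module
#'
#' Two stacked 1x1 convolutions on the channel-concatenated pair of streams,
#' ending in a sigmoid, producing a per-channel (or scalar, with
#' `shared_gate`) blending weight strictly inside (0, 1).
#'
#' @param C Channel count of each input stream.
#' @param shared_gate If `TRUE`, emit a single gate channel shared by all
#'   channels; otherwise one gate per channel.
#' @return An `sdd_module`; forward takes the two streams `a` and `b`.
#' @export
new_pixel_attention <- function(C, shared_gate = FALSE) {
  m <- new_module("pixel_attention")
  hid <- max(1L, C %/% 2L)
  cout <- if (shared_gate) 1L else C
  m$C <- C; m$shared_gate <- shared_gate
  m$conv1 <- new_conv2d(2L * C, hid, 1L)
  m$act <- new_silu()
  m$conv2 <- new_conv2d(hid, cout, 1L)
  m$sig <- new_sigmoid()
  m$children <- list(m$conv1, m$act, m$conv2, m$sig)
  m$forward <- function(a, b) {
    da <- fm_dims(a); db <- fm_dims(b)
    if (!all(da == db)) stop("pixel attention inputs must share shape after resampling")
    g <- m$sig$forward(m$conv2$forward(m$act$forward(m$conv1$forward(cat_channels(a, b)))))
    cache_push(m, list(da = da))
    if (m$shared_gate) array(g, dim = da) else g
  }
  m$backward <- function(dgate) {
    cc <- cache_pop(m)
    dg <- if (m$shared_gate)
      array(rowSums(matrix(dgate, ncol = cc$da[3])), dim = c(cc$da[1], cc$da[2], 1L))
    else dgate
    dcat <- m$conv1$backward(m$act$backward(m$conv2$backward(m$sig$backward(dg))))
    split_channels_bw(dcat, cc$da[3])
  }
  m
}

#' Occlusion-perceptual attention fusion module
#'
#' The low-level stream (stride 4) is brought to the high-level stride by a
#' stride-2 convolution block; the high-level stream is projected by a bare
#' 1x1 convolution. Position attention refines the low stream, channel
#' attention the high stream, and the pixel gate blends them per position:
#' `out = low * g + proj(high) * (1 - g)`.
#'
#' @param c_low,c_high Input channel counts of the two streams.
#' @param c_out Output channel count.
#' @param reduction Channel-attention bottleneck factor.
#' @param shared_gate Scalar-per-pixel gate instead of per-channel.
#' @param gate_kernel Position-attention kernel size.
#' @return An `sdd_module`; forward takes `f_low`, `f_high` and an optional
#'   `gate_override` (0, 1, or NULL) used by the limit tests.
#' @export
new_opam <- function(c_low, c_high, c_out, reduction = 16L,
                     shared_gate = FALSE, gate_kernel = 7L) {
  m <- new_module("opam")
  m$down <- new_conv_block(c_low, c_out, k = 3L, stride = 2L)
  m$proj <- new_conv2d(c_high, c_out, k = 1L, bias = TRUE)
  m$pa <- new_position_attention(gate_kernel)
  m$ca <- new_channel_attention(c_out, reduction)
  m$px <- new_pixel_attention(c_out, shared_gate)
  m$children <- list(m$down, m$proj, m$pa, m$ca, m$px)
  m$forward <- function(f_low, f_high, gate_override = NULL) {
    low <- m$down$forward(f_low)
    high <- m$proj$forward(f_high)
    if (!all(fm_dims(low) == fm_dims(high)))
      stop("OPAM streams disagree in shape after resampling/projection")
    a <- low + m$pa$forward(low)
    b <- high + m$ca$forward(high)
    g <- m$px$forward(a, b)
    if (!is.null(gate_override)) g <- array(gate_override, dim = fm_dims(low))
    cache_push(m, list(low = low, high = high, g = g,
                       override = !is.null(gate_override)))
    low * g + high * (1 - g)
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    dlow <- dy * cc$g
    dhigh <- dy * (1 - cc$g)
    if (cc$override) {
      # gate was forced: no gradient through the attention paths, but their
      # caches must still unwind
      dg <- array(0, dim = fm_dims(cc$low))
    } else {
      dg <- dy * (cc$low - cc$high)
    }
    dab <- m$px$backward(dg)
    dca_in <- m$ca$backward(dab[[2]])
    dpa_in <- m$pa$backward(dab[[1]])
    dlow <- dlow + dab[[1]] + dpa_in
    dhigh <- dhigh + dab[[2]] + dca_in
    list(d_low = m$down$backward(dlow), d_high = m$proj$backward(dhigh))
  }
  m
}

#' Fuse low- and high-level features with occlusion-perceptual attention
#'
#' Functional wrapper around [new_opam]. The `gate_override` argument forces
#' the pixel gate to a constant (0 or 1), recovering the pure projected-high
#' or resampled-low stream exactly.
#'
#' @param f_low Low-level `(H, W, c_low)` map (stride 4 relative to image).
#' @param f_high High-level `(H/2, W/2, c_high)` map.
#' @param c_out Output channels; defaults to the high stream's channels.
#' @param module Optional existing module.
#' @param gate_override NULL, 0 or 1.
#' @return Fused `(H/2, W/2, c_out)` feature map.
#' @export
opam_fuse <- function(f_low, f_high, c_out = NULL, module = NULL,
                      gate_override = NULL) {
  dl <- fm_dims(f_low); dh <- fm_dims(f_high)
  if (is.null(c_out)) c_out <- dh[3]
  if (is.null(module)) module <- new_opam(dl[3], dh[3], c_out)
  y <- module$forward(f_low, f_high, gate_override = gate_override)
  clear_caches(module)
  y
}
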
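# Minimal CPU neural-network engine.
#
# Feature maps are dense (H, W, C) double arrays (native R image layout,
# column-major so each channel is a contiguous H*W block). Every layer is an
# environment ("sdd_module") exposing forward()/backward() closures; forward
# pushes whatever backward needs onto an internal cache stack, so a module may
# be invoked several times per pass (weight sharing) provided backward calls
# arrive in reverse order. Gradients accumulate into g<name> fields until
# zero_grads() is called.

.prof <- new.env(parent = emptyenv())
.prof$active <- FALSE
.prof$macs <- 0

prof_start <- function() { .prof$active <- TRUE; .prof$macs <- 0 }
prof_stop <- function() { .prof$active <- FALSE; .prof$macs }
prof_add <- function(macs) if (.prof$active) .prof$macs <- .prof$macs + macs

new_module <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$children <- list()
  e$param_names <- character()
  e$stack <- list()
  class(e) <- "sdd_module"
  e
}

cache_push <- function(m, cache) m$stack[[length(m$stack) + 1L]] <- cache

cache_pop <- function(m) {
  n <- length(m$stack)
  if (n == 0L) stop("backward called with empty cache stack in ", m$type)
  cache <- m$stack[[n]]
  m$stack[[n]] <- NULL
  cache
}

clear_caches <- function(m) {
  seen <- list()
  walk <- function(mod) {
    for (s in seen) if (identical(s, mod)) return(invisible())
    seen[[length(seen) + 1L]] <<- mod
    mod$stack <- list()
    for (ch in mod$children) walk(ch)
    invisible()
  }
  walk(m)
  invisible(m)
}

#' @keywords internal
fm_dims <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) != 3L) stop("feature map must be a rank-3 (H,W,C) array")
  d
}

# -- parameter bookkeeping ----------------------------------------------------

module_params <- function(m, decay_default = TRUE) {
  out <- list()
  seen <- list()
  walk <- function(mod) {
    for (s in seen) if (identical(s, mod)) return(invisible())
    seen[[length(seen) + 1L]] <<- mod
    for (nm in mod$param_names) {
      decay <- decay_default && !nm %in% c("b", "beta", "gamma", "scales")
      out[[length(out) + 1L]] <<- list(env = mod, w = nm, g = paste0("g", nm), decay = decay)
    }
    for (ch in mod$children) walk(ch)
    invisible()
  }
  walk(m)
  out
}

n_params <- function(m) sum(vapply(module_params(m), function(p) length(p$env[[p$w]]), 0))

zero_grads <- function(m) {
  for (p in module_params(m)) {
    w <- p$env[[p$w]]
    p$env[[p$g]] <- if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else w * 0
  }
  invisible(m)
}

param_checksum <- function(m) {
  s <- 0
  for (p in module_params(m)) s <- s + sum(p$env[[p$w]]^2)
  s
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# -- dense convolution --------------------------------------------------------

replicate_pad <- function(x, p) {
  d <- fm_dims(x)
  ri <- c(rep(1L, p), seq_len(d[1]), rep(d[1], p))
  ci <- c(rep(1L, p), seq_len(d[2]), rep(d[2], p))
  x[ri, ci, , drop = FALSE]
}

crop_pad_grad <- function(dx, p) {
  d <- fm_dims(dx)
  H <- d[1] - 2L * p; W <- d[2] - 2L * p
  core <- dx[(p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
  # replicate padding: border gradients fold back onto edge rows/cols
  core[1, , ] <- core[1, , ] + apply(dx[seq_len(p), (p + 1L):(p + W), , drop = FALSE], c(2, 3), sum)
  core[H, , ] <- core[H, , ] + apply(dx[(p + H + 1L):(p + H + p), (p + 1L):(p + W), , drop = FALSE], c(2, 3), sum)
  core[, 1, ] <- core[, 1, ] + apply(dx[(p + 1L):(p + H), seq_len(p), , drop = FALSE], c(1, 3), sum)
  core[, W, ] <- core[, W, ] + apply(dx[(p + 1L):(p + H), (p + W + 1L):(p + W + p), , drop = FALSE], c(1, 3), sum)
  corner <- function(rs, cs) apply(dx[rs, cs, , drop = FALSE], 3, sum)
  core[1, 1, ] <- core[1, 1, ] + corner(seq_len(p), seq_len(p))
  core[1, W, ] <- core[1, W, ] + corner(seq_len(p), (p + W + 1L):(p + W + p))
  core[H, 1, ] <- core[H, 1, ] + corner((p + H + 1L):(p + H + p), seq_len(p))
  core[H, W, ] <- core[H, W, ] + corner((p + H + 1L):(p + H + p), (p + W + 1L):(p + W + p))
  core
}

new_conv2d <- function(cin, cout, k, stride = 1L, pad = k %/% 2L, bias = TRUE,
                       pad_mode = c("zero", "replicate")) {
  m <- new_module("conv2d")
  m$cin <- cin; m$cout <- cout; m$k <- as.integer(k)
  m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$pad_mode <- match.arg(pad_mode)
  if (m$pad_mode == "replicate" && stride != 1L)
    stop("replicate padding implemented for stride 1 only")
  m$W <- matrix(stats::rnorm(cout * k * k * cin, sd = sqrt(2 / (k * k * cin))),
                nrow = cout)
  m$param_names <- "W"
  if (bias) { m$b <- numeric(cout); m$param_names <- c("W", "b") }
  m$forward <- function(x) {
    d <- fm_dims(x)
    if (d[3] != m$cin) stop(sprintf("conv2d expects %d channels, got %d", m$cin, d[3]))
    xin <- x; prep <- 0L
    if (m$pad_mode == "replicate" && m$pad > 0L) { xin <- replicate_pad(x, m$pad); prep <- m$pad }
    din <- dim(xin)
    cols <- cpp_im2col(as.double(xin), din[1], din[2], din[3], m$k, m$stride,
                       if (m$pad_mode == "zero") m$pad else 0L)
    y <- m$W %*% cols
    if (!is.null(m$b)) y <- y + m$b
    Ho <- (din[1] + 2 * (if (m$pad_mode == "zero") m$pad else 0L) - m$k) %/% m$stride + 1L
    Wo <- ncol(cols) %/% Ho
    prof_add(as.double(m$k)^2 * m$cin * m$cout * Ho * Wo)
    cache_push(m, list(cols = cols, din = din, prep = prep))
    array(t(y), dim = c(Ho, Wo, m$cout))
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    d <- fm_dims(dy)
    dym <- t(matrix(dy, ncol = m$cout))
    m$gW <- m$gW + dym %*% t(cc$cols)
    if (!is.null(m$b)) m$gb <- m$gb + rowSums(dym)
    dcols <- crossprod(m$W, dym)
    dx <- cpp_col2im(dcols, cc$din[1], cc$din[2], cc$din[3], m$k, m$stride,
                     if (m$pad_mode == "zero") m$pad else 0L)
    if (cc$prep > 0L) dx <- crop_pad_grad(dx, cc$prep)
    dx
  }
  zero_grads(m)
  m
}

new_dwconv <- function(C, k, stride = 1L, pad = k %/% 2L) {
  m <- new_module("dwconv")
  m$C <- C; m$k <- as.integer(k); m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$W <- matrix(stats::rnorm(k * k * C, sd = sqrt(2 / (k * k))), nrow = k * k)
  m$param_names <- "W"
  m$forward <- function(x) {
    d <- fm_dims(x)
    if (d[3] != m$C) stop("dwconv channel mismatch")
    y <- cpp_dwconv(as.double(x), d[1], d[2], d[3], m$W, m$k, m$stride, m$pad)
    prof_add(as.double(m$k)^2 * m$C * prod(dim(y)[1:2]))
    cache_push(m, list(x = x, din = d))
    y
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    r <- cpp_dwconv_bw(as.double(cc$x), cc$din[1], cc$din[2], cc$din[3],
                       m$W, m$k, m$stride, m$pad, as.double(dy))
    m$gW <- m$gW + r$dw
    r$dx
  }
  zero_grads(m)
  m
}

# Set a depthwise kernel to the identity (centre tap 1).
dw_set_identity <- function(m) {
  m$W[] <- 0
  m$W[(m$k %/% 2L) * m$k + m$k %/% 2L + 1L, ] <- 1
  invisible(m)
}

# -- normalization and activations -------------------------------------------

# Largest divisor of C not exceeding `want` (tiny widths need fewer groups).
gn_groups_for <- function(C, want = 16L) {
  for (g in seq(min(want, C), 1L)) if (C %% g == 0L) return(as.integer(g))
  1L
}

new_group_norm <- function(C, groups = gn_groups_for(C), eps = 1e-5) {
  if (C %% groups != 0L)
    stop(sprintf("channels (%d) not divisible by normalization groups (%d)", C, groups))
  m <- new_module("group_norm")
  m$C <- C; m$groups <- as.integer(groups); m$eps <- eps
  m$gamma <- rep(1, C); m$beta <- numeric(C)
  m$param_names <- c("gamma", "beta")
  m$forward <- function(x) {
    d <- fm_dims(x)
    cg <- m$C %/% m$groups
    X <- matrix(x, ncol = m$groups)          # (H*W*cg, groups)
    mu <- colMeans(X)
    xc <- sweep(X, 2, mu)
    v <- colMeans(xc * xc)
    istd <- 1 / sqrt(v + m$eps)
    xhat <- sweep(xc, 2, istd, `*`)
    xh <- array(xhat, dim = d)
    y <- sweep(xh, 3, m$gamma, `*`)
    y <- sweep(y, 3, m$beta, `+`)
    cache_push(m, list(xhat = xhat, istd = istd, d = d))
    y
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    d <- cc$d
    xh <- array(cc$xhat, dim = d)
    m$ggamma <- m$ggamma + apply(dy * xh, 3, sum)
    m$gbeta <- m$gbeta + apply(dy, 3, sum)
    dxhat <- sweep(dy, 3, m$gamma, `*`)
    Dx <- matrix(dxhat, ncol = m$groups)
    t1 <- colMeans(Dx)
    t2 <- colMeans(Dx * cc$xhat)
    dX <- sweep(sweep(Dx, 2, t1) - sweep(cc$xhat, 2, t2, `*`), 2, cc$istd, `*`)
    array(dX, dim = d)
  }
  zero_grads(m)
  m
}

new_silu <- function() {
  m <- new_module("silu")
  m$forward <- function(x) {
    s <- 1 / (1 + exp(-x))
    cache_push(m, list(x = x, s = s))
    x * s
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    dy * (cc$s * (1 + cc$x * (1 - cc$s)))
  }
  m
}

new_sigmoid <- function() {
  m <- new_module("sigmoid")
  m$forward <- function(x) {
    s <- 1 / (1 + exp(-x))
    cache_push(m, list(s = s))
    s
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    dy * cc$s * (1 - cc$s)
  }
  m
}

# conv -> group norm -> SiLU, the standard block of the backbone/neck.
new_conv_block <- function(cin, cout, k = 3L, stride = 1L, groups = gn_groups_for(cout)) {
  m <- new_module("conv_block")
  m$conv <- new_conv2d(cin, cout, k, stride, bias = FALSE)
  m$gn <- new_group_norm(cout, groups)
  m$act <- new_silu()
  m$children <- list(m$conv, m$gn, m$act)
  m$forward <- function(x) m$act$forward(m$gn$forward(m$conv$forward(x)))
  m$backward <- function(dy) m$conv$backward(m$gn$backward(m$act$backward(dy)))
  m
}

new_maxpool <- function(k, stride = 1L, pad = k %/% 2L) {
  m <- new_module("maxpool")
  m$k <- as.integer(k); m$stride <- as.integer(stride); m$pad <- as.integer(pad)
  m$forward <- function(x) {
    d <- fm_dims(x)
    r <- cpp_maxpool(as.double(x), d[1], d[2], d[3], m$k, m$stride, m$pad)
    cache_push(m, list(idx = r$idx, d = d))
    r$y
  }
  m$backward <- function(dy) {
    cc <- cache_pop(m)
    cpp_maxpool_bw(as.double(dy), cc$idx, cc$d[1], cc$d[2], cc$d[3])
  }
  m
}

upsample2x <- function(x) {
  d <- fm_dims(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

upsample2x_bw <- function(dy) {
  d <- fm_dims(dy)
  o <- seq(1L, d[1], 2L); p <- seq(1L, d[2], 2L)
  dy[o, p, , drop = FALSE] + dy[o + 1L, p, , drop = FALSE] +
    dy[o, p + 1L, , drop = FALSE] + dy[o + 1L, p + 1L, , drop = FALSE]
}

cat_channels <- function(a, b) {
  da <- fm_dims(a); db <- fm_dims(b)
  if (any(da[1:2] != db[1:2])) stop("spatial mismatch in channel concat")
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

split_channels_bw <- function(dy, c1) {
  d <- fm_dims(dy)
  list(dy[, , seq_len(c1), drop = FALSE],
       dy[, , (c1 + 1L):d[3], drop = FALSE])
}

# -- optimizer ----------------------------------------------------------------

new_adamw <- function(model, lr = 2e-3, weight_decay = 5e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- module_params(model)
  opt$lr <- lr; opt$wd <- weight_decay
  opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(opt$params, function(p) p$env[[p$w]] * 0)
  opt$v <- lapply(opt$params, function(p) p$env[[p$w]] * 0)
  opt
}

adamw_step <- function(opt, lr = opt$lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    g <- p$env[[p$g]]
    opt$m[[i]] <- opt$beta1 * opt$m[[i]] + (1 - opt$beta1) * g
    opt$v[[i]] <- opt$beta2 * opt$v[[i]] + (1 - opt$beta2) * g * g
    mhat <- opt$m[[i]] / bc1
    vhat <- opt$v[[i]] / bc2
    w <- p$env[[p$w]]
    w <- w - lr * (mhat / (sqrt(vhat) + opt$eps) + if (p$decay) opt$wd * w else 0)
    p$env[[p$w]] <- w
  }
  invisible(opt)
}
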
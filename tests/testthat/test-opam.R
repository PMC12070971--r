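test_that("position attention preserves shape, uniformity, and is not permutation invariant", {
  set.seed(31)
  pa <- new_position_attention()
  x <- array(rnorm(10 * 12 * 6), dim = c(10, 12, 6))
  y <- pa$forward(x)
  expect_equal(dim(y), dim(x))
  # spatially uniform input -> spatially uniform output (replicate padding)
  u <- array(rep(rnorm(6), each = 10 * 12), dim = c(10, 12, 6))
  yu <- pa$forward(u)
  for (c in 1:6) expect_lt(diff(range(yu[, , c])), 1e-12)
  # permuting pixels changes the output beyond a pure permutation
  perm <- sample(10 * 12)
  xp <- x
  for (c in 1:6) xp[, , c] <- array(as.vector(x[, , c])[perm], dim = c(10, 12))
  yp <- pa$forward(xp)
  ypp <- yp
  for (c in 1:6) ypp[, , c] <- array(as.vector(yp[, , c])[order(perm)], dim = c(10, 12))
  expect_gt(max(abs(ypp - y)), 1e-6)
  sddetect:::clear_caches(pa)
})

test_that("channel attention gates are per-channel constants in [0,1]", {
  set.seed(32)
  ca <- new_channel_attention(16, reduction = 4)
  x <- array(rnorm(8 * 8 * 16), dim = c(8, 8, 16))
  y <- ca$forward(x)
  gate <- y / x
  for (c in 1:16) {
    g <- gate[, , c]
    expect_lt(stats::var(as.vector(g)), 1e-18)  # constant across space
    expect_true(all(g > 0 & g < 1))
  }
  # forcing the gates to their limits gives identity / zero maps
  ca$b2[] <- 50   # sigmoid -> 1
  expect_equal(ca$forward(x), x, tolerance = 1e-9)
  ca$b2[] <- -50  # sigmoid -> 0
  expect_equal(ca$forward(x), x * 0, tolerance = 1e-9)
  sddetect:::clear_caches(ca)
})

test_that("pixel attention produces gates strictly inside (0,1) with the right shape", {
  set.seed(33)
  px <- new_pixel_attention(8)
  a <- array(rnorm(6 * 6 * 8), dim = c(6, 6, 8))
  b <- array(rnorm(6 * 6 * 8), dim = c(6, 6, 8))
  g <- px$forward(a, b)
  expect_equal(dim(g), c(6L, 6L, 8L))
  expect_true(all(g > 0 & g < 1))
  # zero-weight initialization -> gate exactly 0.5
  px$conv2$W[] <- 0; px$conv2$b[] <- 0
  expect_equal(px$forward(a, b), array(0.5, dim = c(6, 6, 8)))
  expect_error(px$forward(a, array(0, dim = c(5, 6, 8))), "shape")
  sddetect:::clear_caches(px)
  # shared-gate variant broadcasts one channel
  pxs <- new_pixel_attention(8, shared_gate = TRUE)
  gs <- pxs$forward(a, b)
  expect_equal(dim(gs), c(6L, 6L, 8L))
  expect_equal(gs[, , 1], gs[, , 5])
  sddetect:::clear_caches(pxs)
})

test_that("opam limits recover the pure streams bit-exactly", {
  set.seed(34)
  op <- new_opam(c_low = 4, c_high = 6, c_out = 6)
  f_low <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  f_high <- array(rnorm(8 * 8 * 6), dim = c(8, 8, 6))
  low_resampled <- op$down$forward(f_low)
  high_projected <- op$proj$forward(f_high)
  sddetect:::clear_caches(op$down); sddetect:::clear_caches(op$proj)
  y1 <- opam_fuse(f_low, f_high, module = op, gate_override = 1)
  expect_identical(y1, low_resampled)
  y0 <- opam_fuse(f_low, f_high, module = op, gate_override = 0)
  expect_identical(y0, high_projected)
})

test_that("opam output is a per-position convex combination of the streams", {
  set.seed(35)
  op <- new_opam(4, 6, 6)
  f_low <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  f_high <- array(rnorm(8 * 8 * 6), dim = c(8, 8, 6))
  lo <- op$down$forward(f_low); hi <- op$proj$forward(f_high)
  sddetect:::clear_caches(op$down); sddetect:::clear_caches(op$proj)
  y <- opam_fuse(f_low, f_high, module = op)
  mn <- pmin(lo, hi); mx <- pmax(lo, hi)
  expect_true(all(y >= mn - 1e-9 & y <= mx + 1e-9))
  expect_equal(dim(y), dim(hi))
})

test_that("opam gradients reach both attention branches", {
  set.seed(36)
  op <- new_opam(4, 6, 6)
  sddetect:::zero_grads(op)
  f_low <- array(rnorm(16 * 16 * 4), dim = c(16, 16, 4))
  f_high <- array(rnorm(8 * 8 * 6), dim = c(8, 8, 6))
  y <- op$forward(f_low, f_high)
  d <- op$backward(array(rnorm(length(y)), dim = dim(y)))
  expect_equal(dim(d$d_low), dim(f_low))
  expect_equal(dim(d$d_high), dim(f_high))
  expect_gt(sum(abs(op$ca$gW1)), 0)
  expect_gt(sum(abs(op$pa$conv$gW)), 0)
  expect_gt(sum(abs(op$px$conv1$gW)), 0)
})
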
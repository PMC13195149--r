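test_that("receptive-field expansion obeys the shape law and padding", {
  x <- array(1, c(1, 1, 3, 3))
  y <- expand_to_receptive_field(x, k = 3, stride = 1, pad = 1)
  expect_equal(dim(y), c(1, 9, 3, 3))
  # centre position sees the full window of ones
  expect_equal(as.numeric(y[1, , 2, 2]), rep(1, 9))
  # the corner window contains the padding zeros (5 in-bounds, 4 padded)
  expect_equal(sum(y[1, , 1, 1] == 0), 5)  # top-left: rows/cols -1 are padded
  expect_equal(sum(y[1, , 1, 1]), 4)

  x2 <- array(0, c(1, 1, 4, 4))
  y2 <- expand_to_receptive_field(x2, k = 3, stride = 2, pad = 1)
  expect_equal(dim(y2)[3:4], c(2, 2))

  expect_error(expand_to_receptive_field(x, k = 0), "invalid config")
  expect_error(expand_to_receptive_field(x, k = 3, stride = 0),
               "invalid config")
})

test_that("receptive-field expansion matches the nested-loop oracle", {
  for (seed in 1:3) {
    x <- rand_fm(1, 2, 5, 5, seed)
    y <- expand_to_receptive_field(x, k = 3, stride = 1, pad = 1)
    expect_equal(as.numeric(y), as.numeric(oracle_rf_expand(x, 3, 1, 1)),
                 tolerance = 1e-12)
  }
  x <- rand_fm(2, 3, 8, 8, 9)
  y <- expand_to_receptive_field(x, k = 3, stride = 2, pad = 1)
  expect_equal(as.numeric(y), as.numeric(oracle_rf_expand(x, 3, 2, 1)),
               tolerance = 1e-12)
})

test_that("RFCA attention is sigmoid-bounded and directionally consistent", {
  set.seed(4)
  blk <- new_rfca_conv(4, 4)
  e <- rand_fm(1, 4, 9, 9, 5)
  at <- rfca_attention(blk, e)
  expect_true(all(at$a_h > 0 & at$a_h < 1))
  expect_true(all(at$a_w > 0 & at$a_w < 1))
  # forcing the branch convolutions to zero gives sigmoid(0) = 0.5
  blk0 <- blk
  blk0$sub$conv_h$params$w[] <- 0
  blk0$sub$conv_h$params$b[] <- 0
  blk0$sub$conv_w$params$w[] <- 0
  blk0$sub$conv_w$params$b[] <- 0
  at0 <- rfca_attention(blk0, e)
  expect_equal(as.numeric(at0$a_h), rep(0.5, length(at0$a_h)))
  expect_equal(as.numeric(at0$a_w), rep(0.5, length(at0$a_w)))
  # a map constant across W gives a horizontal branch constant across W
  ec <- array(rep(rnorm(4 * 9), times = 9), c(1, 4, 9, 9))
  atc <- rfca_attention(blk, ec)
  expect_lt(max(apply(atc$a_w[1, , 1, ], 1, function(r) diff(range(r)))),
            1e-12)
  # channel mismatch is rejected
  expect_error(rfca_attention(blk, rand_fm(1, 3, 9, 9)), "channel mismatch")
})

test_that("RFCA convolution preserves resolution and honours the attention", {
  set.seed(5)
  x <- rand_fm(2, 16, 32, 32, 6)
  blk <- new_rfca_conv(16, 8, stride = 1)
  y <- mod_fw(blk, x)$y
  expect_equal(dim(y), c(2, 8, 32, 32))
  y2 <- mod_fw(new_rfca_conv(16, 8, stride = 2), x)$y
  expect_equal(dim(y2), c(2, 8, 16, 16))
  expect_error(mod_fw(blk, rand_fm(2, 4, 8, 8)), "invalid config")

  # identity attention leaves the collapse input unchanged; halved attention
  # halves it (the window re-weighting is purely multiplicative)
  e <- rand_fm(1, 16, 12, 12, 7)
  ones_h <- array(1, c(1, 16, 12, 1))
  ones_w <- array(1, c(1, 16, 12, 1))
  w1 <- wetbird:::cpp_attnmul_fw(e, ones_h, ones_w)
  expect_equal(as.numeric(w1), as.numeric(e), tolerance = 1e-12)
  half_h <- array(0.5, c(1, 16, 12, 1))
  w2 <- wetbird:::cpp_attnmul_fw(e, half_h, ones_w)
  expect_equal(as.numeric(w2), as.numeric(0.5 * e), tolerance = 1e-12)
  # and the collapse convolution therefore produces identical outputs
  cfw <- function(z) mod_fw(blk$sub$collapse, z)$y
  expect_equal(cfw(w1), cfw(e), tolerance = 1e-12)
})

test_that("C2f with RFCA necks preserves space, grows width with n, audits", {
  set.seed(6)
  x <- rand_fm(1, 32, 16, 16, 8)
  y <- mod_fw(new_c2f(32, 24, 1, rfca = TRUE), x)$y
  expect_equal(dim(y), c(1, 24, 16, 16))
  b1 <- new_c2f(32, 32, 1, rfca = TRUE)
  b2 <- new_c2f(32, 32, 2, rfca = TRUE)
  # concatenated hidden width grows by exactly one branch's channels
  expect_equal(b2$sub$cv2$cfg$c1 - b1$sub$cv2$cfg$c1, 16)
  expect_error(new_c2f(32, 32, 0), "invalid config")
  # parameter count equals the analytic layer-by-layer census
  b64 <- new_c2f(64, 64, 1, rfca = TRUE)
  expect_equal(wetbird:::n_params(b64), audit_params(b64))
})

test_that("LSKA preserves shape and its 1D pairs reproduce rank-1 kernels", {
  set.seed(7)
  x <- rand_fm(1, 8, 20, 20, 10)
  y <- lska(x, K = 7, d = 2)
  expect_equal(dim(y), dim(x))
  expect_error(new_lska(8, K = 2, d = 2), "invalid config")

  # a (1,k) then (k,1) depth-wise pair equals one 2-D depth-wise convolution
  # with the rank-1 kernel v u^T
  blk <- new_lska(8, 7, 2)
  u <- blk$sub$c0h$params$w   # [8,1,1,3] horizontal taps
  v <- blk$sub$c0v$params$w   # [8,1,3,1] vertical taps
  xp <- wetbird:::pad_axis(x, 4, 1)
  h1 <- mod_fw(blk$sub$c0h, xp)$y
  h1p <- wetbird:::pad_axis(h1, 3, 1)
  pair <- mod_fw(blk$sub$c0v, h1p)$y
  k2d <- array(0, c(3, 3, 8))
  for (cc in 1:8) k2d[, , cc] <- v[cc, 1, , 1] %o% u[cc, 1, 1, ]
  expect_lt(max(abs(pair - oracle_dw_conv2d(x, k2d, 1, 1))), 1e-5)

  # gradient support of one centre output is confined to the analytic
  # effective receptive field implied by (K, d)
  xs <- rand_fm(1, 2, 17, 17, 11)
  blk2 <- new_lska(2, 7, 2)
  fw <- mod_fw(blk2, xs, train = FALSE)
  gy <- array(0, dim(fw$y))
  gy[1, 1, 9, 9] <- 1
  gx <- mod_bw(blk2, fw$cache, gy)$gx
  # attention chain composes kernels of effective half-width (7-1)/2 = 3,
  # so no influence can reach beyond 3 pixels from the centre
  outside <- gx[1, , -(6:12), , drop = FALSE]
  expect_equal(max(abs(outside)), 0)
  outside2 <- gx[1, , , -(6:12), drop = FALSE]
  expect_equal(max(abs(outside2)), 0)
})

test_that("SPPF serial pooling equals single large pools; LSKA slot is modular", {
  set.seed(8)
  x <- rand_fm(1, 8, 12, 12, 12)
  p5 <- new_maxpool(5, 1, 2)
  p9 <- new_maxpool(9, 1, 4)
  p13 <- new_maxpool(13, 1, 6)
  y1 <- mod_fw(p5, x)$y
  y2 <- mod_fw(p5, y1)$y
  y3 <- mod_fw(p5, y2)$y
  expect_identical(y2, mod_fw(p9, x)$y)
  expect_identical(y3, mod_fw(p13, x)$y)

  x2 <- rand_fm(1, 64, 8, 8, 13)
  sl <- new_sppf(64, 32, 5, lska = TRUE)
  expect_equal(dim(mod_fw(sl, x2)$y), c(1, 32, 8, 8))
  # replacing the LSKA stage by the identity reduces SPPF-LSKA to plain SPPF
  plain <- new_sppf(64, 32, 5, lska = FALSE)
  plain$sub$cv1 <- sl$sub$cv1
  plain$sub$cv2 <- sl$sub$cv2
  neut <- sl
  neut$sub$lska <- wetbird:::new_identity()
  expect_equal(mod_fw(neut, x2)$y, mod_fw(plain, x2)$y, tolerance = 1e-12)
  expect_error(new_sppf(8, 8, 4), "invalid config")
})

test_that("CARAFE kernels are normalised and reassembly matches the oracle", {
  set.seed(9)
  blk <- new_carafe(16, cm = 8)
  x <- rand_fm(1, 16, 6, 6, 14)
  kern <- carafe_predict_kernels(blk, x)
  expect_equal(dim(kern), c(1, 25, 12, 12))
  sums <- apply(kern, c(1, 3, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-5)
  expect_true(all(kern >= 0))
  # zeroed encoder gives the uniform kernel 1/Kup^2
  blk0 <- blk
  blk0$sub$enc$params$w[] <- 0
  blk0$sub$enc$params$b[] <- 0
  k0 <- carafe_predict_kernels(blk0, x)
  expect_equal(as.numeric(k0), rep(1 / 25, length(k0)), tolerance = 1e-12)

  # reassembly: brute-force evaluation of the weighted-neighbourhood sum
  x2 <- rand_fm(1, 4, 6, 6, 15)
  k2 <- carafe_predict_kernels(new_carafe(4, cm = 6), x2)
  y <- carafe_reassemble(x2, k2, sigma = 2, kup = 5)
  expect_lt(max(abs(y - oracle_carafe(x2, k2, 2, 5))), 1e-6)

  # constant input is preserved by any normalised kernel
  xc <- array(3.25, c(1, 4, 6, 6))
  yc <- carafe_reassemble(xc, k2, 2, 5)
  # border positions lose out-of-bounds taps, so restrict to the interior
  expect_lt(max(abs(yc[1, , 5:8, 5:8] - 3.25)), 1e-6)

  # one-hot centre kernels reduce to nearest-neighbour up-sampling
  k1 <- array(0, dim(k2))
  k1[, 13, , ] <- 1   # centre tap of the 5x5 neighbourhood
  y1 <- carafe_reassemble(x2, k1, 2, 5)
  expect_identical(y1, wetbird:::cpp_upnn_fw(x2, 2L))

  # convex combination: outputs bounded by the input range
  expect_true(all(y >= min(x2) - 1e-9 & y <= max(x2) + 1e-9))
})
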
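# ---------------------------------------------------------------------------
# Architectural blocks.
#
# RFCAConv: attention is modelled in receptive-field space.  A grouped k x k
# convolution generates k^2 features per input channel per window; these are
# tiled into an expanded map [N, C, kH', kW'] in which every k x k tile is one
# receptive field.  Coordinate attention (directional average pooling, shared
# squeeze, per-direction sigmoid branches) re-weights the expanded map at the
# window level before a k-stride-k convolution collapses each window back to a
# single output position.
# ---------------------------------------------------------------------------

new_rfca_conv <- function(c1, c2, k = 3, stride = 1, reduction = 2,
                          mip_floor = 8) {
  if (k %% 2 != 1 || k < 1 || stride < 1)
    stop("invalid config: rfca kernel must be odd positive, stride positive")
  mip <- max(mip_floor, c1 %/% reduction)
  sub <- list(
    generate = new_conv(c1, c1 * k * k, k, stride = stride, pad = k %/% 2,
                        groups = c1, act = "relu", norm = TRUE),
    squeeze = new_conv(c1, mip, 1, act = "silu", norm = TRUE),
    conv_h = new_conv(mip, c1, 1, act = "sigmoid", norm = FALSE),
    conv_w = new_conv(mip, c1, 1, act = "sigmoid", norm = FALSE),
    collapse = new_conv(c1, c2, k, stride = k, pad = 0, act = "silu",
                        norm = TRUE))
  new_module("wb_rfca", sub = sub,
             cfg = list(c1 = c1, c2 = c2, k = k, stride = stride, mip = mip))
}

# directional CA attention on an expanded receptive-field map
rfca_attention_fw <- function(mod, e, train) {
  d <- dim(e)
  n <- d[1]; cc <- d[2]; hk <- d[3]; wk <- d[4]
  dp <- cpp_dirpool_fw(e)
  xh <- dp$xh
  xw <- dp$xwt
  cat_hw <- array(0, c(n, cc, hk + wk, 1))
  cat_hw[, , seq_len(hk), ] <- xh
  cat_hw[, , hk + seq_len(wk), ] <- xw
  rs <- mod_fw(mod$sub$squeeze, cat_hw, train)
  mod$sub$squeeze <- rs$mod
  y1 <- rs$y
  yh <- y1[, , seq_len(hk), , drop = FALSE]
  yw <- y1[, , hk + seq_len(wk), , drop = FALSE]
  rh <- mod_fw(mod$sub$conv_h, yh, train); mod$sub$conv_h <- rh$mod
  rw <- mod_fw(mod$sub$conv_w, yw, train); mod$sub$conv_w <- rw$mod
  list(mod = mod, ah = rh$y, awt = rw$y,   # [n,C,hk,1] and [n,C,wk,1]
       cache = list(squeeze = rs$cache, conv_h = rh$cache, conv_w = rw$cache,
                    hk = hk, wk = wk, dims = d))
}

rfca_attention_bw <- function(mod, cache, g_ah, g_awt, grads) {
  hk <- cache$hk; wk <- cache$wk
  rw <- mod_bw(mod$sub$conv_w, cache$conv_w, g_awt)
  rh <- mod_bw(mod$sub$conv_h, cache$conv_h, g_ah)
  grads$sub$conv_w <- add_grads(grads$sub$conv_w, rw$grads)
  grads$sub$conv_h <- add_grads(grads$sub$conv_h, rh$grads)
  d <- dim(rh$gx)
  g_y1 <- array(0, c(d[1], d[2], hk + wk, 1))
  g_y1[, , seq_len(hk), ] <- rh$gx
  g_y1[, , hk + seq_len(wk), ] <- rw$gx
  rs <- mod_bw(mod$sub$squeeze, cache$squeeze, g_y1)
  grads$sub$squeeze <- add_grads(grads$sub$squeeze, rs$grads)
  g_xh <- rs$gx[, , seq_len(hk), , drop = FALSE]       # [n,C,hk,1]
  g_xw <- rs$gx[, , hk + seq_len(wk), , drop = FALSE]  # [n,C,wk,1]
  list(g_e = cpp_dirpool_bw(g_xh, g_xw, cache$dims), grads = grads)
}

mod_fw.wb_rfca <- function(mod, x, train = FALSE) {
  k <- mod$cfg$k
  rg <- mod_fw(mod$sub$generate, x, train)
  mod$sub$generate <- rg$mod
  e <- cpp_tile_rearrange(rg$y, k)
  at <- rfca_attention_fw(mod, e, train)
  mod <- at$mod
  w <- cpp_attnmul_fw(e, at$ah, at$awt)
  rc <- mod_fw(mod$sub$collapse, w, train)
  mod$sub$collapse <- rc$mod
  cache <- list(generate = rg$cache, attn = at$cache, collapse = rc$cache,
                e = e, ah = at$ah, awt = at$awt)
  list(y = rc$y, cache = cache, mod = mod)
}

mod_bw.wb_rfca <- function(mod, cache, gy) {
  k <- mod$cfg$k
  grads <- list(params = list(), sub = list())
  rc <- mod_bw(mod$sub$collapse, cache$collapse, gy)
  grads$sub$collapse <- rc$grads
  am <- cpp_attnmul_bw(cache$e, cache$ah, cache$awt, rc$gx)
  at <- rfca_attention_bw(mod, cache$attn, am$gah, am$gawt, grads)
  grads <- at$grads
  g_e <- am$ge + at$g_e
  g_gen <- cpp_tile_rearrange_bw(g_e, k)
  rg <- mod_bw(mod$sub$generate, cache$generate, g_gen)
  grads$sub$generate <- rg$grads
  list(gx = rg$gx, grads = grads)
}

# ---------------------------------------------------------------------------
# bottlenecks and C2f aggregation
# ---------------------------------------------------------------------------

new_bottleneck <- function(c, shortcut = TRUE) {
  sub <- list(cv1 = new_conv(c, c, 3), cv2 = new_conv(c, c, 3))
  new_module("wb_bottleneck", sub = sub, cfg = list(add = shortcut))
}

mod_fw.wb_bottleneck <- function(mod, x, train = FALSE) {
  r <- seq_fw(mod, c("cv1", "cv2"), x, train)
  y <- if (mod$cfg$add) x + r$y else r$y
  list(y = y, cache = r$caches, mod = r$mod)
}

mod_bw.wb_bottleneck <- function(mod, cache, gy) {
  r <- seq_bw(mod, c("cv1", "cv2"), cache, gy,
              list(params = list(), sub = list()))
  gx <- if (mod$cfg$add) r$gx + gy else r$gx
  list(gx = gx, grads = r$grads)
}

# RFCA neck: plain conv then RFCAConv, no residual add
new_rfca_neck <- function(c, reduction = 2, mip_floor = 8) {
  sub <- list(cv1 = new_conv(c, c, 3),
              rfca = new_rfca_conv(c, c, reduction = reduction,
                                   mip_floor = mip_floor))
  new_module("wb_rfca_neck", sub = sub)
}

mod_fw.wb_rfca_neck <- function(mod, x, train = FALSE) {
  r <- seq_fw(mod, c("cv1", "rfca"), x, train)
  list(y = r$y, cache = r$caches, mod = r$mod)
}

mod_bw.wb_rfca_neck <- function(mod, cache, gy)
  seq_bw(mod, c("cv1", "rfca"), cache, gy, list(params = list(), sub = list()))

new_c2f <- function(c1, c2, n = 1, shortcut = FALSE, rfca = FALSE,
                    reduction = 2, mip_floor = 8) {
  if (n < 1) stop("invalid config: n_bottlenecks must be >= 1")
  c <- c2 %/% 2
  sub <- list(cv1 = new_conv(c1, 2 * c, 1),
              cv2 = new_conv((2 + n) * c, c2, 1))
  for (i in seq_len(n))
    sub[[paste0("m", i)]] <- if (rfca) new_rfca_neck(c, reduction, mip_floor)
                             else new_bottleneck(c, shortcut)
  new_module("wb_c2f", sub = sub, cfg = list(c1 = c1, c2 = c2, n = n, c = c))
}

mod_fw.wb_c2f <- function(mod, x, train = FALSE) {
  cfg <- mod$cfg
  r1 <- mod_fw(mod$sub$cv1, x, train)
  mod$sub$cv1 <- r1$mod
  c <- cfg$c
  d <- dim(r1$y)
  a <- r1$y[, seq_len(c), , , drop = FALSE]
  b <- r1$y[, c + seq_len(c), , , drop = FALSE]
  ys <- list(a, b)
  mcaches <- list()
  for (i in seq_len(cfg$n)) {
    nm <- paste0("m", i)
    rm <- mod_fw(mod$sub[[nm]], b, train)
    mod$sub[[nm]] <- rm$mod
    mcaches[[nm]] <- rm$cache
    b <- rm$y
    ys <- c(ys, list(b))
  }
  cat <- array(0, c(d[1], (2 + cfg$n) * c, d[3], d[4]))
  for (i in seq_along(ys)) cat[, (i - 1) * c + seq_len(c), , ] <- ys[[i]]
  r2 <- mod_fw(mod$sub$cv2, cat, train)
  mod$sub$cv2 <- r2$mod
  list(y = r2$y,
       cache = list(cv1 = r1$cache, cv2 = r2$cache, m = mcaches, d = d),
       mod = mod)
}

mod_bw.wb_c2f <- function(mod, cache, gy) {
  cfg <- mod$cfg
  c <- cfg$c
  grads <- list(params = list(), sub = list())
  r2 <- mod_bw(mod$sub$cv2, cache$cv2, gy)
  grads$sub$cv2 <- r2$grads
  gparts <- lapply(seq_len(2 + cfg$n), function(i) {
    g <- r2$gx[, (i - 1) * c + seq_len(c), , , drop = FALSE]
    g
  })
  gb <- gparts[[2 + cfg$n]]
  for (i in rev(seq_len(cfg$n))) {
    nm <- paste0("m", i)
    rm <- mod_bw(mod$sub[[nm]], cache$m[[nm]], gb)
    grads$sub[[nm]] <- rm$grads
    gb <- rm$gx + gparts[[i + 1]]
  }
  d <- cache$d
  g1 <- array(0, d)
  g1[, seq_len(c), , ] <- gparts[[1]]
  g1[, c + seq_len(c), , ] <- gb
  r1 <- mod_bw(mod$sub$cv1, cache$cv1, g1)
  grads$sub$cv1 <- r1$grads
  list(gx = r1$gx, grads = grads)
}

# ---------------------------------------------------------------------------
# LSKA: cascaded separable large-kernel attention.
# A K x K depth-wise kernel is realised as 1D horizontal+vertical pairs:
# a (2d-1) local pair and a dilated pair of size (K-(2d-1))/d + 1 with
# dilation d, followed by a 1x1 channel-mixing convolution; the result
# multiplies the input as an attention map.
# ---------------------------------------------------------------------------

lska_kernel_sizes <- function(K, d) {
  if (d < 1 || K < 2 * d - 1)
    stop("invalid config: LSKA requires K >= 2d-1, d >= 1")
  kl <- 2 * d - 1
  rem <- K - kl
  if (rem %% d != 0)
    stop("invalid config: (K - (2d-1)) must be divisible by d")
  kd <- rem %/% d + 1
  list(local = kl, dilated = kd)
}

new_lska <- function(c, K = 7, d = 2) {
  ks <- lska_kernel_sizes(K, d)
  dw <- function(kh, kw, dil)
    new_conv(c, c, kh = kh, kw = kw, dilation = dil, groups = c,
             pad = NULL, act = "none", norm = FALSE, bias = FALSE)
  sub <- list(
    c0h = dw(1, ks$local, 1),
    c0v = dw(ks$local, 1, 1),
    csh = dw(1, ks$dilated, d),
    csv = dw(ks$dilated, 1, d),
    pw = new_conv(c, c, 1, act = "none", norm = FALSE, bias = FALSE))
  # asymmetric padding is emulated with symmetric pad on the long axis only
  sub$c0h$cfg$pad <- 0; sub$c0v$cfg$pad <- 0
  sub$csh$cfg$pad <- 0; sub$csv$cfg$pad <- 0
  new_module("wb_lska", sub = sub, cfg = list(c = c, K = K, d = d, ks = ks))
}

# pad a feature map symmetrically along one spatial axis
pad_axis <- function(x, axis, p) {
  if (p == 0) return(x)
  d <- dim(x)
  d2 <- d
  d2[axis] <- d[axis] + 2 * p
  y <- array(0, d2)
  if (axis == 3) y[, , p + seq_len(d[3]), ] <- x else y[, , , p + seq_len(d[4])] <- x
  y
}

unpad_axis <- function(g, axis, p) {
  if (p == 0) return(g)
  d <- dim(g)
  if (axis == 3) g[, , p + seq_len(d[3] - 2 * p), , drop = FALSE]
  else g[, , , p + seq_len(d[4] - 2 * p), drop = FALSE]
}

lska_chain <- c("c0h", "c0v", "csh", "csv", "pw")

lska_pads <- function(mod) {
  ks <- mod$cfg$ks; d <- mod$cfg$d
  list(c0h = c(4, (ks$local - 1) %/% 2),
       c0v = c(3, (ks$local - 1) %/% 2),
       csh = c(4, d * (ks$dilated - 1) %/% 2),
       csv = c(3, d * (ks$dilated - 1) %/% 2),
       pw = c(3, 0))
}

mod_fw.wb_lska <- function(mod, x, train = FALSE) {
  pads <- lska_pads(mod)
  caches <- list()
  a <- x
  for (nm in lska_chain) {
    p <- pads[[nm]]
    ap <- pad_axis(a, p[1], p[2])
    r <- mod_fw(mod$sub[[nm]], ap, train)
    mod$sub[[nm]] <- r$mod
    caches[[nm]] <- r$cache
    a <- r$y
  }
  list(y = x * a, cache = list(chain = caches, x = x, attn = a), mod = mod)
}

mod_bw.wb_lska <- function(mod, cache, gy) {
  pads <- lska_pads(mod)
  grads <- list(params = list(), sub = list())
  g_a <- gy * cache$x
  gx <- gy * cache$attn
  for (nm in rev(lska_chain)) {
    r <- mod_bw(mod$sub[[nm]], cache$chain[[nm]], g_a)
    grads$sub[[nm]] <- r$grads
    p <- pads[[nm]]
    g_a <- unpad_axis(r$gx, p[1], p[2])
  }
  list(gx = gx + g_a, grads = grads)
}

# ---------------------------------------------------------------------------
# SPPF and SPPF-LSKA
# ---------------------------------------------------------------------------

new_sppf <- function(c1, c2, pool_k = 5, lska = FALSE, lska_K = 7, lska_d = 2) {
  if (pool_k %% 2 != 1) stop("invalid config: pool_k must be odd")
  c_ <- c1 %/% 2
  sub <- list(cv1 = new_conv(c1, c_, 1),
              cv2 = new_conv(4 * c_, c2, 1),
              pool = new_maxpool(pool_k, 1, pool_k %/% 2))
  if (lska) sub$lska <- new_lska(4 * c_, lska_K, lska_d)
  new_module("wb_sppf", sub = sub,
             cfg = list(c1 = c1, c2 = c2, pool_k = pool_k, lska = lska))
}

mod_fw.wb_sppf <- function(mod, x, train = FALSE) {
  r1 <- mod_fw(mod$sub$cv1, x, train); mod$sub$cv1 <- r1$mod
  y0 <- r1$y
  pc <- list()
  ys <- list(y0)
  a <- y0
  for (i in 1:3) {
    rp <- mod_fw(mod$sub$pool, a, train)
    pc[[i]] <- rp$cache
    a <- rp$y
    ys <- c(ys, list(a))
  }
  d <- dim(y0)
  cat <- array(0, c(d[1], 4 * d[2], d[3], d[4]))
  for (i in 1:4) cat[, (i - 1) * d[2] + seq_len(d[2]), , ] <- ys[[i]]
  lc <- NULL
  z <- cat
  if (mod$cfg$lska) {
    rl <- mod_fw(mod$sub$lska, z, train)
    mod$sub$lska <- rl$mod
    lc <- rl$cache
    z <- rl$y
  }
  r2 <- mod_fw(mod$sub$cv2, z, train); mod$sub$cv2 <- r2$mod
  list(y = r2$y,
       cache = list(cv1 = r1$cache, cv2 = r2$cache, pool = pc, lska = lc,
                    c_ = d[2]),
       mod = mod)
}

mod_bw.wb_sppf <- function(mod, cache, gy) {
  grads <- list(params = list(), sub = list())
  r2 <- mod_bw(mod$sub$cv2, cache$cv2, gy)
  grads$sub$cv2 <- r2$grads
  g <- r2$gx
  if (mod$cfg$lska) {
    rl <- mod_bw(mod$sub$lska, cache$lska, g)
    grads$sub$lska <- rl$grads
    g <- rl$gx
  }
  c_ <- cache$c_
  gparts <- lapply(1:4, function(i) {
    gg <- g[, (i - 1) * c_ + seq_len(c_), , , drop = FALSE]
    gg
  })
  gacc <- gparts[[4]]
  for (i in 3:1) {
    rp <- mod_bw(mod$sub$pool, cache$pool[[i]], gacc)
    grads$sub$pool <- add_grads(grads$sub$pool, rp$grads)
    gacc <- rp$gx + gparts[[i]]
  }
  r1 <- mod_bw(mod$sub$cv1, cache$cv1, gacc)
  grads$sub$cv1 <- r1$grads
  list(gx = r1$gx, grads = grads)
}

# ---------------------------------------------------------------------------
# CARAFE: content-aware reassembly of features.
# A 1x1 compressor reduces channels to Cm; a Kenc x Kenc encoder predicts
# sigma^2*Kup^2 kernel coefficients per source position, which are
# pixel-shuffled to the sigma-times-larger grid and softmax-normalised over
# the Kup^2 taps; the output is the kernel-weighted sum over the Kup x Kup
# source neighbourhood, shared across channels.
# ---------------------------------------------------------------------------

new_carafe <- function(c, cm = 60, kenc = 3, kup = 5, sigma = 2) {
  if (kup %% 2 != 1) stop("invalid config: kup must be odd")
  if (sigma < 1) stop("invalid config: sigma must be >= 1")
  sub <- list(
    comp = new_conv(c, cm, 1, act = "none", norm = FALSE),
    enc = new_conv(cm, sigma^2 * kup^2, kenc, act = "none", norm = FALSE))
  new_module("wb_carafe", sub = sub,
             cfg = list(c = c, cm = cm, kenc = kenc, kup = kup, sigma = sigma))
}

# [N, K2*s^2, H, W] -> [N, K2, sH, sW]; channel u = t + K2*(si + s*sj)
carafe_shuffle <- function(ek, k2, s) {
  d <- dim(ek)
  dim(ek) <- c(d[1], k2, s, s, d[3], d[4])
  ek <- aperm(ek, c(1, 2, 3, 5, 4, 6))
  dim(ek) <- c(d[1], k2, s * d[3], s * d[4])
  ek
}

carafe_unshuffle <- function(g, k2, s) {
  d <- dim(g)  # [N, k2, sH, sW]
  h <- d[3] %/% s; w <- d[4] %/% s
  dim(g) <- c(d[1], k2, s, h, s, w)
  g <- aperm(g, c(1, 2, 3, 5, 4, 6))
  dim(g) <- c(d[1], k2 * s * s, h, w)
  g
}

softmax_k <- function(a) cpp_softmax_taps(a)

mod_fw.wb_carafe <- function(mod, x, train = FALSE) {
  cfg <- mod$cfg
  r1 <- mod_fw(mod$sub$comp, x, train); mod$sub$comp <- r1$mod
  r2 <- mod_fw(mod$sub$enc, r1$y, train); mod$sub$enc <- r2$mod
  k2 <- cfg$kup^2
  raw <- carafe_shuffle(r2$y, k2, cfg$sigma)
  kern <- softmax_k(raw)
  y <- cpp_carafe_fw(x, kern, cfg$sigma, cfg$kup)
  list(y = y,
       cache = list(comp = r1$cache, enc = r2$cache, kern = kern, x = x),
       mod = mod)
}

mod_bw.wb_carafe <- function(mod, cache, gy) {
  cfg <- mod$cfg
  grads <- list(params = list(), sub = list())
  r <- cpp_carafe_bw(cache$x, cache$kern, gy, cfg$sigma, cfg$kup)
  graw <- cpp_softmax_taps_bw(cache$kern, r$gk)
  g_enc_out <- carafe_unshuffle(graw, cfg$kup^2, cfg$sigma)
  r2 <- mod_bw(mod$sub$enc, cache$enc, g_enc_out)
  grads$sub$enc <- r2$grads
  r1 <- mod_bw(mod$sub$comp, cache$comp, r2$gx)
  grads$sub$comp <- r1$grads
  list(gx = r$gx + r1$gx, grads = grads)
}
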
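# ---------------------------------------------------------------------------
# Decoupled anchor-free detection head with distribution-focal box regression.
# Per level: a box branch predicting 4*reg_max distribution logits and a
# class branch predicting nc logits; raw maps are concatenated channel-wise.
# ---------------------------------------------------------------------------

new_detect <- function(chs, nc = 1, reg_max = 16, strides = c(8, 16, 32)) {
  c2 <- max(16, chs[1] %/% 4, reg_max * 4)
  c3 <- max(chs[1], min(nc, 100))
  sub <- list()
  for (i in seq_along(chs)) {
    sub[[paste0("b1_", i)]] <- new_conv(chs[i], c2, 3)
    sub[[paste0("b2_", i)]] <- new_conv(c2, c2, 3)
    sub[[paste0("b3_", i)]] <- new_conv(c2, 4 * reg_max, 1, act = "none",
                                        norm = FALSE)
    sub[[paste0("c1_", i)]] <- new_conv(chs[i], c3, 3)
    sub[[paste0("c2_", i)]] <- new_conv(c3, c3, 3)
    sub[[paste0("c3_", i)]] <- new_conv(c3, nc, 1, act = "none", norm = FALSE)
  }
  new_module("wb_detect", sub = sub,
             cfg = list(chs = chs, nc = nc, reg_max = reg_max,
                        strides = strides, nl = length(chs)))
}

mod_fw.wb_detect <- function(mod, x, train = FALSE) {
  stopifnot(is.list(x), length(x) == mod$cfg$nl)
  levels <- list()
  caches <- list()
  for (i in seq_len(mod$cfg$nl)) {
    bn <- paste0(c("b1_", "b2_", "b3_"), i)
    cn <- paste0(c("c1_", "c2_", "c3_"), i)
    rb <- seq_fw(mod, bn, x[[i]], train)
    mod <- rb$mod
    rc <- seq_fw(mod, cn, x[[i]], train)
    mod <- rc$mod
    d <- dim(rb$y)
    y <- array(0, c(d[1], d[2] + mod$cfg$nc, d[3], d[4]))
    y[, seq_len(d[2]), , ] <- rb$y
    y[, d[2] + seq_len(mod$cfg$nc), , ] <- rc$y
    levels[[i]] <- y
    caches[[i]] <- list(box = rb$caches, cls = rc$caches, nbox = d[2])
  }
  list(y = levels, cache = caches, mod = mod)
}

mod_bw.wb_detect <- function(mod, cache, gy) {
  grads <- list(params = list(), sub = list())
  gx <- vector("list", mod$cfg$nl)
  for (i in seq_len(mod$cfg$nl)) {
    g <- gy[[i]]
    nb <- cache[[i]]$nbox
    gb <- g[, seq_len(nb), , , drop = FALSE]
    gc <- g[, nb + seq_len(mod$cfg$nc), , , drop = FALSE]
    bn <- paste0(c("b1_", "b2_", "b3_"), i)
    cn <- paste0(c("c1_", "c2_", "c3_"), i)
    rb <- seq_bw(mod, bn, cache[[i]]$box, gb, grads)
    grads <- rb$grads
    rc <- seq_bw(mod, cn, cache[[i]]$cls, gc, grads)
    grads <- rc$grads
    gx[[i]] <- rb$gx + rc$gx
  }
  list(gx = gx, grads = grads)
}

# prior-aware bias initialisation of the head output convolutions: the box
# distribution starts near 1 and the class logit near the expected object
# frequency, which stabilises the first optimisation steps
init_head_bias <- function(model) {
  det <- model$nodes[[model$detect_idx]]$mod
  nc <- det$cfg$nc
  sz <- model$cfg$input_size
  for (i in seq_len(det$cfg$nl)) {
    det$sub[[paste0("b3_", i)]]$params$b[] <- 1.0
    s <- det$cfg$strides[i]
    det$sub[[paste0("c3_", i)]]$params$b[] <- log(5 / nc / (sz / s)^2)
  }
  model$nodes[[model$detect_idx]]$mod <- det
  model
}

# ---------------------------------------------------------------------------
# decoding raw maps to boxes
# ---------------------------------------------------------------------------

# distribution-focal expectation.  box_raw [N, 4*reg_max, H, W] with the bin
# index varying fastest within each side's channel block.  Returns the
# expectation [N, 4, A] (A = H*W anchors, row index varying fastest) and the
# softmax probabilities as a reg_max x (N*4*A) matrix for reuse in backward.
dfl_expect <- function(box_raw, reg_max) {
  d <- dim(box_raw)
  A <- d[3] * d[4]
  a <- array(box_raw, c(d[1], reg_max, 4, A))
  am <- matrix(aperm(a, c(2, 1, 3, 4)), nrow = reg_max)
  cm <- am[1, ]
  for (r in seq_len(reg_max)[-1]) cm <- pmax(cm, am[r, ])
  e <- exp(am - rep(cm, each = reg_max))
  s <- colSums(e)
  p <- e / rep(s, each = reg_max)
  ex <- colSums(p * (0:(reg_max - 1)))
  list(expect = array(ex, c(d[1], 4, A)), p = p)
}

# anchor centre coordinates (pixel units) for a level
anchor_points <- function(h, w, stride) {
  gx <- (rep(seq_len(w), each = h) - 0.5) * stride
  gy <- (rep(seq_len(h), times = w) - 0.5) * stride
  cbind(gx, gy)   # column-major anchor order matches array flattening h fastest
}

# decode one sample's raw levels into pixel boxes [A_total, 4] and per-class
# sigmoid scores [A_total, nc]
decode_raw <- function(levels, strides, reg_max, nc, n = 1) {
  boxes <- NULL
  scores <- NULL
  for (l in seq_along(levels)) {
    y <- levels[[l]]
    d <- dim(y)
    br <- y[n, seq_len(4 * reg_max), , , drop = FALSE]
    dim(br) <- c(1, 4 * reg_max, d[3], d[4])
    cl <- y[n, 4 * reg_max + seq_len(nc), , , drop = FALSE]
    dim(cl) <- c(1, nc, d[3], d[4])
    ex <- dfl_expect(br, reg_max)$expect[1, , ]   # [4, A]
    if (is.null(dim(ex))) ex <- matrix(ex, nrow = 4)
    ap <- anchor_points(d[3], d[4], strides[l])
    x1 <- ap[, 1] - ex[1, ] * strides[l]
    y1 <- ap[, 2] - ex[2, ] * strides[l]
    x2 <- ap[, 1] + ex[3, ] * strides[l]
    y2 <- ap[, 2] + ex[4, ] * strides[l]
    cl2 <- matrix(aperm(cl, c(3, 4, 2, 1)), ncol = nc)  # [A, nc], h fastest
    sc <- 1 / (1 + exp(-cl2))
    boxes <- rbind(boxes, cbind(x1, y1, x2, y2))
    scores <- rbind(scores, sc)
  }
  list(boxes = boxes, scores = scores)
}
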
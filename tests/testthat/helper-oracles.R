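`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles used across the suite.  These deliberately
# re-derive results with naive nested loops, never through the package's own
# computational path.

# sliding-window extraction oracle for the receptive-field expansion
oracle_rf_expand <- function(x, k, stride, pad) {
  d <- dim(x)
  ho <- (d[3] + 2 * pad - k) %/% stride + 1
  wo <- (d[4] + 2 * pad - k) %/% stride + 1
  y <- array(0, c(d[1], d[2] * k * k, ho, wo))
  for (n in seq_len(d[1]))
    for (cc in seq_len(d[2]))
      for (i in 0:(k - 1))
        for (j in 0:(k - 1)) {
          u <- cc + d[2] * (i + k * j)
          for (a in seq_len(ho))
            for (b in seq_len(wo)) {
              hi <- (a - 1) * stride - pad + i + 1
              wi <- (b - 1) * stride - pad + j + 1
              v <- if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
                x[n, cc, hi, wi] else 0
              y[n, u, a, b] <- v
            }
        }
  y
}

# direct evaluation of the content-aware reassembly sum
oracle_carafe <- function(x, kern, sigma, kup) {
  d <- dim(x)
  r <- (kup - 1) %/% 2
  y <- array(0, c(d[1], d[2], sigma * d[3], sigma * d[4]))
  for (n in seq_len(d[1]))
    for (cc in seq_len(d[2]))
      for (ho in seq_len(sigma * d[3]))
        for (wo in seq_len(sigma * d[4])) {
          hc <- (ho - 1) %/% sigma + 1
          wc <- (wo - 1) %/% sigma + 1
          acc <- 0
          for (di in -r:r)
            for (dj in -r:r) {
              hi <- hc + di; wi <- wc + dj
              if (hi < 1 || hi > d[3] || wi < 1 || wi > d[4]) next
              t <- (di + r) + kup * (dj + r) + 1
              acc <- acc + kern[n, t, ho, wo] * x[n, cc, hi, wi]
            }
          y[n, cc, ho, wo] <- acc
        }
  y
}

# naive 2-D depth-wise convolution (same channel count, zero padding)
oracle_dw_conv2d <- function(x, kernels, pad_h, pad_w, dil = 1) {
  d <- dim(x)
  kh <- dim(kernels)[1]; kw <- dim(kernels)[2]
  y <- array(0, d)
  for (n in seq_len(d[1]))
    for (cc in seq_len(d[2]))
      for (h in seq_len(d[3]))
        for (w in seq_len(d[4])) {
          acc <- 0
          for (i in seq_len(kh))
            for (j in seq_len(kw)) {
              hi <- h + (i - 1 - (kh - 1) / 2) * dil
              wi <- w + (j - 1 - (kw - 1) / 2) * dil
              if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
                acc <- acc + kernels[i, j, cc] * x[n, cc, hi, wi]
            }
          y[n, cc, h, w] <- acc
        }
  y
}

# independent greedy matcher (same rule, separate code path)
oracle_match <- function(boxes, scores, gts, thresh) {
  ord <- order(-scores)
  used <- logical(nrow(gts))
  tp <- 0
  flags <- logical(length(scores))
  one_iou <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  for (i in ord) {
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gts))) {
      if (used[j]) next
      v <- one_iou(boxes[i, ], gts[j, ])
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= thresh) {
      used[bj] <- TRUE
      flags[i] <- TRUE
      tp <- tp + 1
    }
  }
  list(TP = tp, FP = length(scores) - tp, FN = nrow(gts) - tp, flags = flags)
}

# 101-point AP from explicit (score, is_tp) pairs and a ground-truth count
oracle_ap <- function(scores, is_tp, ngt) {
  ord <- order(-scores)
  tp <- cumsum(is_tp[ord])
  fp <- cumsum(!is_tp[ord])
  rec <- tp / ngt
  prec <- tp / (tp + fp)
  prec <- rev(cummax(rev(prec)))
  vals <- sapply(seq(0, 1, 0.01), function(r) {
    sel <- rec >= r
    if (!any(sel)) 0 else max(prec[sel])
  })
  mean(vals)
}

# analytic parameter census from module configuration alone (independent of
# the stored arrays)
audit_params <- function(mod) {
  own <- if (inherits(mod, "wb_conv")) {
    cfg <- mod$cfg
    cfg$kh * cfg$kw * (cfg$c1 / cfg$groups) * cfg$c2 +
      (if (cfg$bias) cfg$c2 else 0)
  } else 0
  own + sum(vapply(mod$sub, audit_params, 0))
}

audit_model <- function(model)
  sum(vapply(model$nodes, function(nd) audit_params(nd$mod), 0))

# deterministic tiny random feature map
rand_fm <- function(n, c, h, w, seed = 1) {
  set.seed(seed)
  array(rnorm(n * c * h * w), c(n, c, h, w))
}
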
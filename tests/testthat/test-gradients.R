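# Finite-difference verification of the hand-derived backward passes.

fd_check <- function(blk, x, train = FALSE, n_x = 4, n_p = 4, eps = 1e-5,
                     tol = 1e-6) {
  fw <- mod_fw(blk, x, train)
  gy <- array(rnorm(length(fw$y)), dim(fw$y))
  bw <- mod_bw(blk, fw$cache, gy)
  for (i in sample(length(x), n_x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (sum(mod_fw(blk, xp, train)$y * gy) -
              sum(mod_fw(blk, xm, train)$y * gy)) / (2 * eps)
    expect_equal(bw$gx[i], num, tolerance = tol)
  }
  fl <- wetbird:::flatten_params(blk)
  gfl <- wetbird:::flatten_grads(bw$grads)
  keys <- sample(names(fl), min(n_p, length(fl)))
  for (k in keys) {
    i <- sample(length(fl[[k]]), 1)
    evalp <- function(s) {
      b2 <- wetbird:::map_params(blk, bw$grads, function(p, g, key) {
        if (key == k) p[i] <- p[i] + s
        p
      })
      sum(mod_fw(b2, x, train)$y * gy)
    }
    num <- (evalp(eps) - evalp(-eps)) / (2 * eps)
    expect_equal(gfl[[k]][i], num, tolerance = tol)
  }
  invisible(TRUE)
}

test_that("every block's backward matches finite differences", {
  set.seed(30)
  x <- rand_fm(2, 6, 8, 8, 31)
  fd_check(new_conv(6, 8, 3, stride = 2), x)
  fd_check(new_conv(6, 12, 3, groups = 3, dilation = 2), x)
  fd_check(new_conv(6, 8, 1, act = "sigmoid", norm = FALSE), x)
  fd_check(new_rfca_conv(6, 5), x)
  fd_check(new_c2f(6, 6, 2, rfca = TRUE), x)
  fd_check(new_c2f(6, 6, 1, shortcut = TRUE), x)
  fd_check(new_lska(6, 7, 2), x)
  fd_check(new_sppf(6, 6, 5, lska = TRUE), x)
  fd_check(new_carafe(6, cm = 4), x)
})

test_that("batch-statistics mode backward is also exact", {
  set.seed(32)
  x <- rand_fm(3, 4, 6, 6, 33)
  fd_check(new_conv(4, 6, 3), x, train = TRUE, tol = 1e-5)
  fd_check(new_rfca_conv(4, 4), x, train = TRUE, tol = 1e-5)
})

test_that("CIoU gradient matches finite differences", {
  set.seed(34)
  for (trial in 1:20) {
    p <- matrix(c(0, 0, 0, 0) + runif(4, 0, 4) + c(0, 0, 4, 4), nrow = 1)
    t <- matrix(runif(4, 0, 4) + c(0, 0, 4, 4), nrow = 1)
    tm <- wetbird:::ciou_terms(p, t)
    g <- wetbird:::ciou_grad(p, t, tm)
    for (k in 1:4) {
      eps <- 1e-6
      pp <- p; pp[k] <- pp[k] + eps
      pm <- p; pm[k] <- pm[k] - eps
      f <- function(q) {
        tmq <- wetbird:::ciou_terms(q, t)
        # alpha is detached in the analytic gradient; freeze it here too
        1 - (tmq$iou - tmq$rho2 / tmq$c2 - tm$alpha * tmq$v)
      }
      num <- (f(pp) - f(pm)) / (2 * eps)
      expect_equal(g[1, k], num, tolerance = 1e-4)
    }
  }
})

test_that("the detection loss gradient propagates through the raw maps", {
  set.seed(36)
  cfg <- model_config(width_multiple = 0.0625, bifpn_width = 8,
                      input_size = 64)
  m <- build_model(cfg)
  x <- rand_fm(1, 3, 64, 64, 37)
  fw <- model_forward(m, x, train = TRUE)
  # one generous target: the assignment then has no multi-target conflicts,
  # so finite differences rarely cross an assignment boundary (the loss is
  # only piecewise smooth in the predictions)
  tgt <- list(data.frame(x1 = 8, y1 = 8, x2 = 50, y2 = 50, class_id = 0L))
  ls <- detection_loss(fw$levels, tgt, nc = 1)
  # the gradient treats the task-aligned assignment as a constant, so the
  # finite-difference reference evaluates the loss under the same frozen
  # assignment
  frozen <- function(levs) detection_loss(levs, tgt, nc = 1,
                                          assignments = ls$assignments)$loss
  checks <- 0
  for (l in 1:3) {
    gl <- ls$glevels[[l]]
    idx <- which(abs(gl) > 1e-5)
    if (length(idx) == 0) next
    for (i in sample(idx, min(4, length(idx)))) {
      eps <- 1e-5
      lp <- fw$levels; lp[[l]][i] <- lp[[l]][i] + eps
      lm <- fw$levels; lm[[l]][i] <- lm[[l]][i] - eps
      num <- (frozen(lp) - frozen(lm)) / (2 * eps)
      checks <- checks + 1
      expect_equal(gl[i], num, tolerance = 1e-4)
    }
  }
  expect_gte(checks, 6)
})
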
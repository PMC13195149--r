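test_that("IoU agrees with hand geometry", {
  expect_equal(iou(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(iou(c(0, 0, 1, 1), c(5, 5, 6, 6)), 0)
  expect_equal(iou(c(0, 0, 1, 1), c(0.5, 0, 1.5, 1)), 1 / 3)
  expect_error(iou(c(0, 0, 0, 1), c(0, 0, 1, 1)), "degenerate")
})

test_that("greedy matching handles the canonical cases and the oracle", {
  gts <- matrix(c(0, 0, 10, 10, 20, 20, 30, 30), 2, 4, byrow = TRUE)
  dets <- data.frame(x1 = c(0, 20), y1 = c(0, 20), x2 = c(10, 30),
                     y2 = c(10, 30), score = c(0.9, 0.8))
  m <- match_detections(dets, gts, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN), c(2L, 0L, 0L))
  m0 <- match_detections(NULL, gts, 0.5)
  expect_equal(c(m0$TP, m0$FP, m0$FN), c(0L, 0L, 2L))
  expect_error(match_detections(dets, gts, 0), "invalid config")

  set.seed(40)
  for (trial in 1:60) {
    nd <- sample(0:6, 1)
    ng <- sample(1:4, 1)
    mk <- function(n) {
      x1 <- runif(n, 0, 20); y1 <- runif(n, 0, 20)
      cbind(x1, y1, x1 + runif(n, 2, 10), y1 + runif(n, 2, 10))
    }
    gts <- mk(ng)
    db <- mk(nd)
    sc <- runif(nd)
    dets <- if (nd > 0)
      data.frame(x1 = db[, 1], y1 = db[, 2], x2 = db[, 3], y2 = db[, 4],
                 score = sc)
    else NULL
    got <- match_detections(dets, gts, 0.4)
    want <- oracle_match(db, sc, gts, 0.4)
    expect_equal(c(got$TP, got$FP, got$FN),
                 c(want$TP, want$FP, want$FN))
  }
})

test_that("precision and recall follow their definitions", {
  expect_equal(precision(list(TP = 3, FP = 1)), 0.75)
  expect_equal(recall(list(TP = 3, FN = 1)), 0.75)
  expect_warning(p0 <- precision(list(TP = 0, FP = 0)), "undefined")
  expect_equal(p0, 0)
})

test_that("average precision: exact cases and a hand-built curve", {
  gts <- list(img1 = matrix(c(0, 0, 10, 10), 1, 4))
  perfect <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, score = 0.9,
                        image = "img1")
  expect_equal(average_precision(perfect, gts, 0.5), 1)
  junk <- data.frame(x1 = 50, y1 = 50, x2 = 60, y2 = 60, score = 0.9,
                     image = "img1")
  expect_equal(average_precision(junk, gts, 0.5), 0)
  expect_error(average_precision(perfect, list(img1 = matrix(0, 0, 4))),
               "no ground")

  # 6 detections / 4 ground truths with a constructed TP pattern
  g4 <- matrix(c(0, 0, 10, 10, 20, 0, 30, 10, 40, 0, 50, 10, 60, 0, 70, 10),
               4, 4, byrow = TRUE)
  db <- rbind(g4[1, ], c(100, 100, 110, 110), g4[2, ],
              c(120, 100, 130, 110), g4[3, ], c(140, 100, 150, 110))
  sc <- c(0.95, 0.9, 0.85, 0.8, 0.75, 0.7)
  dets <- data.frame(x1 = db[, 1], y1 = db[, 2], x2 = db[, 3], y2 = db[, 4],
                     score = sc, image = "img1")
  got <- average_precision(dets, list(img1 = g4), 0.5)
  want <- oracle_ap(sc, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE), 4)
  expect_equal(got, want, tolerance = 1e-12)
  # AP does not depend on the order of the detection list
  shuf <- dets[sample(nrow(dets)), ]
  expect_equal(average_precision(shuf, list(img1 = g4), 0.5), got)
  # appending a low-confidence zero-IoU false positive never increases AP
  worse <- rbind(dets, data.frame(x1 = 500, y1 = 500, x2 = 510, y2 = 510,
                                  score = 0.01, image = "img1"))
  expect_lte(average_precision(worse, list(img1 = g4), 0.5), got)
})

test_that("dataset-level evaluation: exact detections, shifts, class means", {
  gts <- list(a = data.frame(x1 = c(0, 30), y1 = c(0, 30), x2 = c(10, 42),
                             y2 = c(10, 42), class_id = 0L))
  dets <- data.frame(x1 = c(0, 30), y1 = c(0, 30), x2 = c(10, 42),
                     y2 = c(10, 42), score = 0.9, class_id = 0L, image = "a")
  ev <- evaluate_detections(dets, gts)
  expect_equal(ev$precision, 1)
  expect_equal(ev$recall, 1)
  expect_equal(ev$map50, 1)
  expect_equal(ev$map5095, 1)

  # boxes shifted by half their width: IoU = 1/3, passing 0.5 never, so use
  # a quarter-width shift: IoU = 0.6 -> TP at 0.5/0.55/0.6, FP above
  sh <- data.frame(x1 = c(2.5, 33), y1 = c(0, 30), x2 = c(12.5, 45),
                   y2 = c(10, 42), score = 0.9, class_id = 0L, image = "a")
  ev2 <- evaluate_detections(sh, gts)
  iou_sh <- iou(c(2.5, 0, 12.5, 10), c(0, 0, 10, 10))
  n_pass <- sum(seq(0.5, 0.95, 0.05) <= iou_sh + 1e-9)
  expect_equal(ev2$map50, 1)
  expect_equal(ev2$map5095, n_pass / 10)
  expect_gte(ev2$map50, ev2$map5095)

  # one class perfect, one class undetected -> class-mean 0.5
  gts2 <- list(a = data.frame(x1 = c(0, 30), y1 = c(0, 30), x2 = c(10, 42),
                              y2 = c(10, 42), class_id = c(0L, 1L)))
  dets2 <- data.frame(x1 = 0, y1 = 0, x2 = 10, y2 = 10, score = 0.9,
                      class_id = 0L, image = "a")
  expect_equal(evaluate_detections(dets2, gts2)$map50, 0.5)
})

test_that("map5095 never exceeds map50 on randomised instances", {
  set.seed(41)
  for (trial in 1:200) {
    ng <- sample(1:8, 1)
    x1 <- runif(ng, 0, 80); y1 <- runif(ng, 0, 80)
    g <- data.frame(x1 = x1, y1 = y1, x2 = x1 + runif(ng, 4, 15),
                    y2 = y1 + runif(ng, 4, 15), class_id = 0L)
    nd <- sample(1:8, 1)
    base <- g[sample(ng, nd, replace = TRUE), ]
    jit <- matrix(rnorm(nd * 4, 0, 2), nd, 4)
    d <- data.frame(x1 = base$x1 + jit[, 1], y1 = base$y1 + jit[, 2],
                    x2 = base$x2 + jit[, 3], y2 = base$y2 + jit[, 4],
                    score = runif(nd), class_id = 0L, image = "a")
    d <- d[d$x2 > d$x1 & d$y2 > d$y1, , drop = FALSE]
    if (nrow(d) == 0) next
    ev <- evaluate_detections(d, list(a = g))
    expect_lte(ev$map5095, ev$map50 + 1e-12)
  }
})

test_that("the FPS probe guards its arguments and times a stub", {
  set.seed(42)
  m <- build_model(model_config(width_multiple = 0.0625, bifpn_width = 8))
  expect_error(measure_fps(m, 64, n_timed = 0), "invalid config")
  fps <- measure_fps(m, 64, n_warmup = 0, n_timed = 2)
  expect_gt(fps, 0)
  # a stub with a fixed 20 ms latency clocks near 50 FPS
  stub <- function(x) Sys.sleep(0.02)
  expect_equal(measure_fps(stub, 32, n_warmup = 0, n_timed = 5), 50,
               tolerance = 0.2)
})
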
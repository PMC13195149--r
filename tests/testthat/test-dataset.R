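test_that("YOLO label files parse, validate and round-trip", {
  p <- file.path(tempdir(), "lab.txt")
  writeLines("0 0.5 0.5 0.1 0.1", p)
  lab <- read_yolo_labels(p)
  expect_equal(nrow(lab), 1)
  expect_equal(lab$cx, 0.5)
  expect_equal(lab$w, 0.1)

  writeLines("0 1.2 0.5 0.1 0.1", p)
  expect_error(read_yolo_labels(p), "line 1")
  writeLines("0 a 0.5 0.1 0.1", p)
  expect_error(read_yolo_labels(p), "non-numeric")
  writeLines(character(0), p)
  expect_equal(nrow(read_yolo_labels(p)), 0)

  set.seed(50)
  n <- 50
  w <- runif(n, 0.01, 0.2); h <- runif(n, 0.01, 0.2)
  labs <- data.frame(class_id = sample(0:3, n, TRUE),
                     cx = runif(n, 0.2, 0.8), cy = runif(n, 0.2, 0.8),
                     w = w, h = h)
  write_yolo_labels(labs, p)
  back <- read_yolo_labels(p)
  expect_equal(as.matrix(back[, 2:5]), as.matrix(labs[, 2:5]),
               tolerance = 1e-6)
  expect_equal(back$class_id, labs$class_id)
})

test_that("splitting follows the rounding rule, disjointness and the seed", {
  s <- as.list(seq_len(2000))
  sp <- split_dataset(s, c(0.7, 0.2, 0.1), seed = 3)
  expect_equal(lengths(list(sp$train, sp$val, sp$test)), c(1400, 400, 200))
  ids <- c(unlist(sp$train), unlist(sp$val), unlist(sp$test))
  expect_equal(sort(ids), 1:2000)

  sp10 <- split_dataset(as.list(1:10), seed = 1)
  expect_equal(lengths(list(sp10$train, sp10$val, sp10$test)), c(7, 2, 1))

  sp_a <- split_dataset(s, seed = 11)
  sp_b <- split_dataset(s, seed = 11)
  expect_identical(sp_a, sp_b)
  expect_error(split_dataset(list()), "empty")
  expect_error(split_dataset(s, c(0.5, 0.2, 0.1)), "sum to 1")
})

test_that("rotation maps boxes by the corner-rotation construction", {
  set.seed(51)
  img <- array(sample(0:255, 64 * 64 * 3, TRUE), c(64, 64, 3))
  lab <- yolo_label(0, 0.5, 0.5, 0.25, 0.25)
  smp <- image_sample(img, lab, "t")
  expect_identical(rotate_with_boxes(smp, 0), smp)
  # a centred square on a square canvas is invariant under 45-degree turns
  r45 <- rotate_with_boxes(smp, 45)
  expect_equal(r45$labels$cx, 0.5, tolerance = 1e-9)
  expect_equal(r45$labels$cy, 0.5, tolerance = 1e-9)
  expect_error(rotate_with_boxes(smp, 50), "invalid config")

  # oracle: rotate the four corners explicitly with the 2-D rotation matrix
  ang <- 15
  labs <- data.frame(class_id = 0L, cx = c(0.4, 0.6), cy = c(0.35, 0.7),
                     w = c(0.1, 0.14), h = c(0.12, 0.08))
  smp2 <- image_sample(img, labs, "t2")
  got <- rotate_with_boxes(smp2, ang)$labels
  th <- ang * pi / 180
  ctr <- 64 / 2
  for (i in 1:2) {
    px <- c(labs$cx[i] - labs$w[i] / 2, labs$cx[i] + labs$w[i] / 2) * 64
    py <- c(labs$cy[i] - labs$h[i] / 2, labs$cy[i] + labs$h[i] / 2) * 64
    xs <- c(px[1], px[2], px[1], px[2]) - ctr
    ys <- c(py[1], py[1], py[2], py[2]) - ctr
    rx <- cos(th) * xs - sin(th) * ys + ctr
    ry <- sin(th) * xs + cos(th) * ys + ctr
    expect_equal(got$cx[i], mean(range(rx)) / 64, tolerance = 1e-6)
    expect_equal(got$cy[i], mean(range(ry)) / 64, tolerance = 1e-6)
    expect_equal(got$w[i], diff(range(rx)) / 64, tolerance = 1e-6)
  }
})

test_that("noise injections match their stated distributions", {
  set.seed(52)
  flat <- array(128L, c(100, 100, 3))
  g <- add_gaussian_noise(flat, 10)
  expect_true(all(g >= 0 & g <= 255))
  expect_equal(sd(as.numeric(g - 128)), 10, tolerance = 0.1)

  sp <- add_salt_pepper(flat, 0.01)
  flipped <- sum(sp[, , 1] != 128L)
  # binomial(10000, 0.01): 99% interval approximately [75, 127]
  expect_gte(flipped, 70)
  expect_lte(flipped, 135)
  expect_true(all(sp[sp != 128L] %in% c(0L, 255L)))

  expect_identical(adjust_brightness(flat, 1.0), flat)
  expect_error(add_gaussian_noise(flat, -1), "invalid config")
  expect_error(add_salt_pepper(flat, 2), "invalid config")
  expect_error(adjust_brightness(flat, 0), "invalid config")
})

test_that("offline augmentation produces exact counts and valid labels", {
  set.seed(53)
  cfg <- scene_config(image_size = 64, n_birds_range = c(1, 4), seed = 60)
  train <- generate_scenes(10, cfg)
  aug <- augment_training_set(train, augmentation_config(seed = 2))
  expect_equal(length(aug), 30)
  kinds <- vapply(aug[11:30], function(s) attr(s, "noise_kind") %||% "",
                  "", USE.NAMES = FALSE)
  expect_equal(sum(kinds == "gauss"), 10)
  expect_equal(sum(kinds == "sp"), 10)
  for (s in aug) {
    expect_true(all(s$image >= 0 & s$image <= 255))
    if (nrow(s$labels) > 0) {
      v <- as.matrix(s$labels[, 2:5])
      expect_true(all(v >= 0 & v <= 1))
    }
  }
  expect_equal(length(augment_training_set(list())), 0)
  # byte-level determinism under a fixed seed
  aug2 <- augment_training_set(train, augmentation_config(seed = 2))
  expect_identical(lapply(aug, `[[`, "image"), lapply(aug2, `[[`, "image"))
})

test_that("bounding-box statistics summarise the size distribution", {
  labs <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5,
                     w = rep(0.05, 4), h = rep(0.05, 4))
  st <- bbox_stats(labs)
  expect_equal(st$mean_area, 0.0025)
  expect_equal(st$small_fraction, 1)
  set.seed(54)
  w5 <- c(0.02, 0.05, 0.1, 0.2, 0.4)
  labs5 <- data.frame(class_id = 0L, cx = 0.5, cy = 0.5, w = w5, h = w5)
  st5 <- bbox_stats(labs5)
  expect_equal(as.numeric(st5$q_w), as.numeric(quantile(w5, c(0, .25, .5, .75, 1))))
  expect_error(bbox_stats(labs5[0, ]), "no labels")
})
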
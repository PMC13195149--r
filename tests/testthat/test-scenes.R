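test_that("scene generation: empty case, determinism, size constraint", {
  cfg0 <- scene_config(image_size = 64, n_birds_range = c(0, 0), seed = 70)
  s0 <- generate_scene(cfg0)
  expect_equal(nrow(s0$labels), 0)
  expect_equal(dim(s0$image), c(64, 64, 3))

  cfg <- scene_config(image_size = 96, seed = 71)
  a <- generate_scene(cfg, 5)
  b <- generate_scene(cfg, 5)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  expect_true(all(a$labels$w * a$labels$h < 0.10))
  expect_error(scene_config(bird_area_fraction_range = c(0.01, 0.2)),
               "below 0.10")
  expect_error(scene_config(background = "city"), "unknown background")
})

test_that("labels enclose the rendered target support to within one pixel", {
  # targets are darker than their local background by construction, so the
  # support inside each box must contain pixels well below the box border
  # median, and no immediate 2-px outer ring pixel may be part of a target
  cfg <- scene_config(image_size = 128, n_birds_range = c(3, 6),
                      occlusion_prob = 0, seed = 72,
                      contrast_delta_range = c(-90, -60))
  for (sd in c(1, 2)) {
    s <- generate_scene(cfg, sd)
    px <- wetbird:::labels_to_pixel_boxes(s$labels, 128, 128)
    lum <- apply(s$image, c(1, 2), mean)
    for (i in seq_len(nrow(px))) {
      rs <- max(1, floor(px$y1[i] + 0.5)):min(128, ceiling(px$y2[i] - 0.5))
      cs <- max(1, floor(px$x1[i] + 0.5)):min(128, ceiling(px$x2[i] - 0.5))
      inside <- lum[rs, cs]
      ring <- lum[max(1, min(rs) - 3):min(128, max(rs) + 3),
                  max(1, min(cs) - 3):min(128, max(cs) + 3)]
      # the box contains genuinely dark target pixels
      expect_lt(min(inside), median(ring) - 30)
      # every row and column of the tight box touches the support, i.e. the
      # box is minimal to within a pixel
      row_min <- apply(inside, 1, min)
      col_min <- apply(inside, 2, min)
      thr <- median(ring) - 20
      expect_lt(row_min[1], thr)
      expect_lt(row_min[length(row_min)], thr)
      expect_lt(col_min[1], thr)
      expect_lt(col_min[length(col_min)], thr)
    }
  }
})

test_that("water ripple backgrounds are non-degenerate", {
  cfg <- scene_config(image_size = 96, n_birds_range = c(0, 0),
                      background = "water_ripple", seed = 73)
  s <- generate_scene(cfg)
  expect_gt(sd(as.numeric(s$image)), 5)
})

test_that("dataset generation writes regenerable image/label pairs", {
  dir <- file.path(tempdir(), "wbds")
  unlink(dir, recursive = TRUE)
  cfg <- scene_config(image_size = 64, seed = 74)
  mp <- generate_dataset(3, cfg, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_dataset(dir)
  expect_equal(length(back), 3)
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  # any single scene regenerates bit-identically from its recorded seed
  s2 <- generate_scene(cfg, man$scene_seeds[[2]])
  expect_identical(s2$image, back[[2]]$image)
  expect_equal(as.matrix(s2$labels), as.matrix(back[[2]]$labels),
               tolerance = 2e-6)
  expect_error(generate_dataset(0, cfg, dir), "n_images")
})
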
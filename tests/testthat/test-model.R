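test_that("parameter counting matches closed forms and the audit walker", {
  set.seed(20)
  # single 3x3 conv block, 16 -> 32, with bias: 3*3*16*32 + 32
  cv <- new_conv(16, 32, 3)
  expect_equal(wetbird:::n_params(cv), 4640)
  for (fl in list(variant_flags(), variant_flags(use_rfca = TRUE),
                  variant_flags(use_bifpn_p2 = TRUE, use_carafe = TRUE))) {
    m <- build_model(model_config(flags = fl))
    expect_equal(count_parameters(m), audit_model(m))
  }
})

test_that("single-flag variants move the count in the direction reported", {
  set.seed(21)
  base <- count_parameters(build_model(model_config()))
  one <- function(...) count_parameters(build_model(
    model_config(flags = variant_flags(...))))
  expect_lt(one(use_bifpn_p2 = TRUE), base)
  expect_gt(one(use_rfca = TRUE), base)
  expect_gt(one(use_sppf_lska = TRUE), base)
  expect_gt(one(use_carafe = TRUE), base)
})

test_that("FLOP accounting follows the convolutional scaling laws", {
  set.seed(22)
  m <- build_model(model_config())
  g640 <- estimate_flops(m, 640)
  # within 5% of the reported 8.1-8.2 G band
  expect_gt(g640, 8.1 * 0.95)
  expect_lt(g640, 8.2 * 1.05)
  # halving the input side divides convolutional FLOPs by 4
  g320 <- estimate_flops(m, 320)
  expect_equal(g640 / g320, 4, tolerance = 0.01)
})

test_that("forward geometry: pyramid strides, halving, determinism", {
  set.seed(23)
  m <- build_model(model_config(width_multiple = 0.0625, bifpn_width = 8))
  x <- rand_fm(1, 3, 640, 640, 24)
  lv <- model_forward(m, x)$levels
  expect_equal(vapply(lv, function(l) dim(l)[3], 0), c(80, 40, 20))
  x2 <- rand_fm(2, 3, 320, 320, 25)
  lv2 <- model_forward(m, x2)$levels
  expect_equal(vapply(lv2, function(l) dim(l)[3], 0), c(40, 20, 10))
  expect_equal(dim(lv2[[1]])[1], 2)
  lv2b <- model_forward(m, x2)$levels
  expect_identical(lv2, lv2b)
  expect_true(all(vapply(lv2, function(l) all(is.finite(l)), TRUE)))
  expect_error(model_forward(m, rand_fm(1, 3, 100, 100)), "divisible by 32")
})

test_that("all 16 flag combinations build, forward and backpropagate", {
  set.seed(26)
  x <- rand_fm(1, 3, 160, 160, 27)
  for (r in c(FALSE, TRUE)) for (l in c(FALSE, TRUE))
    for (b in c(FALSE, TRUE)) for (ca in c(FALSE, TRUE)) {
      cfg <- model_config(width_multiple = 0.0625, bifpn_width = 8,
                          input_size = 160,
                          flags = variant_flags(r, l, b, ca))
      m <- build_model(cfg)
      fw <- model_forward(m, x, train = TRUE)
      tgt <- list(data.frame(x1 = 40, y1 = 40, x2 = 60, y2 = 60,
                             class_id = 0L))
      ls <- detection_loss(fw$levels, tgt, nc = 1)
      expect_true(is.finite(ls$loss))
      bw <- model_backward(fw$model, fw, ls$glevels)
      flat <- unlist(lapply(bw$grads[!vapply(bw$grads, is.null, TRUE)],
                            wetbird:::flatten_grads))
      expect_true(all(is.finite(flat)))
      expect_gt(sum(abs(flat)), 0)
    }
})

test_that("checkpoints round-trip bitwise and reject mismatched flags", {
  set.seed(28)
  cfg <- model_config(width_multiple = 0.0625, bifpn_width = 8,
                      flags = variant_flags(use_carafe = TRUE))
  m <- build_model(cfg)
  p <- file.path(tempdir(), "wb_ckpt.rds")
  save_weights(m, p)
  m2 <- load_weights(p)
  expect_identical(count_parameters(m2), count_parameters(m))
  x <- rand_fm(1, 3, 64, 64, 29)
  expect_identical(model_forward(m, x)$levels, model_forward(m2, x)$levels)
  # a different variant architecture cannot absorb these weights
  expect_error(
    load_weights(p, model_config(width_multiple = 0.0625, bifpn_width = 8,
                                 flags = variant_flags(use_rfca = TRUE))),
    "mismatch")
  expect_error(load_weights(file.path(tempdir(), "absent.rds")), "not found")
})
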
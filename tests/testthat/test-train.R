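test_that("training defaults mirror the study protocol", {
  tc <- train_config()
  expect_equal(tc$epochs, 200)
  expect_equal(tc$patience, 50)
  expect_equal(tc$batch, 8)
  expect_equal(tc$lr0, 0.01)
  expect_equal(tc$lrf, 0.01)
  expect_equal(tc$momentum, 0.937)
  expect_equal(tc$weight_decay, 5e-4)
  expect_equal(tc$warmup_epochs, 3)
  expect_equal(tc$close_mosaic, 10)
  expect_identical(tc$optimizer, "SGD")
  expect_error(train_config(optimizer = "Adam"), "only SGD")
})

test_that("early stopping triggers once the metric stops improving", {
  set.seed(80)
  cfg <- model_config(width_multiple = 0.0625, bifpn_width = 8,
                      input_size = 32)
  m <- build_model(cfg)
  ds <- generate_scenes(4, scene_config(image_size = 32,
                                        n_birds_range = c(1, 2), seed = 81))
  # an untrained model scores a frozen mAP of 0, so patience=1 stops at 2
  res <- train_model(m, ds, ds,
                     train_config(epochs = 10, patience = 1, batch = 4,
                                  lr0 = 0, seed = 1),
                     verbose = FALSE)
  expect_equal(res$epochs_run, 2)
})

test_that("identical seeds give identical first-epoch losses", {
  set.seed(82)
  ds <- generate_scenes(6, scene_config(image_size = 32,
                                        n_birds_range = c(1, 2), seed = 83))
  run1 <- function() {
    set.seed(84)
    m <- build_model(model_config(width_multiple = 0.0625, bifpn_width = 8,
                                  input_size = 32))
    train_model(m, ds, ds, train_config(epochs = 1, batch = 4, seed = 9),
                verbose = FALSE)$history$loss[1]
  }
  expect_identical(run1(), run1())
  expect_error(train_model(build_model(model_config(width_multiple = 0.0625,
                                                    bifpn_width = 8)),
                           list(), list(), train_config()), "non-empty")
})

test_that("the CLI wires the pipeline commands together", {
  out <- file.path(tempdir(), "wbcli")
  unlink(out, recursive = TRUE)
  expect_error(run_cli(character(0)), "usage error")
  expect_error(run_cli(c("fly")), "unknown subcommand")
  expect_error(run_cli(c("train", "--bogus", "1")), "unknown option")

  run_cli(c("synth", "--n", "4", "--input-size", "64", "--seed", "5",
            "--out", out))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  expect_true(file.exists(file.path(out, "resolved_config.yaml")))
  expect_equal(length(read_dataset(out)), 4)

  out2 <- file.path(tempdir(), "wbcli_aug")
  unlink(out2, recursive = TRUE)
  run_cli(c("augment", "--data", out, "--out", out2, "--seed", "5"))
  expect_equal(length(read_dataset(out2)), 12)

  out3 <- file.path(tempdir(), "wbcli_prof")
  unlink(out3, recursive = TRUE)
  run_cli(c("profile", "--input-size", "64", "--out", out3))
  prof <- read.csv(file.path(out3, "profile.csv"))
  expect_equal(nrow(prof), 6)
  expect_equal(prof$params_M,
               c(3.01, 3.13, 3.27, 1.99, 3.14, 2.50))

  # the closed loop: ground-truth labels fed back as detections are perfect
  ds <- read_dataset(out)
  dets <- do.call(rbind, lapply(ds, function(s) {
    b <- wetbird:::labels_to_pixel_boxes(s$labels, 64, 64)
    if (nrow(b) == 0) return(NULL)
    data.frame(b[, 1:4], score = 0.99, class_id = 0L, image = s$id)
  }))
  truths <- lapply(ds, function(s)
    wetbird:::labels_to_pixel_boxes(s$labels, 64, 64))
  names(truths) <- vapply(ds, `[[`, "", "id")
  ev <- evaluate_detections(dets, truths)
  expect_equal(ev$map50, 1)
})
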
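# Training orchestration: protocol defaults, YAML round trip, mosaic
# geometry, determinism, and the evaluation/sweep harness.

micro_scenes <- function(n, delta = 0.6, size = 64L, seed = 300)
  generate_dataset(n, tiny_spec(delta, size), seed)

micro_cfg <- function(epochs = 2L)
  run_config("tiny", image_size = 64L, batch_size = 4L, epochs = epochs,
             mosaic_disable_last = 1L, width_mult = 0.25)

test_that("run configuration defaults match the reference training protocol", {
  cfg <- run_config("full")
  expect_identical(cfg$image_size, 640L)
  expect_identical(cfg$batch_size, 16L)
  expect_identical(cfg$optimizer, "SGD")
  expect_equal(cfg$momentum, 0.937)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_equal(cfg$initial_lr, 0.01)
  expect_identical(cfg$epochs, 300L)
  expect_identical(cfg$seed, 0L)
  expect_identical(cfg$mosaic_disable_last, 10L)
  tiny <- run_config("tiny")
  expect_identical(tiny$image_size, 160L)
  expect_equal(tiny$width_mult, 0.25)
  expect_true(is.infinite(tiny$early_stopping_patience))
})

test_that("configuration round-trips through YAML", {
  cfg <- run_config("tiny", seed = 5L, initial_lr = 0.02)
  p <- file.path(tempdir(), "cfg.yaml")
  config_to_yaml(cfg, p)
  back <- config_from_yaml(p)
  expect_equal(back, cfg)
})

test_that("mosaic composes quadrants and remaps boxes", {
  blank <- list(image = array(0, c(32, 32, 3)),
                boxes = data.frame(xmin = numeric(0), ymin = numeric(0),
                                   xmax = numeric(0), ymax = numeric(0),
                                   class = integer(0)))
  m <- mosaic_augment(rep(list(blank), 4), 32L, seed = 1)
  expect_true(all(m$image == 0))
  expect_identical(nrow(m$boxes), 0L)
  # forced centre at the midpoint: each quadrant is the matching corner crop
  set.seed(31)
  imgs <- lapply(1:4, function(i) list(image = array(runif(32 * 32 * 3), c(32, 32, 3)),
                                       boxes = blank$boxes))
  m2 <- mosaic_augment(imgs, 32L, center = c(16, 16))
  expect_identical(m2$image[1:16, 1:16, ], imgs[[1]]$image[17:32, 17:32, ])
  expect_identical(m2$image[1:16, 17:32, ], imgs[[2]]$image[17:32, 1:16, ])
  expect_identical(m2$image[17:32, 1:16, ], imgs[[3]]$image[1:16, 17:32, ])
  expect_identical(m2$image[17:32, 17:32, ], imgs[[4]]$image[1:16, 1:16, ])
  # a box fully inside a quadrant is translated rigidly
  withbox <- imgs
  withbox[[4]]$boxes <- data.frame(xmin = 2, ymin = 3, xmax = 10, ymax = 9, class = 0L)
  m3 <- mosaic_augment(withbox, 32L, center = c(16, 16))
  expect_equal(as.numeric(m3$boxes[1, 1:4]), c(2 + 16, 3 + 16, 10 + 16, 9 + 16))
  # a box mostly outside its quadrant crop is dropped
  withbox[[4]]$boxes <- data.frame(xmin = 15.9, ymin = 0, xmax = 32, ymax = 2, class = 0L)
  m4 <- mosaic_augment(withbox, 32L, center = c(31, 31))
  expect_identical(nrow(m4$boxes), 0L)
})

test_that("training is deterministic and logs the loss identity per step", {
  scenes <- micro_scenes(8)
  log1 <- file.path(tempdir(), "log1.jsonl")
  m1 <- seanet_train(scenes, micro_cfg(), log_path = log1)
  m2 <- seanet_train(scenes, micro_cfg())
  expect_identical(m1$history, m2$history)
  p1 <- predict(m1, scenes[[1]]$image)
  p2 <- predict(m2, scenes[[1]]$image)
  expect_identical(p1, p2)
  rows <- lapply(readLines(log1), jsonlite::fromJSON)
  expect_gte(length(rows), 4)
  for (r in rows)
    expect_equal(r$total, 7.5 * r$box + 0.5 * r$cls + 1.5 * r$dfl, tolerance = 1e-10)
})

test_that("the mosaic schedule is active for all but the final epochs", {
  scenes <- micro_scenes(4)
  cfg <- run_config("tiny", image_size = 64L, batch_size = 4L, epochs = 4L,
                    mosaic_disable_last = 3L, width_mult = 0.25)
  m <- seanet_train(scenes, cfg)
  expect_equal(m$history$mosaic, c(1, 0, 0, 0))
  expect_equal(sum(m$history$mosaic), cfg$epochs - cfg$mosaic_disable_last)
})

test_that("zero-epoch training returns an untrained but usable model", {
  scenes <- micro_scenes(4)
  m <- seanet_train(scenes, micro_cfg(epochs = 0L))
  expect_identical(m$trained_epochs, 0L)
  p <- predict(m, scenes[[1]]$image)
  expect_true(is.data.frame(p))
})

test_that("models survive a checkpoint round trip", {
  scenes <- micro_scenes(6)
  m <- seanet_train(scenes, micro_cfg())
  ck <- file.path(tempdir(), "ck.rds")
  save_seanet(m, ck)
  m2 <- load_seanet(ck)
  expect_identical(predict(m, scenes[[1]]$image), predict(m2, scenes[[1]]$image))
})

test_that("evaluation under zero degradation equals plain evaluation", {
  scenes <- micro_scenes(4)
  m <- seanet_train(scenes, micro_cfg(epochs = 1L))
  e1 <- seanet_evaluate(m, scenes)
  e2 <- seanet_evaluate(m, scenes)
  expect_identical(e1$ap50, e2$ap50)
  d <- seanet_evaluate(m, scenes, degradation_spec("gaussian_noise", 1), seed = 3)
  d2 <- seanet_evaluate(m, scenes, degradation_spec("gaussian_noise", 1), seed = 3)
  expect_identical(d$ap, d2$ap)
  expect_equal(d$degradation$noise_std, 10)
})

test_that("the robustness sweep covers the full 2 x 5 ladder", {
  scenes <- micro_scenes(3)
  m <- seanet_train(scenes, micro_cfg(epochs = 1L))
  sw <- robustness_sweep(m, scenes, seed = 2)
  expect_identical(nrow(sw), 10L)
  expect_identical(sort(unique(sw$severity)), 1:5)
  expect_equal(sw$noise_std[sw$kind == "gaussian_noise"], c(10, 20, 30, 40, 50))
  expect_equal(sw$blur_kernel[sw$kind == "motion_blur"], c(5L, 9L, 13L, 17L, 21L))
  csv <- file.path(tempdir(), "sweep.csv")
  robustness_sweep(m, scenes[1:2], seed = 2, csv_path = csv)
  expect_true(file.exists(csv))
})
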
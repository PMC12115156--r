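# Synthetic scene generator, degradation operators and dataset IO.

test_that("generation is bit-identical under a fixed seed", {
  spec <- tiny_spec(0.4)
  a <- generate_scene(spec, seed = 7)
  b <- generate_scene(spec, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  c <- generate_scene(spec, seed = 8)
  expect_false(identical(a$image, c$image))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_scene(tiny_spec(0.3), seed = 55)); after <- runif(3)
  expect_identical(before, after)
})

test_that("zero contrast yields a vanishing foreground/background intensity gap", {
  # pixel-paired oracle: composited luminance against the background the
  # generator rendered at the same pixels
  for (s in 12:14) {
    sc <- generate_scene(tiny_spec(0), seed = s, return_mask = TRUE)
    gap <- abs(mean(scene_lum(sc)[sc$mask]) - mean(sc$background[sc$mask]))
    expect_lt(gap, 2 / 255)
  }
})

test_that("requested contrast is realised in the rendered scene", {
  sc <- generate_scene(tiny_spec(0.3), seed = 13, return_mask = TRUE)
  gap <- mean(scene_lum(sc)[sc$mask]) - mean(sc$background[sc$mask])
  expect_gt(gap, 0.25)
  expect_lt(gap, 0.35)
})

test_that("boxes are tight around the rendered masks", {
  spec <- scene_spec(image_size = 96L, contrast_delta = 0.5,
                     n_objects = c(1L, 2L), mean_objects = 1.2)
  found <- 0
  for (s in 1:12) {
    sc <- generate_scene(spec, seed = 400 + s, return_mask = TRUE)
    if (nrow(sc$boxes) != 1) next   # the union mask is per-scene; use singletons
    found <- found + 1
    rows <- range(which(rowSums(sc$mask) > 0))
    cols <- range(which(colSums(sc$mask) > 0))
    expect_equal(sc$boxes$xmin, cols[1] - 1)
    expect_equal(sc$boxes$xmax, cols[2])
    expect_equal(sc$boxes$ymin, rows[1] - 1)
    expect_equal(sc$boxes$ymax, rows[2])
  }
  expect_gte(found, 3)
})

test_that("object counts and areas respect the configured ranges", {
  spec <- scene_spec(image_size = 128L)
  counts <- sapply(1:40, function(s) nrow(generate_scene(spec, seed = s)$boxes))
  expect_true(all(counts >= 1 & counts <= 15))
  sc <- generate_scene(spec, seed = 77)
  af <- with(sc$boxes, (xmax - xmin) * (ymax - ymin)) / 128^2
  expect_true(all(af > 0 & af < 1))
})

test_that("the degradation severity ladder matches the printed protocol", {
  expect_equal(sapply(1:5, function(s) degradation_spec("gaussian_noise", s)$noise_std),
               c(10, 20, 30, 40, 50))
  expect_equal(sapply(1:5, function(s) degradation_spec("motion_blur", s)$blur_kernel),
               c(5L, 9L, 13L, 17L, 21L))
  expect_error(degradation_spec("gaussian_noise", 6))
})

test_that("gaussian noise has the requested moments and is reproducible", {
  img <- array(0.5, c(64, 64, 3))
  expect_identical(apply_gaussian_noise(img, 0, seed = 1), img)
  n1 <- apply_gaussian_noise(img, 30, seed = 2)
  n2 <- apply_gaussian_noise(img, 30, seed = 2)
  expect_identical(n1, n2)
  expect_lt(abs(sd((n1 - img) * 255) - 30), 1)   # pre-clipping regime at mid-gray
  expect_true(all(n1 >= 0 & n1 <= 1))
})

test_that("motion blur is a normalised line kernel with replicate borders", {
  k5 <- seanet:::motion_kernel(5, 0)
  expect_equal(sum(k5), 1)
  const <- array(0.37, c(16, 16, 3))
  expect_lt(max(abs(apply_motion_blur(const, 9) - const)), 1e-12)
  expect_error(apply_motion_blur(const, 4), "odd")
  # horizontal blur of a vertical step edge equals a sliding-window oracle
  img <- array(0, c(12, 12, 3)); img[, 7:12, ] <- 1
  got <- apply_motion_blur(img, 5, 0)
  pad <- img[, c(1, 1, 1:12, 12, 12), 1]
  want <- sapply(1:12, function(x) sapply(1:12, function(y)
    sum(k5[3, ] * pad[y, x:(x + 4)])))
  expect_lt(max(abs(got[, , 1] - want)), 1e-12)
  # stronger blur never increases gradient energy
  sc <- generate_scene(tiny_spec(0.5), seed = 5)
  energy <- sapply(c(5, 9, 13, 17, 21), function(k) {
    b <- apply_motion_blur(sc$image, k)
    sum(diff(b[, , 1])^2) + sum(t(diff(t(b[, , 1])))^2)
  })
  expect_true(all(diff(energy) <= 1e-9))
})

test_that("datasets round-trip through both annotation formats", {
  scenes <- lapply(1:3, function(s) generate_scene(tiny_spec(0.5), seed = 200 + s))
  scenes[[3]]$boxes <- scenes[[3]]$boxes[0, ]   # an empty-annotation scene
  for (fmt in c("yolo", "coco")) {
    dir <- file.path(tempdir(), paste0("ds_", fmt))
    unlink(dir, recursive = TRUE)
    write_dataset(scenes, dir, fmt)
    back <- read_dataset(dir, fmt)
    expect_length(back, 3)
    for (i in 1:3) {
      expect_equal(dim(back[[i]]$image), dim(scenes[[i]]$image))
      expect_equal(nrow(back[[i]]$boxes), nrow(scenes[[i]]$boxes))
      if (nrow(scenes[[i]]$boxes)) {
        o <- order(back[[i]]$boxes$xmin)
        oo <- order(scenes[[i]]$boxes$xmin)
        size <- dim(scenes[[i]]$image)[1]
        expect_lt(max(abs(as.matrix(back[[i]]$boxes[o, 1:4]) -
                            as.matrix(scenes[[i]]$boxes[oo, 1:4])) / size), 1e-6)
        expect_identical(sort(back[[i]]$boxes$class), sort(scenes[[i]]$boxes$class))
      }
    }
  }
})
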
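# Feature pyramid: level alignment, stride arithmetic, wiring connectivity
# and the unweighted-concatenation fusion contract.

test_that("alignment handles up, down and equal-stride hops", {
  ctx <- seanet:::new_ctx()
  set.seed(11)
  up <- seanet:::new_align(ctx, 64L, 32L, 32, 16)
  y <- align_to_level(rand_fmap(1, 64, 20, 20, seed = 1), 32, 16, 32L, block = up)
  expect_identical(dim(y), c(1L, 32L, 40L, 40L))
  dn <- seanet:::new_align(ctx, 32L, 64L, 16, 32)
  y <- align_to_level(rand_fmap(1, 32, 40, 40, seed = 2), 16, 32, 64L, block = dn)
  expect_identical(dim(y), c(1L, 64L, 20L, 20L))
  eq <- seanet:::new_align(ctx, 16L, 24L, 16, 16)
  y <- align_to_level(rand_fmap(1, 16, 10, 10, seed = 3), 16, 16, 24L, block = eq)
  expect_identical(dim(y), c(1L, 24L, 10L, 10L))
  expect_error(seanet:::new_align(ctx, 8L, 8L, 32, 8), "ratio")
})

test_that("nearest-neighbour upsampling preserves constant maps exactly", {
  x <- seanet:::ag_const(array(3.25, c(1, 2, 4, 4)))
  y <- seanet:::vl(seanet:::op_upsample2(x))
  expect_identical(dim(y), c(1L, 2L, 8L, 8L))
  expect_true(all(y == 3.25))
})

test_that("pyramid outputs sit at strides 8/16/32 for divisible inputs", {
  set.seed(12)
  blk <- seanet:::new_sefpn(seanet:::new_ctx(), c(16L, 16L, 16L), 1L)
  for (s in c(64L, 96L)) {
    r <- sefpn_forward(rand_fmap(1, 16, s / 8, s / 8, seed = s),
                       rand_fmap(1, 16, s / 16, s / 16, seed = s + 1),
                       rand_fmap(1, 16, s / 32, s / 32, seed = s + 2),
                       widths = c(16L, 16L, 16L), block = blk)
    expect_identical(dim(r$d1)[3:4], as.integer(c(s / 8, s / 8)))
    expect_identical(dim(r$d2)[3:4], as.integer(c(s / 16, s / 16)))
    expect_identical(dim(r$d3)[3:4], as.integer(c(s / 32, s / 32)))
  }
  expect_error(
    sefpn_forward(rand_fmap(1, 16, 8, 8, seed = 1), rand_fmap(1, 16, 5, 5, seed = 2),
                  rand_fmap(1, 16, 2, 2, seed = 3), widths = c(16L, 16L, 16L),
                  block = blk),
    "halve")
})

test_that("standard 640-input tap sizes map to 80/40/20 outputs", {
  set.seed(13)
  blk <- seanet:::new_sefpn(seanet:::new_ctx(), c(64L, 128L, 256L), 1L)
  r <- sefpn_forward(rand_fmap(1, 64, 80, 80, seed = 4),
                     rand_fmap(1, 128, 40, 40, seed = 5),
                     rand_fmap(1, 256, 20, 20, seed = 6), block = blk)
  expect_identical(sapply(r, function(d) dim(d)[3]), c(d1 = 80L, d2 = 40L, d3 = 20L))
})

test_that("every backbone tap reaches the outputs it should (connectivity)", {
  set.seed(14)
  blk <- seanet:::new_sefpn(seanet:::new_ctx(), c(8L, 8L, 8L), 1L)
  p4 <- rand_fmap(1, 8, 8, 8, seed = 7)
  p6 <- rand_fmap(1, 8, 4, 4, seed = 8)
  p9 <- rand_fmap(1, 8, 2, 2, seed = 9)
  base <- sefpn_forward(p4, p6, p9, widths = c(8L, 8L, 8L), block = blk)
  z4 <- sefpn_forward(p4 * 0, p6, p9, widths = c(8L, 8L, 8L), block = blk)
  z9 <- sefpn_forward(p4, p6, p9 * 0, widths = c(8L, 8L, 8L), block = blk)
  for (k in c("d1", "d2", "d3")) {
    expect_gt(max(abs(z4[[k]] - base[[k]])), 0)  # P4 feeds D1 and the bottom-up chain
    expect_gt(max(abs(z9[[k]] - base[[k]])), 0)  # P9 feeds U4 -> D1 -> D2 -> D3
  }
})

test_that("fusion uses exactly four CEM nodes and no standalone fusion weights", {
  ctx <- seanet:::new_ctx()
  seanet:::new_sefpn(ctx, c(8L, 8L, 8L), 1L)
  names <- vapply(ctx$params, function(p) p$name, character(1))
  cems <- unique(sub("^(fpn\\.cem_[a-z0-9]+)\\..*$", "\\1",
                     grep("^fpn\\.cem_", names, value = TRUE)))
  expect_length(cems, 4L)
  # every parameter belongs to a CEM or an alignment block: concatenation
  # itself carries no learned weights
  expect_true(all(grepl("^fpn\\.(cem_|up|down)", names)))
})
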
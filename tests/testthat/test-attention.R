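# Fore-background contrast attention, spatial-channel attention, BottleRep
# and their assembly into the Contrast Enhancement Module.

test_that("foreground and background activation maps are exact complements", {
  set.seed(3)
  blk <- seanet:::new_fbc(seanet:::new_ctx(), 6L)
  for (i in 1:5) {
    r <- fbc_forward(rand_fmap(2, 6, 5, 5, seed = i), block = blk, trace = TRUE)
    expect_lt(max(abs(r$Ff + r$Fb - 1)), 1e-6)
    expect_true(all(r$Ff > 0 & r$Ff < 1))
    expect_true(all(r$cf > 0 & r$cf < 1 & r$cb > 0 & r$cb < 1))
  }
})

test_that("pooled vectors have shape [B, 1, C]", {
  set.seed(4)
  blk <- seanet:::new_fbc(seanet:::new_ctx(), 8L)
  r <- fbc_forward(rand_fmap(2, 8, 4, 4, seed = 11), block = blk, trace = TRUE)
  expect_identical(dim(r$vf), c(2L, 1L, 8L))
  expect_identical(dim(r$vb), c(2L, 1L, 8L))
})

test_that("fbc matches a nested-loop evaluation of its equations", {
  set.seed(5)
  for (i in 1:6) {
    C <- sample(2:4, 1)
    blk <- seanet:::new_fbc(seanet:::new_ctx(), C)
    x <- rand_fmap(sample(1:2, 1), C, sample(2:4, 1), sample(2:4, 1), seed = 100 + i)
    got <- fbc_forward(x, block = blk)
    want <- fbc_loop_oracle(x, blk)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("symmetric gates force an exactly zero output map", {
  blk <- seanet:::new_fbc(seanet:::new_ctx(), 4L)
  blk$cv$w$v[] <- 0                      # CBLR pre-activation identically 0
  blk$rho_b$w$v <- blk$rho_f$w$v         # tie the two affine maps
  blk$rho_b$b$v <- blk$rho_f$b$v
  x <- rand_fmap(2, 4, 3, 3, seed = 21)
  r <- fbc_forward(x, block = blk, trace = TRUE)
  expect_true(all(r$Ff == 0.5))
  expect_identical(r$cf, r$cb)
  expect_true(all(r$out == 0))
})

test_that("scam preserves shape and saturates to identity with large logits", {
  set.seed(6)
  blk <- seanet:::new_scam(seanet:::new_ctx(), 16L)
  x <- rand_fmap(2, 16, 8, 8, seed = 31)
  expect_identical(dim(scam_forward(x, block = blk)), dim(x))
  blk$fc2$b$v[] <- 30                    # channel gates ~ 1
  blk$sp$b$v[] <- 30                     # spatial gate ~ 1
  y <- scam_forward(x, block = blk)
  expect_lt(max(abs(y - x)), 1e-8)
})

test_that("channel gate of a constant-per-channel map equals the gate of its pooled version", {
  set.seed(7)
  blk <- seanet:::new_scam(seanet:::new_ctx(), 8L)
  vals <- rnorm(8)
  x <- aperm(array(vals, c(8, 6, 6, 1)), c(4, 1, 2, 3))
  g_full <- blk$channel_gate(x)
  g_pool <- blk$channel_gate(array(vals, c(1, 8, 1, 1)))
  expect_lt(max(abs(g_full - g_pool)), 1e-12)
})

test_that("bottlerep is a residual block with a learnable identity shortcut", {
  blk <- seanet:::new_bottlerep(seanet:::new_ctx(), 8L, 8L)
  expect_true(all(bottlerep_forward(array(0, c(1, 8, 5, 5)),
                                    block = blk, training = TRUE) == 0))
  # zero the conv path, keep the shortcut at weight 1 -> identity
  blk$c2$cv$w$v[] <- 0
  x <- rand_fmap(1, 8, 5, 5, seed = 41)
  expect_lt(max(abs(bottlerep_forward(x, block = blk) - x)), 1e-12)
})

test_that("bottlerep equals a manual step-by-step composition", {
  set.seed(8)
  blk <- seanet:::new_bottlerep(seanet:::new_ctx(), 4L, 4L)
  x <- rand_fmap(1, 4, 5, 5, seed = 51)
  silu <- function(z) z / (1 + exp(-z))
  manual_cbs <- function(layer, x) {
    y <- naive_conv(x, layer$cv$w$v, numeric(0), c(1, 1), c(1, 1), c(1, 1))
    for (cc in seq_len(dim(y)[2]))
      y[, cc, , ] <- naive_bn_eval(y[, cc, , ], layer$nm$state$rm[cc],
                                   layer$nm$state$rv[cc], layer$nm$gamma$v[cc],
                                   layer$nm$beta$v[cc])
    silu(y)
  }
  want <- manual_cbs(blk$c2, manual_cbs(blk$c1, x)) + as.numeric(blk$alpha$v) * x
  got <- bottlerep_forward(x, block = blk)
  expect_lt(max(abs(got - want)), 1e-10)
})

test_that("cem follows the declared dataflow and channel arithmetic", {
  set.seed(9)
  blk <- seanet:::new_cem(seanet:::new_ctx(), 32L, 32L, 3L, hidden = 16L)
  x <- rand_fmap(2, 32, 16, 16, seed = 61)
  r <- cem_forward(x, block = blk, trace = TRUE)
  expect_identical(r$n_mid, 4L)                 # y1 plus three BottleRep outputs
  expect_identical(r$concat_width, 4L * 16L)
  expect_identical(dim(r$out), c(2L, 32L, 16L, 16L))
})

test_that("a zero-gated fbc branch reduces y1 to CBS1(SCAM(x))", {
  set.seed(10)
  blk <- seanet:::new_cem(seanet:::new_ctx(), 8L, 8L, 3L, hidden = 4L)
  blk$fbc$cv$w$v[] <- 0
  blk$fbc$rho_b$w$v <- blk$fbc$rho_f$w$v
  blk$fbc$rho_b$b$v <- blk$fbc$rho_f$b$v
  x <- rand_fmap(1, 8, 6, 6, seed = 71)
  r <- cem_forward(x, block = blk, trace = TRUE)
  want <- seanet:::ag_no_grad(seanet:::vl(
    blk$cbs1$fwd(blk$scam$fwd(seanet:::ag_const(x), FALSE), FALSE)))
  expect_lt(max(abs(r$y1 - want)), 1e-12)
})
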
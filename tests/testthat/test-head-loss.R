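# CIoU, distribution focal loss, box decoding, task-aligned assignment and
# the composite weighted loss.

test_that("ciou reproduces hand-computable geometry", {
  expect_equal(ciou(c(0, 0, 2, 2), c(0, 0, 2, 2)), 1.0)
  # disjoint boxes, equal aspect: IoU 0, centre gap^2 16, enclosing diag^2 40
  expect_equal(ciou(c(0, 0, 2, 2), c(4, 0, 6, 2)), -0.4, tolerance = 1e-12)
  # nested, same centre, same aspect: distance and aspect terms vanish
  a <- c(0, 0, 4, 4); b <- c(1, 1, 3, 3)
  iou <- 4 / 16
  expect_equal(ciou(a, b), iou, tolerance = 1e-12)
  expect_error(ciou(c(0, 0, 0, 2), c(0, 0, 1, 1)), "degenerate")
})

test_that("ciou is bounded by IoU and lies in (-2, 1]", {
  set.seed(24)
  n <- 1000
  mk <- function() {
    x <- runif(n, 0, 50); y <- runif(n, 0, 50)
    cbind(x, y, x + runif(n, 1, 30), y + runif(n, 1, 30))
  }
  a <- mk(); b <- mk()
  ci <- ciou(a, b)
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  iou <- inter / ((a[, 3] - a[, 1]) * (a[, 4] - a[, 2]) +
                    (b[, 3] - b[, 1]) * (b[, 4] - b[, 2]) - inter)
  expect_true(all(ci <= iou + 1e-12))
  expect_true(all(ci > -2 & ci <= 1))
  # scalar-loop evaluation agrees with the vectorised implementation
  idx <- sample(n, 50)
  for (i in idx) expect_equal(ciou(a[i, ], b[i, ]), ci[i], tolerance = 1e-12)
})

test_that("distribution focal loss matches hand evaluations", {
  K <- 16
  logit_point <- rep(-1e3, K); logit_point[6] <- 1e3   # point mass at bin 5
  expect_equal(dfl_loss(logit_point, 5), 0, tolerance = 1e-9)
  expect_equal(dfl_loss(rep(0, K), 4.5), log(K), tolerance = 1e-12)
  expect_warning(out <- dfl_loss(rep(0, K), K + 2), "clamp")
  # the bracketing two-point distribution minimises the loss for t = 3.3
  t <- 3.3
  best <- -(0.7 * log(0.7) + 0.3 * log(0.3))
  cand <- list(rep(0, K),
               { z <- rep(-30, K); z[4] <- 0; z },
               { z <- rep(-30, K); z[5] <- 0; z },
               { z <- rep(-30, K); z[c(4, 5)] <- c(log(0.7), log(0.3)); z },
               { z <- rep(-30, K); z[c(4, 5)] <- c(log(0.5), log(0.5)); z })
  losses <- sapply(cand, dfl_loss, target_offset = t)
  expect_equal(min(losses), losses[4], tolerance = 1e-9)
  expect_equal(losses[4], best, tolerance = 1e-6)
})

test_that("box decoding equals a loop-based softmax-expectation oracle", {
  set.seed(25)
  K <- 8
  anch <- seanet:::anchor_grid(2, 3, 8)
  A <- nrow(anch)
  dl <- array(rnorm(A * 4 * K), c(A, 4, K))
  got <- decode_boxes(dl, anch)
  for (a in seq_len(A)) {
    off <- numeric(4)
    for (j in 1:4) {
      p <- exp(dl[a, j, ] - max(dl[a, j, ]))
      p <- p / sum(p)
      off[j] <- sum(p * (0:(K - 1))) * anch$stride[a]
    }
    want <- c(anch$cx[a] - off[1], anch$cy[a] - off[2],
              anch$cx[a] + off[3], anch$cy[a] + off[4])
    expect_equal(unname(got[a, ]), want, tolerance = 1e-10)
  }
  # point mass at bin 0 -> zero-extent box at the anchor centre
  pm <- array(-1e3, c(1, 4, K)); pm[, , 1] <- 1e3
  z <- decode_boxes(pm, anch[1, ])
  expect_equal(unname(z[1, ]), c(anch$cx[1], anch$cy[1], anch$cx[1], anch$cy[1]),
               tolerance = 1e-9)
  # point mass at bin k -> side offset exactly k * stride
  pm2 <- array(-1e3, c(1, 4, K)); pm2[, , 4] <- 1e3
  z2 <- decode_boxes(pm2, anch[1, ])
  expect_equal(unname(z2[1, 3] - anch$cx[1]), 3 * anch$stride[1], tolerance = 1e-9)
})

test_that("assignment handles empty and singleton cases", {
  anch <- seanet:::anchor_grid(4, 4, 8)
  A <- nrow(anch)
  pc <- matrix(0.5, A, 2)
  pb <- cbind(anch$cx - 4, anch$cy - 4, anch$cx + 4, anch$cy + 4)
  asg0 <- assign_targets(pb, pc, anch, NULL, integer(0))
  expect_identical(asg0$n_matched, 0L)
  expect_equal(asg0$target_scores_sum, 1)        # the floor at 1
  expect_true(all(asg0$target_scores == 0))
  gt <- matrix(c(2, 2, 14, 14), 1)
  asg1 <- assign_targets(pb, pc, anch, gt, 0L)
  expect_gt(asg1$n_matched, 0L)
  expect_true(all(asg1$matches[, "gt"] == 1L))
})

test_that("assignment agrees with exhaustive enumeration of the rule", {
  set.seed(26)
  for (i in 1:12) {
    anch <- seanet:::anchor_grid(5, 5, 8)[sample(25, sample(10:25, 1)), ]
    A <- nrow(anch)
    nc <- 2
    pc <- matrix(runif(A * nc), A, nc)
    pb <- cbind(anch$cx - runif(A, 2, 10), anch$cy - runif(A, 2, 10),
                anch$cx + runif(A, 2, 10), anch$cy + runif(A, 2, 10))
    G <- sample(1:3, 1)
    gt <- t(sapply(seq_len(G), function(g) {
      x <- runif(1, 0, 25); y <- runif(1, 0, 25)
      c(x, y, x + runif(1, 8, 20), y + runif(1, 8, 20))
    }))
    gcl <- sample(0:(nc - 1), G, replace = TRUE)
    asg <- assign_targets(pb, pc, anch, gt, gcl)
    want <- assigner_oracle(pb, pc, anch, gt, gcl)
    got <- integer(A)
    if (asg$n_matched) got[asg$matches[, "anchor"]] <- asg$matches[, "gt"]
    expect_identical(got, want)
  }
})

test_that("loss components satisfy the weighted-total identity and floors", {
  set.seed(27)
  anch <- seanet:::anchor_grid(4, 4, 8)
  A <- nrow(anch); nc <- 2; K <- 8
  cls <- matrix(rnorm(A * nc), A, nc)
  dst <- matrix(rnorm(A * 4 * K), A, 4 * K)
  gt <- matrix(c(4, 4, 20, 20, 10, 14, 30, 30), 2, byrow = TRUE)
  dl <- aperm(array(dst, c(A, K, 4)), c(1, 3, 2))
  pb <- decode_boxes(dl, anch)
  asg <- assign_targets(pb, 1 / (1 + exp(-cls)), anch, gt, c(0L, 1L))
  lb <- total_loss(cls, dst, anch, asg, gt, reg_max = K)
  expect_equal(lb$total, 7.5 * lb$box_loss + 0.5 * lb$cls_loss + 1.5 * lb$dfl_loss,
               tolerance = 1e-12)
  expect_true(all(c(lb$box_loss, lb$cls_loss, lb$dfl_loss) >= 0))
  expect_gte(lb$target_scores_sum, 1)
  # empty assignment: box and dfl vanish, classification remains
  asg0 <- assign_targets(pb, 1 / (1 + exp(-cls)), anch, NULL, integer(0))
  lb0 <- total_loss(cls, dst, anch, asg0, NULL, reg_max = K)
  expect_equal(lb0$box_loss, 0)
  expect_equal(lb0$dfl_loss, 0)
  expect_equal(lb0$target_scores_sum, 1)
  expect_gt(lb0$cls_loss, 0)
})

test_that("perfect box predictions zero the box and dfl components", {
  anch <- seanet:::anchor_grid(4, 4, 1)   # unit stride: one centre per cell
  A <- nrow(anch); nc <- 1; K <- 8
  # ground truth centred on one anchor, all side offsets exactly 1 bin; the
  # strict centre-inside rule then matches exactly that anchor
  a0 <- 6L
  gt <- matrix(c(anch$cx[a0] - 1, anch$cy[a0] - 1,
                 anch$cx[a0] + 1, anch$cy[a0] + 1), 1)
  dst <- matrix(-1e3, A, 4 * K)
  for (j in 1:4) dst[, (j - 1) * K + 2] <- 1e3   # point mass at bin 1
  cls <- matrix(5, A, nc)
  dl <- aperm(array(dst, c(A, K, 4)), c(1, 3, 2))
  pb <- decode_boxes(dl, anch)
  asg <- assign_targets(pb, 1 / (1 + exp(-cls)), anch, gt, 0L)
  expect_identical(asg$n_matched, 1L)
  lb <- total_loss(cls, dst, anch, asg, gt, reg_max = K)
  expect_lt(lb$box_loss, 1e-6)
  expect_lt(lb$dfl_loss, 1e-6)
})
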
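# Evaluation: greedy matching, 101-point interpolated AP, P/R/F1.

box_df <- function(m, class = 0L, score = NULL) {
  d <- data.frame(xmin = m[, 1], ymin = m[, 2], xmax = m[, 3], ymax = m[, 4],
                  class = class)
  if (!is.null(score)) d$score <- score
  d
}

test_that("greedy matching handles the elementary cases", {
  gt <- box_df(rbind(c(0, 0, 10, 10)))
  pr <- box_df(rbind(c(1, 1, 10, 10)), score = 0.9)
  m <- match_detections(pr, gt, 0.5)
  expect_equal(m$counts, list(tp = 1L, fp = 0L, fn = 0L))
  pr2 <- box_df(rbind(c(50, 50, 60, 60)), score = 0.9)
  gt2 <- box_df(rbind(c(0, 0, 10, 10), c(20, 20, 30, 30)))
  m2 <- match_detections(pr2, gt2, 0.5)
  expect_equal(m2$counts, list(tp = 0L, fp = 1L, fn = 2L))
})

test_that("greedy matching agrees with a loop-based oracle on random instances", {
  set.seed(19)
  for (i in 1:20) {
    ng <- sample(1:4, 1); np <- sample(1:6, 1)
    gt <- box_df(t(sapply(seq_len(ng), function(j) {
      x <- runif(1, 0, 50); y <- runif(1, 0, 50)
      c(x, y, x + runif(1, 5, 20), y + runif(1, 5, 20))
    })), class = sample(0:1, ng, replace = TRUE))
    pr <- box_df(t(sapply(seq_len(np), function(j) {
      x <- runif(1, 0, 50); y <- runif(1, 0, 50)
      c(x, y, x + runif(1, 5, 20), y + runif(1, 5, 20))
    })), class = sample(0:1, np, replace = TRUE), score = runif(np))
    thr <- sample(c(0.3, 0.5), 1)
    expect_identical(match_detections(pr, gt, thr)$flags,
                     greedy_match_oracle(pr, gt, thr))
  }
})

test_that("101-point AP reproduces hand-computable cases", {
  expect_equal(average_precision(TRUE, 0.9, 1), 1.0)
  expect_equal(average_precision(c(FALSE, FALSE), c(0.9, 0.8), 3), 0)
  # (TP, FP, TP) at scores (.9,.8,.7) with 2 gts: envelope 1 up to r=0.5,
  # then 2/3: AP = (51 + 50 * 2/3) / 101
  ap <- average_precision(c(TRUE, FALSE, TRUE), c(0.9, 0.8, 0.7), 2)
  expect_equal(ap, (51 + 50 * 2 / 3) / 101, tolerance = 1e-12)
  expect_error(average_precision(TRUE, 0.9, 0), "ground truth")
})

test_that("AP agrees with the envelope-enumeration oracle and is rank-only", {
  set.seed(20)
  for (i in 1:40) {
    n <- sample(1:20, 1)
    flags <- runif(n) < 0.5
    scores <- runif(n)
    n_gt <- max(1, sum(flags) + sample(0:3, 1))
    ap <- average_precision(flags, scores, n_gt)
    expect_equal(ap, ap_envelope_oracle(flags, scores, n_gt), tolerance = 1e-9)
    # monotone score transform leaves AP unchanged (rank-only dependence)
    expect_equal(average_precision(flags, 10 + scores^3, n_gt), ap, tolerance = 1e-12)
  }
})

test_that("per-threshold AP is non-increasing in the IoU threshold", {
  set.seed(21)
  gt <- box_df(t(sapply(1:6, function(j) {
    x <- runif(1, 0, 80); y <- runif(1, 0, 80)
    c(x, y, x + runif(1, 10, 20), y + runif(1, 10, 20))
  })))
  pr <- gt
  pr$xmin <- pr$xmin + rnorm(6, 0, 3); pr$xmax <- pr$xmax + rnorm(6, 0, 3)
  pr$ymin <- pr$ymin + rnorm(6, 0, 3); pr$ymax <- pr$ymax + rnorm(6, 0, 3)
  pr$score <- runif(6)
  aps <- sapply(seq(0.5, 0.95, 0.05), function(t) {
    m <- match_detections(pr, gt, t)
    average_precision(m$flags, pr$score, nrow(gt))
  })
  expect_true(all(diff(aps) <= 1e-12))
})

test_that("precision/recall/F1 identities hold, including degenerate cases", {
  r <- prf1(10, 0, 0)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  expect_false(r$degenerate)
  r0 <- prf1(0, 0, 0)
  expect_true(r0$degenerate)
  expect_equal(r0$f1, 0)
  # harmonic-mean bounds
  set.seed(22)
  for (i in 1:25) {
    tp <- sample(1:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    r <- prf1(tp, fp, fn)
    expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
  }
})

test_that("dataset evaluation is perfect for exact predictions", {
  set.seed(23)
  gts <- lapply(1:3, function(i) box_df(t(sapply(1:3, function(j) {
    x <- runif(1, 0, 60); y <- runif(1, 0, 60)
    c(x, y, x + 15, y + 12)
  })), class = sample(0:1, 3, replace = TRUE)))
  preds <- lapply(gts, function(g) { g$score <- 0.9; g })
  ev <- evaluate_detections(preds, gts, n_classes = 2)
  expect_equal(ev$ap, 1)
  expect_equal(ev$ap50, 1)
  expect_equal(ev$f1, 1)
  expect_s3_class(ev, "seanet_eval")
})
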
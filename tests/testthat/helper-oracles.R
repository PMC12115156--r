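# Shared independent oracles and fixture builders. All fixtures are built in
# code under fixed seeds; oracles are deliberately written as plain loops,
# independent of the package's vectorised / compiled implementations.

# naive direct convolution (cross-correlation), zero padding
naive_conv <- function(x, w, b, stride = c(1, 1), pad = c(0, 0), dil = c(1, 1)) {
  d <- dim(x); wd <- dim(w)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  O <- wd[1]; kh <- wd[3]; kw <- wd[4]
  Ho <- (H + 2 * pad[1] - ((kh - 1) * dil[1] + 1)) %/% stride[1] + 1
  Wo <- (W + 2 * pad[2] - ((kw - 1) * dil[2] + 1)) %/% stride[2] + 1
  y <- array(0, c(B, O, Ho, Wo))
  for (bb in 1:B) for (o in 1:O) for (oh in 1:Ho) for (ow in 1:Wo) {
    acc <- if (length(b)) b[o] else 0
    for (cc in 1:C) for (i in 1:kh) for (j in 1:kw) {
      h <- (oh - 1) * stride[1] - pad[1] + (i - 1) * dil[1] + 1
      wc <- (ow - 1) * stride[2] - pad[2] + (j - 1) * dil[2] + 1
      if (h >= 1 && h <= H && wc >= 1 && wc <= W)
        acc <- acc + x[bb, cc, h, wc] * w[o, cc, i, j]
    }
    y[bb, o, oh, ow] <- acc
  }
  y
}

# batch-norm in evaluation mode, by hand
naive_bn_eval <- function(x_scalar, rm, rv, gamma, beta, eps = 1e-5) {
  (x_scalar - rm) / sqrt(rv + eps) * gamma + beta
}

# nested-loop evaluation of the fore-background contrast attention using the
# block's own parameter values (evaluation-mode batch norm); no matrix algebra
fbc_loop_oracle <- function(x, block) {
  d <- dim(x)
  B <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  wc <- block$cv$w$v           # [1, C, 1, 1]
  rm <- block$nm$state$rm; rv <- block$nm$state$rv
  gam <- block$nm$gamma$v; bet <- block$nm$beta$v
  wf <- block$rho_f$w$v; bf <- block$rho_f$b$v
  wb <- block$rho_b$w$v; bb <- block$rho_b$b$v
  out <- array(0, d)
  sig <- function(z) 1 / (1 + exp(-z))
  for (b in 1:B) {
    ff <- matrix(0, H, W)
    for (h in 1:H) for (w in 1:W) {
      pre <- 0
      for (cc in 1:C) pre <- pre + wc[1, cc, 1, 1] * x[b, cc, h, w]
      z <- naive_bn_eval(pre, rm[1], rv[1], gam[1], bet[1])
      z <- if (z > 0) z else 0.1 * z
      ff[h, w] <- sig(z)
    }
    vf <- numeric(C); vb <- numeric(C)
    for (cc in 1:C) for (h in 1:H) for (w in 1:W) {
      vf[cc] <- vf[cc] + ff[h, w] * x[b, cc, h, w]
      vb[cc] <- vb[cc] + (1 - ff[h, w]) * x[b, cc, h, w]
    }
    cf <- numeric(C); cb <- numeric(C)
    for (cc in 1:C) {
      zf <- bf[cc]; zb <- bb[cc]
      for (j in 1:C) {
        zf <- zf + wf[j, cc] * vf[j]
        zb <- zb + wb[j, cc] * vb[j]
      }
      cf[cc] <- sig(zf); cb[cc] <- sig(zb)
    }
    for (cc in 1:C) out[b, cc, , ] <- x[b, cc, , ] * (cf[cc] - cb[cc])
  }
  out
}

# empirical one-axis support of the dilated-branch convolution chain: an
# impulse is pushed through k x 1, 1 x k, dilated 3x3 (rate k) and a final
# 3x3, all with all-ones kernels, and the nonzero extent is measured
conv_chain_support <- function(k, size = 63L) {
  x <- array(0, c(1, 1, size, size))
  x[1, 1, (size + 1) %/% 2, (size + 1) %/% 2] <- 1
  run <- function(x, kh, kw, dil) {
    w <- array(1, c(1, 1, kh, kw))
    pad <- c((kh - 1) * dil %/% 2, (kw - 1) * dil %/% 2)
    seanet:::conv2d_fwd_cpp(x, dim(x), w, dim(w), numeric(0),
                            c(1L, 1L), as.integer(pad), as.integer(c(dil, dil)))
  }
  y <- run(x, k, 1L, 1L)
  y <- run(y, 1L, k, 1L)
  y <- run(y, 3L, 3L, k)
  y <- run(y, 3L, 3L, 1L)
  nz_rows <- which(apply(y[1, 1, , ] != 0, 1, any))
  nz_cols <- which(apply(y[1, 1, , ] != 0, 2, any))
  c(rows = diff(range(nz_rows)) + 1L, cols = diff(range(nz_cols)) + 1L)
}

# greedy matcher oracle: straightforward loops over score-sorted detections
greedy_match_oracle <- function(preds, gts, thr) {
  flags <- logical(nrow(preds))
  for (cl in unique(preds$class)) {
    pidx <- which(preds$class == cl)
    pidx <- pidx[order(-preds$score[pidx])]
    gidx <- which(gts$class == cl)
    used <- rep(FALSE, length(gidx))
    for (p in pidx) {
      best <- 0; best_iou <- -1
      for (gi in seq_along(gidx)) {
        if (used[gi]) next
        i <- box_iou(as.matrix(preds[p, c("xmin", "ymin", "xmax", "ymax")]),
                     as.matrix(gts[gidx[gi], c("xmin", "ymin", "xmax", "ymax")]))[1, 1]
        if (i >= thr && i > best_iou) { best <- gi; best_iou <- i }
      }
      if (best > 0) { used[best] <- TRUE; flags[p] <- TRUE }
    }
  }
  flags
}

# 101-point AP by direct enumeration of the precision envelope
ap_envelope_oracle <- function(flags, scores, n_gt) {
  o <- order(-scores)
  f <- flags[o]
  n <- length(f)
  total <- 0
  for (r in seq(0, 1, by = 0.01)) {
    best <- 0
    tp <- 0
    for (i in seq_len(n)) {
      tp <- tp + f[i]
      if (tp / n_gt >= r) {
        p <- tp / i
        if (p > best) best <- p
      }
    }
    total <- total + best
  }
  total / 101
}

# exhaustive task-aligned assigner oracle following the declared rule
assigner_oracle <- function(pred_boxes, pred_cls, anchors, gt_boxes, gt_classes,
                            alpha = 0.5, beta = 6.0, topk = 10L) {
  A <- nrow(pred_cls); G <- nrow(gt_boxes)
  metric <- matrix(0, A, G); iou <- matrix(0, A, G); inside <- matrix(FALSE, A, G)
  for (a in 1:A) for (g in 1:G) {
    iou[a, g] <- box_iou(pred_boxes[a, , drop = FALSE], gt_boxes[g, , drop = FALSE])[1, 1]
    metric[a, g] <- max(pred_cls[a, gt_classes[g] + 1], 1e-9)^alpha * iou[a, g]^beta
    inside[a, g] <- anchors$cx[a] > gt_boxes[g, 1] && anchors$cx[a] < gt_boxes[g, 3] &&
      anchors$cy[a] > gt_boxes[g, 2] && anchors$cy[a] < gt_boxes[g, 4]
  }
  sel <- matrix(FALSE, A, G)
  for (g in 1:G) {
    cand <- which(inside[, g])
    if (!length(cand)) next
    ord <- cand[order(-metric[cand, g], cand)]
    sel[ord[seq_len(min(topk, length(ord)))], g] <- TRUE
  }
  assigned <- integer(A)
  for (a in 1:A) {
    gs <- which(sel[a, ])
    if (length(gs)) assigned[a] <- gs[which.max(metric[a, gs])]
  }
  assigned
}

# deterministic small feature map
rand_fmap <- function(b, c, h, w, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(b * c * h * w), c(b, c, h, w))
}

scene_lum <- function(sc)
  (sc$image[, , 1] + sc$image[, , 2] + sc$image[, , 3]) / 3

# tiny scene spec used across tests
tiny_spec <- function(delta = 0.5, size = 96L, n_classes = 3L)
  scene_spec(image_size = size, contrast_delta = delta,
             n_objects = c(1L, 6L), mean_objects = 3.5, n_classes = n_classes)
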
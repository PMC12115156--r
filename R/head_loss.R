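# Anchor-free detection head, task-aligned target assignment, and the
# composite detection loss: CIoU box loss, binary cross-entropy
# classification loss and distribution focal loss, combined as
# total = 7.5 * box + 0.5 * cls + 1.5 * dfl with the matched-score-sum
# normalisation floored at 1.

#' Complete intersection-over-union of two box sets
#'
#' `CIoU = IoU - rho^2/c^2 - alpha v`, where `rho` is the centre distance,
#' `c` the diagonal of the smallest enclosing box, `v` the squared scaled
#' arctan difference of aspect ratios and `alpha = v / (1 - IoU + v)`.
#' Always `CIoU <= IoU`, with equality for same-centre, same-aspect boxes,
#' and `CIoU = 1` iff the boxes are identical.
#'
#' @param a,b numeric matrices `[N,4]` (or length-4 vectors), rows
#'   `(xmin, ymin, xmax, ymax)`; paired row-wise.
#' @return numeric vector of CIoU values in `(-2, 1]`.
#' @export
ciou <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  stopifnot(nrow(a) == nrow(b))
  wa <- a[, 3] - a[, 1]; ha <- a[, 4] - a[, 2]
  wb <- b[, 3] - b[, 1]; hb <- b[, 4] - b[, 2]
  if (any(wa <= 0 | ha <= 0 | wb <= 0 | hb <= 0))
    stop("degenerate (zero-area) box")
  iw <- pmax(0, pmin(a[, 3], b[, 3]) - pmax(a[, 1], b[, 1]))
  ih <- pmax(0, pmin(a[, 4], b[, 4]) - pmax(a[, 2], b[, 2]))
  inter <- iw * ih
  iou <- inter / (wa * ha + wb * hb - inter)
  cw <- pmax(a[, 3], b[, 3]) - pmin(a[, 1], b[, 1])
  ch <- pmax(a[, 4], b[, 4]) - pmin(a[, 2], b[, 2])
  c2 <- cw^2 + ch^2
  rho2 <- ((a[, 1] + a[, 3]) / 2 - (b[, 1] + b[, 3]) / 2)^2 +
    ((a[, 2] + a[, 4]) / 2 - (b[, 2] + b[, 4]) / 2)^2
  v <- (4 / pi^2) * (atan(wb / hb) - atan(wa / ha))^2
  alpha <- ifelse(v > 0, v / (1 - iou + v), 0)
  iou - rho2 / c2 - alpha * v
}

#' Distribution focal loss for one box side
#'
#' The continuous target offset (in stride units) is supervised by
#' cross-entropy against the two integer bins bracketing it, linearly
#' weighted by proximity.
#'
#' @param dist_logits numeric vector (or `[N, reg_max]` matrix) of bin logits.
#' @param target_offset continuous target(s) in `[0, reg_max - 1]`; values
#'   outside are clamped with a warning.
#' @return non-negative loss value(s).
#' @export
dfl_loss <- function(dist_logits, target_offset) {
  m <- if (is.matrix(dist_logits)) dist_logits else matrix(dist_logits, nrow = 1)
  K <- ncol(m)
  if (any(target_offset < 0 | target_offset > K - 1)) {
    warning("target offset outside bin range; clamping")
    target_offset <- pmin(pmax(target_offset, 0), K - 1)
  }
  as.numeric(vl(op_dfl(ag_const(m), target_offset)))
}

# anchor grid for one level: centres at (j - 0.5) * stride, rows ordered
# (h-major then w) to match op_flatten_preds
anchor_grid <- function(h, w, stride) {
  data.frame(
    cx = rep((seq_len(w) - 0.5) * stride, times = h),
    cy = rep((seq_len(h) - 0.5) * stride, each = w),
    stride = stride
  )
}

#' Decode distribution logits into boxes
#'
#' Each side's offset is the expected bin index under the softmax of its
#' logits, scaled by the anchor stride and taken from the anchor centre.
#'
#' @param dist_logits array `[A, 4, reg_max]` (sides ordered left, top,
#'   right, bottom).
#' @param anchors data frame with `cx`, `cy`, `stride` per anchor.
#' @param image_size optional `(width, height)` to clip against.
#' @return `[A, 4]` matrix of `(xmin, ymin, xmax, ymax)`.
#' @export
decode_boxes <- function(dist_logits, anchors, image_size = NULL) {
  d <- dim(dist_logits)
  stopifnot(length(d) == 3, d[2] == 4)
  K <- d[3]
  bins <- 0:(K - 1)
  off <- sapply(1:4, function(j) {
    z <- dist_logits[, j, , drop = FALSE]
    dim(z) <- c(d[1], K)
    z <- exp(z - z[cbind(seq_len(d[1]), max.col(z, ties.method = "first"))])
    as.numeric((z / rowSums(z)) %*% bins)
  })
  off <- matrix(off, ncol = 4) * anchors$stride
  out <- cbind(anchors$cx - off[, 1], anchors$cy - off[, 2],
               anchors$cx + off[, 3], anchors$cy + off[, 4])
  if (!is.null(image_size)) {
    out[, c(1, 3)] <- pmin(pmax(out[, c(1, 3)], 0), image_size[1])
    out[, c(2, 4)] <- pmin(pmax(out[, c(2, 4)], 0), image_size[2])
  }
  colnames(out) <- c("xmin", "ymin", "xmax", "ymax")
  out
}

#' Task-aligned target assignment
#'
#' Alignment metric `m = p^alpha * IoU^beta` between each anchor's predicted
#' probability for the ground-truth class and its decoded box IoU. Anchors
#' whose centre lies inside a ground-truth box are candidates; the top-k
#' candidates per ground truth are matched, and an anchor claimed by several
#' ground truths keeps the one with the highest metric. Target scores are the
#' per-ground-truth normalised metric scaled by the best IoU; box weights
#' equal the matched target score.
#'
#' @param pred_boxes `[A,4]` decoded boxes (pixels).
#' @param pred_cls `[A, n_classes]` predicted class probabilities in (0,1).
#' @param anchors data frame with `cx`, `cy` per anchor.
#' @param gt_boxes `[G,4]` ground-truth boxes; `gt_classes` integer ids.
#' @param alpha,beta,topk assignment hyperparameters.
#' @return list with `matches` (`[N,2]`: anchor index, gt index),
#'   `target_scores` (`[A, n_classes]`), `box_weight` (`[N]`),
#'   `n_matched`, and `target_scores_sum = max(sum(target_scores), 1)`.
#' @export
assign_targets <- function(pred_boxes, pred_cls, anchors, gt_boxes, gt_classes,
                           alpha = 0.5, beta = 6.0, topk = 10L) {
  A <- nrow(pred_cls)
  nc <- ncol(pred_cls)
  ts <- matrix(0, A, nc)
  G <- if (is.null(gt_boxes)) 0L else nrow(matrix(gt_boxes, ncol = 4))
  if (G == 0L) {
    return(list(matches = matrix(integer(0), 0, 2), target_scores = ts,
                box_weight = numeric(0), n_matched = 0L, target_scores_sum = 1))
  }
  gt_boxes <- matrix(gt_boxes, ncol = 4)
  iou <- box_iou(pred_boxes, gt_boxes)                      # [A,G]
  p <- pmax(pred_cls[, gt_classes + 1, drop = FALSE], 1e-9) # [A,G]
  metric <- p^alpha * iou^beta
  inside <- outer(anchors$cx, gt_boxes[, 1], ">") & outer(anchors$cx, gt_boxes[, 3], "<") &
    outer(anchors$cy, gt_boxes[, 2], ">") & outer(anchors$cy, gt_boxes[, 4], "<")
  assigned_gt <- integer(A)      # 0 = unmatched
  assigned_metric <- numeric(A)
  for (g in seq_len(G)) {
    cand <- which(inside[, g])
    if (!length(cand)) next
    sel <- cand[order(-metric[cand, g], cand)][seq_len(min(topk, length(cand)))]
    for (a in sel) {
      if (assigned_gt[a] == 0L || metric[a, g] > assigned_metric[a]) {
        assigned_gt[a] <- g
        assigned_metric[a] <- metric[a, g]
      }
    }
  }
  matched <- which(assigned_gt > 0L)
  if (!length(matched)) {
    return(list(matches = matrix(integer(0), 0, 2), target_scores = ts,
                box_weight = numeric(0), n_matched = 0L, target_scores_sum = 1))
  }
  # normalise per ground truth: ts = m / max(m_g) * max(iou_g)
  score <- numeric(length(matched))
  for (g in unique(assigned_gt[matched])) {
    ai <- matched[assigned_gt[matched] == g]
    mmax <- max(metric[ai, g])
    imax <- max(iou[ai, g])
    s <- if (mmax > 0) metric[ai, g] / mmax * imax else rep(0, length(ai))
    score[match(ai, matched)] <- s
    ts[cbind(ai, gt_classes[g] + 1)] <- s
  }
  list(matches = cbind(anchor = matched, gt = assigned_gt[matched]),
       target_scores = ts, box_weight = score, n_matched = length(matched),
       target_scores_sum = max(sum(ts), 1))
}

# Composite loss on autograd nodes for one image.
# cls_node: [A, nc] logits; dist_node: [A, 4*K] logits (side-major blocks).
loss_nodes <- function(cls_node, dist_node, anchors, asg, gt_boxes, reg_max,
                       cls_literal = FALSE) {
  K <- reg_max
  tss <- asg$target_scores_sum
  if (cls_literal && asg$n_matched > 0) {
    rc <- cbind(asg$matches[, "anchor"],
                apply(asg$target_scores[asg$matches[, "anchor"], , drop = FALSE], 1, which.max))
    tvec <- asg$target_scores[rc]
    cls_l <- op_bce_logits(node_wrap_vec(op_gather(cls_node, rc)), tvec)
  } else {
    cls_l <- op_mulc(op_bce_logits(cls_node, asg$target_scores), 1 / tss)
  }
  if (asg$n_matched == 0) {
    return(list(box = ag_const(0), cls = cls_l, dfl = ag_const(0),
                total = op_wsum(list(ag_const(0), cls_l, ag_const(0)), c(7.5, 0.5, 1.5)),
                tss = tss))
  }
  ai <- asg$matches[, "anchor"]
  gi <- asg$matches[, "gt"]
  tb <- matrix(gt_boxes, ncol = 4)[gi, , drop = FALSE]
  cx <- anchors$cx[ai]; cy <- anchors$cy[ai]; st <- anchors$stride[ai]
  bins <- 0:(K - 1)
  side <- vector("list", 4)
  dlog <- vector("list", 4)
  for (j in 1:4) {
    dlog[[j]] <- op_rows(dist_node, ai)
    dlog[[j]] <- node_slice_cols(dlog[[j]], ((j - 1) * K + 1):(j * K))
    side[[j]] <- op_affine_const(op_matvec_const(op_softmax_rows(dlog[[j]]), bins), st)
  }
  px1 <- op_affine_const(side[[1]], -1, cx)
  py1 <- op_affine_const(side[[2]], -1, cy)
  px2 <- op_affine_const(side[[3]], 1, cx)
  py2 <- op_affine_const(side[[4]], 1, cy)
  ci <- ciou_nodes(px1, py1, px2, py2, tb)
  w <- asg$box_weight
  box_l <- op_mulc(op_sum(op_affine_const(op_rsubc(1, ci), w)), 1 / tss)
  # DFL targets: side offsets of the gt box in stride units, clamped to bins
  eps <- 0.01
  toff <- cbind((cx - tb[, 1]) / st, (cy - tb[, 2]) / st,
                (tb[, 3] - cx) / st, (tb[, 4] - cy) / st)
  toff <- pmin(pmax(toff, 0), K - 1 - eps)
  dfl_terms <- lapply(1:4, function(j) op_dfl(dlog[[j]], toff[, j]))
  dfl_per_box <- op_mulc(Reduce(op_add, dfl_terms), 0.25)
  dfl_l <- op_mulc(op_sum(op_affine_const(dfl_per_box, w)), 1 / tss)
  total <- op_wsum(list(box_l, cls_l, dfl_l), c(7.5, 0.5, 1.5))
  list(box = box_l, cls = cls_l, dfl = dfl_l, total = total, tss = tss)
}

# CIoU between predicted box nodes (per-coordinate vectors) and constant
# target boxes; alpha is treated as a constant, as is conventional.
ciou_nodes <- function(px1, py1, px2, py2, tb) {
  tx1 <- ag_const(tb[, 1]); ty1 <- ag_const(tb[, 2])
  tx2 <- ag_const(tb[, 3]); ty2 <- ag_const(tb[, 4])
  pw <- op_pmaxc(op_sub(px2, px1), 1e-6)
  ph <- op_pmaxc(op_sub(py2, py1), 1e-6)
  tw <- tb[, 3] - tb[, 1]; th <- tb[, 4] - tb[, 2]
  iw <- op_pmaxc(op_sub(op_pmin(px2, tx2), op_pmax(px1, tx1)), 0)
  ih <- op_pmaxc(op_sub(op_pmin(py2, ty2), op_pmax(py1, ty1)), 0)
  inter <- op_mul(iw, ih)
  uni <- op_addc(op_sub(op_add(op_mul(pw, ph), ag_const(tw * th)), inter), 1e-9)
  iou <- op_div(inter, uni)
  cw <- op_sub(op_pmax(px2, tx2), op_pmin(px1, tx1))
  chh <- op_sub(op_pmax(py2, ty2), op_pmin(py1, ty1))
  c2 <- op_addc(op_add(op_square(cw), op_square(chh)), 1e-9)
  pcx <- op_mulc(op_add(px1, px2), 0.5)
  pcy <- op_mulc(op_add(py1, py2), 0.5)
  rho2 <- op_add(op_square(op_affine_const(pcx, 1, -(tb[, 1] + tb[, 3]) / 2)),
                 op_square(op_affine_const(pcy, 1, -(tb[, 2] + tb[, 4]) / 2)))
  dv <- op_affine_const(op_atan(op_div(pw, ph)), -2 / pi, atan(tw / th) * 2 / pi)
  v <- op_square(dv)
  # alpha detached from the graph
  alpha <- {
    vv <- vl(v); ii <- vl(iou)
    ifelse(vv > 0, vv / (1 - ii + vv), 0)
  }
  op_sub(op_sub(iou, op_div(rho2, c2)), op_affine_const(v, alpha))
}

# slice matrix-node columns
node_slice_cols <- function(x, cols) {
  node_new(x$v[, cols, drop = FALSE], list(x), function(n) {
    d2 <- dim(n$ps[[1]]$v)
    gx <- matrix(0, d2[1], d2[2])
    gx[, get("cols", environment(n$back))] <- n$g
    acc_grad(n$ps[[1]], gx)
  })
}

# wrap a vector node as a 1-column view for ops expecting matrices
node_wrap_vec <- function(x) x

#' Composite detection loss for one image
#'
#' Computes the box (CIoU), classification (BCE) and distribution focal
#' components and their weighted total
#' `7.5 * box + 0.5 * cls + 1.5 * dfl`, normalising box and DFL (and, in the
#' default mode, BCE) by the matched target-score sum floored at 1.
#'
#' @param cls_logits `[A, n_classes]` classification logits.
#' @param dist_logits `[A, 4*reg_max]` box-distribution logits.
#' @param anchors data frame with `cx`, `cy`, `stride`.
#' @param assignment result of [assign_targets()].
#' @param gt_boxes `[G,4]` ground-truth boxes.
#' @param reg_max number of distribution bins per side.
#' @param cls_literal if `TRUE`, the classification term is the plain
#'   unnormalised sum over matched boxes.
#' @return list with `box_loss`, `cls_loss`, `dfl_loss`, `total`,
#'   `target_scores_sum`.
#' @export
total_loss <- function(cls_logits, dist_logits, anchors, assignment, gt_boxes,
                       reg_max = 16L, cls_literal = FALSE) {
  r <- ag_no_grad(loss_nodes(ag_const(cls_logits), ag_const(dist_logits),
                             anchors, assignment, gt_boxes, reg_max, cls_literal))
  list(box_loss = as.numeric(vl(r$box)), cls_loss = as.numeric(vl(r$cls)),
       dfl_loss = as.numeric(vl(r$dfl)), total = as.numeric(vl(r$total)),
       target_scores_sum = r$tss)
}

# greedy non-maximum suppression; returns kept indices
nms <- function(boxes, scores, iou_threshold = 0.7) {
  if (nrow(boxes) == 0) return(integer(0))
  o <- order(-scores)
  keep <- integer(0)
  while (length(o)) {
    i <- o[1]
    keep <- c(keep, i)
    if (length(o) == 1) break
    ious <- box_iou(boxes[i, , drop = FALSE], boxes[o[-1], , drop = FALSE])
    o <- o[-1][ious[1, ] < iou_threshold]
  }
  keep
}
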
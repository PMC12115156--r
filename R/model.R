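# Full detector: backbone (with the detail-amplification block), semantic
# enhancement pyramid, and the anchor-free decoupled head.

#' Construct an untrained detector
#'
#' @param n_classes number of object classes.
#' @param width_mult width multiplier applied to all stage widths (1 = full
#'   model, 0.25 = the tiny CPU profile).
#' @param stage_widths backbone stage widths before scaling.
#' @param cem_repeats BottleRep repetitions inside each Contrast Enhancement
#'   Module.
#' @param reg_max number of distribution-focal-loss bins per box side.
#' @param use_mdam include the multi-scale detail amplification block
#'   (ablation switch).
#' @param seed seed for weight initialisation.
#' @return an object of class `seanet_model`.
#' @export
seanet_model <- function(n_classes = 3L, width_mult = 1,
                         stage_widths = c(32L, 64L, 64L, 128L, 256L),
                         cem_repeats = 3L, reg_max = 16L, use_mdam = TRUE,
                         seed = 0L) {
  with_seed(as.integer(seed), {
    ctx <- new_ctx()
    bcfg <- backbone_config(stage_widths, width_mult = width_mult,
                            use_mdam = use_mdam)
    bb <- new_backbone(ctx, bcfg)
    w <- bb$tap_widths
    fpn <- new_sefpn(ctx, w, cem_repeats)
    heads <- lapply(seq_along(w), function(l) {
      # decoupled branches: each task gets its own 3x3 stem
      cstem <- cbs_bn(ctx, w[l], w[l], 3L, name = sprintf("head%d.cstem", l))
      rstem <- cbs_bn(ctx, w[l], w[l], 3L, name = sprintf("head%d.rstem", l))
      cls <- conv_layer(ctx, w[l], n_classes, 1L, name = sprintf("head%d.cls", l))
      reg <- conv_layer(ctx, w[l], 4L * reg_max, 1L, name = sprintf("head%d.reg", l))
      cls$b$v[] <- log(0.01 / 0.99)  # rare-positive prior for stable warmup
      list(cstem = cstem, rstem = rstem, cls = cls, reg = reg)
    })
    m <- list(ctx = ctx, backbone = bb, fpn = fpn, heads = heads,
              n_classes = as.integer(n_classes), reg_max = as.integer(reg_max),
              strides = c(8L, 16L, 32L), width_mult = width_mult,
              history = NULL, trained_epochs = 0L)
    class(m) <- "seanet_model"
    m
  })
}

# raw forward: returns per-level cls/dist nodes [B, C, H, W]
model_forward_nodes <- function(model, x, training = TRUE) {
  taps <- model$backbone$fwd(x, training)
  py <- model$fpn$fwd(taps$p4, taps$p6, taps$p9, training)
  feats <- list(py$d1, py$d2, py$d3)
  lapply(seq_along(feats), function(l) {
    h <- model$heads[[l]]
    list(cls = h$cls$fwd(h$cstem$fwd(feats[[l]], training), training),
         reg = h$reg$fwd(h$rstem$fwd(feats[[l]], training), training),
         hw = dim(vl(feats[[l]]))[3:4])
  })
}

# anchors for an input of the given size
model_anchors <- function(model, image_size) {
  do.call(rbind, lapply(model$strides, function(s)
    anchor_grid(image_size %/% s, image_size %/% s, s)))
}

# convert a [H,W,3] image (or list of them) into a [B,3,H,W] input batch
images_to_batch <- function(images) {
  if (!is.list(images)) images <- list(images)
  d <- dim(images[[1]])
  x <- array(0, c(length(images), 3L, d[1], d[2]))
  for (i in seq_along(images)) x[i, , , ] <- aperm(images[[i]], c(3, 1, 2))
  x
}

# flatten per-level head outputs into per-image [A, .] matrices (values)
flatten_levels <- function(levels, b, B) {
  cls <- list(); dst <- list()
  for (lv in levels) {
    hw <- prod(lv$hw)
    idx <- (b - 1L) * hw + seq_len(hw)
    cls[[length(cls) + 1L]] <- op_rows(lv$cls_flat, idx)
    dst[[length(dst) + 1L]] <- op_rows(lv$reg_flat, idx)
  }
  list(cls = op_vcat(cls), dst = op_vcat(dst))
}

# forward + batch loss; returns scalar nodes and the numeric breakdown
model_loss <- function(model, images, gt_list, training = TRUE,
                       cls_literal = FALSE) {
  x <- ag_const(images_to_batch(images))
  B <- dim(vl(x))[1]
  img_size <- dim(vl(x))[3]
  levels <- model_forward_nodes(model, x, training)
  for (l in seq_along(levels)) {
    levels[[l]]$cls_flat <- op_flatten_preds(levels[[l]]$cls)
    levels[[l]]$reg_flat <- op_flatten_preds(levels[[l]]$reg)
  }
  anchors1 <- model_anchors(model, img_size)
  A <- nrow(anchors1)
  K <- model$reg_max
  per_img <- lapply(seq_len(B), function(b) flatten_levels(levels, b, B))
  big_cls <- op_vcat(lapply(per_img, `[[`, "cls"))
  big_dst <- op_vcat(lapply(per_img, `[[`, "dst"))
  anchors <- list(cx = rep(anchors1$cx, B), cy = rep(anchors1$cy, B),
                  stride = rep(anchors1$stride, B))
  # per-image assignment on detached values
  ts_all <- NULL; matches <- NULL; weights <- NULL; gt_all <- NULL
  n_gt_off <- 0L
  for (b in seq_len(B)) {
    cls_v <- vl(per_img[[b]]$cls)
    dst_v <- vl(per_img[[b]]$dst)
    dl <- array(dst_v, c(A, K, 4L))       # columns are side-major blocks
    dl <- aperm(dl, c(1, 3, 2))
    pb <- decode_boxes(dl, anchors1)
    g <- gt_list[[b]]
    asg <- assign_targets(pb, 1 / (1 + exp(-cls_v)), anchors1,
                          if (nrow(g)) as.matrix(g[, 1:4]) else NULL,
                          g$class)
    ts_all <- rbind(ts_all, asg$target_scores)
    if (asg$n_matched > 0) {
      matches <- rbind(matches, cbind(anchor = asg$matches[, "anchor"] + (b - 1L) * A,
                                      gt = asg$matches[, "gt"] + n_gt_off))
      weights <- c(weights, asg$box_weight)
    }
    if (nrow(g)) {
      gt_all <- rbind(gt_all, as.matrix(g[, 1:4]))
      n_gt_off <- n_gt_off + nrow(g)
    }
  }
  asg_all <- list(matches = if (is.null(matches)) matrix(integer(0), 0, 2) else matches,
                  target_scores = ts_all,
                  box_weight = if (is.null(weights)) numeric(0) else weights,
                  n_matched = if (is.null(matches)) 0L else nrow(matches),
                  target_scores_sum = max(sum(ts_all), 1))
  loss_nodes(big_cls, big_dst, anchors, asg_all, gt_all, K, cls_literal)
}

#' Run the detector on images
#'
#' @param object a trained `seanet_model`.
#' @param images one `[H,W,3]` image or a list of them; side length must be
#'   divisible by 32.
#' @param conf_threshold confidence floor applied before non-maximum
#'   suppression.
#' @param iou_threshold class-wise NMS IoU threshold.
#' @param max_det maximum detections per image.
#' @param ... unused.
#' @return a detection data frame (or list of them) with columns
#'   `xmin, ymin, xmax, ymax, class, score`.
#' @export
predict.seanet_model <- function(object, images, conf_threshold = 0.001,
                                 iou_threshold = 0.7, max_det = 300L, ...) {
  single <- !is.list(images)
  if (single) images <- list(images)
  out <- vector("list", length(images))
  img_size <- dim(images[[1]])[1]
  anchors1 <- model_anchors(object, img_size)
  A <- nrow(anchors1)
  K <- object$reg_max
  # process in small batches to bound memory
  bs <- 8L
  for (start in seq(1, length(images), by = bs)) {
    idx <- start:min(start + bs - 1L, length(images))
    r <- ag_no_grad({
      x <- ag_const(images_to_batch(images[idx]))
      levels <- model_forward_nodes(object, x, training = FALSE)
      for (l in seq_along(levels)) {
        levels[[l]]$cls_flat <- op_flatten_preds(levels[[l]]$cls)
        levels[[l]]$reg_flat <- op_flatten_preds(levels[[l]]$reg)
      }
      levels
    })
    B <- length(idx)
    for (bi in seq_len(B)) {
      cls <- NULL; dst <- NULL
      for (lv in r) {
        hw <- prod(lv$hw)
        rid <- (bi - 1L) * hw + seq_len(hw)
        cls <- rbind(cls, vl(lv$cls_flat)[rid, , drop = FALSE])
        dst <- rbind(dst, vl(lv$reg_flat)[rid, , drop = FALSE])
      }
      prob <- 1 / (1 + exp(-cls))
      score <- apply(prob, 1, max)
      cl <- max.col(prob, ties.method = "first") - 1L
      keep <- which(score >= conf_threshold)
      if (!length(keep)) {
        out[[idx[bi]]] <- data.frame(xmin = numeric(0), ymin = numeric(0),
                                     xmax = numeric(0), ymax = numeric(0),
                                     class = integer(0), score = numeric(0))
        next
      }
      dl <- array(dst[keep, , drop = FALSE], c(length(keep), K, 4L))
      dl <- aperm(dl, c(1, 3, 2))
      boxes <- decode_boxes(dl, anchors1[keep, ], c(img_size, img_size))
      kept <- integer(0)
      for (c0 in unique(cl[keep])) {
        sel <- which(cl[keep] == c0)
        kk <- nms(boxes[sel, , drop = FALSE], score[keep][sel], iou_threshold)
        kept <- c(kept, sel[kk])
      }
      kept <- kept[order(-score[keep][kept])]
      if (length(kept) > max_det) kept <- kept[seq_len(max_det)]
      ok <- (boxes[kept, 3] > boxes[kept, 1]) & (boxes[kept, 4] > boxes[kept, 2])
      kept <- kept[ok]
      out[[idx[bi]]] <- data.frame(
        xmin = boxes[kept, 1], ymin = boxes[kept, 2],
        xmax = boxes[kept, 3], ymax = boxes[kept, 4],
        class = cl[keep][kept], score = score[keep][kept])
    }
  }
  if (single) out[[1]] else out
}

#' @export
print.seanet_model <- function(x, ...) {
  cat("Semantic enhancement detector\n")
  cat(sprintf("  classes: %d   width multiplier: %.2f   parameters: %s\n",
              x$n_classes, x$width_mult,
              format(n_params(x$ctx), big.mark = ",")))
  cat(sprintf("  strides: %s   DFL bins: %d   trained epochs: %d\n",
              paste(x$strides, collapse = "/"), x$reg_max, x$trained_epochs))
  invisible(x)
}

#' @export
summary.seanet_model <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    h <- object$history
    cat(sprintf("  final losses: box %.3f  cls %.3f  dfl %.3f  total %.3f\n",
                utils::tail(h$box, 1), utils::tail(h$cls, 1),
                utils::tail(h$dfl, 1), utils::tail(h$total, 1)))
  }
  invisible(object)
}

#' Plot the training-loss history of a model
#'
#' @param x a trained `seanet_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.seanet_model <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$box, h$cls, h$dfl), type = "l", lty = 1,
                    xlab = "epoch", ylab = "loss component", ...)
  graphics::legend("topright", c("box", "cls", "dfl"), col = 1:3, lty = 1, bty = "n")
  invisible(x)
}

#' Save / load a trained detector as a weights file
#'
#' The checkpoint embeds the architecture arguments needed to rebuild the
#' model plus all parameter values and normalisation statistics.
#'
#' @param model a `seanet_model`.
#' @param path file path.
#' @return `load_seanet` returns the restored model.
#' @export
save_seanet <- function(model, path) {
  saveRDS(list(arch = list(n_classes = model$n_classes,
                           width_mult = model$width_mult,
                           reg_max = model$reg_max),
               state = ctx_state(model$ctx),
               history = model$history,
               trained_epochs = model$trained_epochs), path)
  invisible(path)
}

#' @rdname save_seanet
#' @export
load_seanet <- function(path) {
  ck <- readRDS(path)
  m <- seanet_model(n_classes = ck$arch$n_classes,
                    width_mult = ck$arch$width_mult,
                    reg_max = ck$arch$reg_max)
  ctx_restore(m$ctx, ck$state)
  m$history <- ck$history
  m$trained_epochs <- ck$trained_epochs
  m
}
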
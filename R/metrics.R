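# Detection evaluation: greedy matching, 101-point interpolated average
# precision over IoU thresholds 0.5:0.05:0.95, and precision/recall/F1.

#' Pairwise intersection-over-union of axis-aligned boxes
#'
#' Boxes are rows `(xmin, ymin, xmax, ymax)` in pixel coordinates.
#'
#' @param a,b numeric matrices `[N,4]` and `[M,4]`.
#' @return `[N,M]` IoU matrix.
#' @export
box_iou <- function(a, b) {
  a <- matrix(a, ncol = 4); b <- matrix(b, ncol = 4)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(0, n, m))
  ix <- pmax(0, outer(a[, 3], b[, 3], pmin) - outer(a[, 1], b[, 1], pmax))
  iy <- pmax(0, outer(a[, 4], b[, 4], pmin) - outer(a[, 2], b[, 2], pmax))
  inter <- ix * iy
  aa <- (a[, 3] - a[, 1]) * (a[, 4] - a[, 2])
  ab <- (b[, 3] - b[, 1]) * (b[, 4] - b[, 2])
  inter / (outer(aa, ab, "+") - inter)
}

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in order of descending score (per class); each is
#' matched one-to-one to the unmatched ground-truth box of the same class
#' with the highest IoU, provided that IoU reaches the threshold.
#'
#' @param preds data frame with columns `xmin, ymin, xmax, ymax, class, score`.
#' @param gts data frame with columns `xmin, ymin, xmax, ymax, class`.
#' @param iou_threshold matching threshold.
#' @return list with `counts` (tp, fp, fn) and `flags` (logical TP flag per
#'   detection, in the original row order of `preds`).
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  np <- nrow(preds)
  flags <- logical(np)
  tp <- 0L
  for (cl in unique(c(preds$class, gts$class))) {
    pi <- which(preds$class == cl)
    gi <- which(gts$class == cl)
    if (length(pi) == 0) next
    pi <- pi[order(-preds$score[pi])]
    used <- logical(length(gi))
    if (length(gi)) {
      iou <- box_iou(as.matrix(preds[pi, c("xmin", "ymin", "xmax", "ymax")]),
                     as.matrix(gts[gi, c("xmin", "ymin", "xmax", "ymax")]))
      for (k in seq_along(pi)) {
        cand <- which(!used & iou[k, ] >= iou_threshold)
        if (length(cand)) {
          best <- cand[which.max(iou[k, cand])]
          used[best] <- TRUE
          flags[pi[k]] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  list(counts = list(tp = tp, fp = np - tp, fn = nrow(gts) - tp), flags = flags)
}

#' 101-point interpolated average precision
#'
#' Detections are sorted by descending score; precision is replaced by its
#' running maximum to the right (the precision envelope) and sampled at 101
#' equally spaced recall levels 0, 0.01, ..., 1.
#'
#' @param flags logical vector, TRUE where the detection is a true positive.
#' @param scores detection confidences aligned with `flags`.
#' @param n_gt number of ground-truth boxes; must be positive.
#' @return average precision in `[0, 1]`.
#' @export
average_precision <- function(flags, scores, n_gt) {
  stopifnot(length(flags) == length(scores))
  if (n_gt <= 0) stop("average precision is undefined without ground truth")
  if (length(flags) == 0) return(0)
  o <- order(-scores)
  tp <- cumsum(flags[o])
  fp <- cumsum(!flags[o])
  recall <- tp / n_gt
  precision <- tp / (tp + fp)
  # envelope: max precision at recall >= r
  env <- rev(cummax(rev(precision)))
  rs <- seq(0, 1, by = 0.01)
  idx <- findInterval(rs, recall, left.open = TRUE) + 1  # first point with recall >= r
  p_at <- ifelse(idx <= length(env), env[idx], 0)
  mean(p_at)
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`. Undefined
#' quantities (zero denominators) are reported as 0 with `degenerate = TRUE`.
#'
#' @param tp,fp,fn non-negative counts.
#' @return list with `precision`, `recall`, `f1`, `degenerate`.
#' @export
prf1 <- function(tp, fp, fn) {
  degen <- (tp + fp) == 0 || (tp + fn) == 0
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, degenerate = degen)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`; accepts percentages or proportions and returns
#' the same scale.
#'
#' @param precision,recall numeric.
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

#' Evaluate detections over a dataset
#'
#' Computes COCO-style AP (mean over IoU thresholds 0.5:0.05:0.95 and over
#' classes with ground truth), AP50, AP75, per-class AP, and macro-averaged
#' precision/recall/F1 at the per-class confidence maximising F1 (IoU 0.5).
#'
#' @param preds list (one per image) of detection data frames with columns
#'   `xmin, ymin, xmax, ymax, class, score`.
#' @param gts list (one per image) of ground-truth data frames with columns
#'   `xmin, ymin, xmax, ymax, class`.
#' @param n_classes number of classes (ids `0:(n_classes-1)`).
#' @param iou_thresholds thresholds for the headline AP.
#' @return an object of class `seanet_eval`: list with `ap`, `ap50`, `ap75`,
#'   `precision`, `recall`, `f1`, `per_class_ap`, `pr_curve`.
#' @export
evaluate_detections <- function(preds, gts, n_classes,
                                iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  stopifnot(length(preds) == length(gts))
  classes <- 0:(n_classes - 1)
  n_gt_class <- vapply(classes, function(cl)
    sum(vapply(gts, function(g) sum(g$class == cl), numeric(1))), numeric(1))
  # per (class, threshold) pooled flags
  ap_mat <- matrix(NA_real_, length(classes), length(iou_thresholds))
  pr_curve <- NULL
  prf_class <- matrix(NA_real_, length(classes), 2)  # best-F1 P and R per class
  for (ti in seq_along(iou_thresholds)) {
    t <- iou_thresholds[ti]
    for (ci in seq_along(classes)) {
      cl <- classes[ci]
      if (n_gt_class[ci] == 0) next
      scores <- numeric(0); flags <- logical(0)
      for (i in seq_along(preds)) {
        p <- preds[[i]]; g <- gts[[i]]
        psel <- p[p$class == cl, , drop = FALSE]
        gsel <- g[g$class == cl, , drop = FALSE]
        if (nrow(psel) == 0) next
        m <- match_detections(psel, gsel, t)
        scores <- c(scores, psel$score)
        flags <- c(flags, m$flags)
      }
      ap_mat[ci, ti] <- average_precision(flags, scores, n_gt_class[ci])
      if (t == 0.5) {
        if (length(flags)) {
          o <- order(-scores)
          tp <- cumsum(flags[o]); fp <- cumsum(!flags[o])
          rec <- tp / n_gt_class[ci]; prec <- tp / (tp + fp)
          f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
          k <- which.max(f1)
          prf_class[ci, ] <- c(prec[k], rec[k])
          pr_curve[[as.character(cl)]] <- cbind(recall = rec, precision = prec)
        } else {
          prf_class[ci, ] <- c(0, 0)
          pr_curve[[as.character(cl)]] <- cbind(recall = 0, precision = 0)
        }
      }
    }
  }
  valid <- n_gt_class > 0
  per_class_ap <- rowMeans(ap_mat, na.rm = TRUE)
  names(per_class_ap) <- classes
  p_macro <- mean(prf_class[valid, 1])
  r_macro <- mean(prf_class[valid, 2])
  res <- list(
    ap = mean(ap_mat[valid, , drop = FALSE]),
    ap50 = mean(ap_mat[valid, which(abs(iou_thresholds - 0.5) < 1e-9), drop = FALSE]),
    ap75 = if (any(abs(iou_thresholds - 0.75) < 1e-9))
      mean(ap_mat[valid, which(abs(iou_thresholds - 0.75) < 1e-9), drop = FALSE]) else NA_real_,
    precision = p_macro, recall = r_macro,
    f1 = f1_score(p_macro, r_macro),
    per_class_ap = per_class_ap[valid],
    ap_by_threshold = stats::setNames(colMeans(ap_mat[valid, , drop = FALSE]),
                                      iou_thresholds),
    pr_curve = pr_curve,
    n_gt = sum(n_gt_class)
  )
  class(res) <- "seanet_eval"
  res
}

#' @export
print.seanet_eval <- function(x, ...) {
  cat(sprintf("Detection evaluation (%d ground-truth boxes)\n", x$n_gt))
  cat(sprintf("  AP    %.3f\n  AP50  %.3f\n  AP75  %.3f\n", x$ap, x$ap50, x$ap75))
  cat(sprintf("  P %.3f  R %.3f  F1 %.3f (macro, best-F1 operating point)\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Plot the precision-recall curves of an evaluation
#'
#' @param x a `seanet_eval` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.seanet_eval <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1), xlab = "recall",
                 ylab = "precision", main = "PR curves (IoU 0.5)", ...)
  cls <- names(x$pr_curve)
  for (i in seq_along(cls)) {
    cc <- x$pr_curve[[i]]
    graphics::lines(cc[, "recall"], cc[, "precision"], col = i, lwd = 2)
  }
  graphics::legend("bottomleft", legend = paste("class", cls),
                   col = seq_along(cls), lwd = 2, bty = "n")
  invisible(x)
}
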
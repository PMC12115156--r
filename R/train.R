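# Training and evaluation orchestration: run configuration, mosaic
# augmentation, SGD with warmup + cosine schedule, early stopping, the
# degradation robustness sweep, and JSON-lines logging.

#' Training run configuration
#'
#' Defaults follow the reference protocol: 640-pixel inputs, batch size 16,
#' SGD with momentum 0.937, weight decay 0.0005 and initial learning rate
#' 0.01, 300 epochs, seed 0, mosaic augmentation disabled for the last 10
#' epochs, early stopping on validation AP50. The `tiny` profile is a
#' first-class CPU configuration: 160-pixel inputs, width multiplier 0.25,
#' 30 epochs, early stopping off.
#'
#' @param profile `"full"` or `"tiny"`.
#' @param image_size,batch_size,epochs,seed training protocol parameters.
#' @param momentum,weight_decay,initial_lr SGD hyperparameters.
#' @param mosaic_disable_last number of final epochs without mosaic.
#' @param early_stopping_patience epochs without AP50 improvement before
#'   stopping (`Inf` disables).
#' @param n_classes,width_mult,reg_max model architecture parameters.
#' @param cls_literal use the literal unnormalised matched-box sum for the
#'   classification loss instead of the anchor-wide normalised form.
#' @param warmup_epochs linear learning-rate warmup length.
#' @param use_ema keep an exponential moving average of the weights and
#'   adopt it at the end of training (evaluation stability).
#' @return an object of class `run_config`.
#' @export
run_config <- function(profile = c("full", "tiny"),
                       image_size = NULL, batch_size = NULL, epochs = NULL,
                       seed = 0L, momentum = 0.937, weight_decay = 5e-4,
                       initial_lr = NULL, mosaic_disable_last = 10L,
                       early_stopping_patience = NULL,
                       n_classes = 3L, width_mult = NULL, reg_max = 16L,
                       cls_literal = FALSE, warmup_epochs = NULL,
                       use_ema = TRUE) {
  profile <- match.arg(profile)
  tiny <- profile == "tiny"
  cfg <- list(
    profile = profile,
    image_size = if (is.null(image_size)) (if (tiny) 160L else 640L) else as.integer(image_size),
    batch_size = if (is.null(batch_size)) (if (tiny) 8L else 16L) else as.integer(batch_size),
    epochs = if (is.null(epochs)) (if (tiny) 30L else 300L) else as.integer(epochs),
    optimizer = "SGD",
    momentum = momentum, weight_decay = weight_decay,
    initial_lr = if (is.null(initial_lr)) (if (tiny) 0.02 else 0.01) else initial_lr,
    seed = as.integer(seed),
    mosaic_disable_last = as.integer(mosaic_disable_last),
    early_stopping_patience = if (is.null(early_stopping_patience))
      (if (tiny) Inf else 50) else early_stopping_patience,
    n_classes = as.integer(n_classes),
    width_mult = if (is.null(width_mult)) (if (tiny) 0.25 else 1) else width_mult,
    reg_max = as.integer(reg_max),
    cls_literal = isTRUE(cls_literal),
    warmup_epochs = as.integer(if (is.null(warmup_epochs)) (if (tiny) 1L else 3L) else warmup_epochs),
    use_ema = isTRUE(use_ema)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file path.
#' @return `config_from_yaml` returns a `run_config`.
#' @export
config_to_yaml <- function(cfg, path) {
  x <- unclass(cfg)
  x$early_stopping_patience <-
    if (is.infinite(x$early_stopping_patience)) -1 else x$early_stopping_patience
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname config_to_yaml
#' @export
config_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  pat <- x$early_stopping_patience
  run_config(profile = x$profile, image_size = x$image_size,
             batch_size = x$batch_size, epochs = x$epochs, seed = x$seed,
             momentum = x$momentum, weight_decay = x$weight_decay,
             initial_lr = x$initial_lr,
             mosaic_disable_last = x$mosaic_disable_last,
             early_stopping_patience = if (!is.null(pat) && pat < 0) Inf else pat,
             n_classes = x$n_classes, width_mult = x$width_mult,
             reg_max = x$reg_max, cls_literal = x$cls_literal,
             warmup_epochs = x$warmup_epochs,
             use_ema = isTRUE(x$use_ema))
}

#' Mosaic augmentation
#'
#' Composes four annotated images into one canvas split into quadrants
#' around a (random) centre. Each quadrant shows the corner crop of its
#' source image adjacent to the centre; boxes are translated, clipped to
#' their quadrant, and dropped if less than 10% of their original area
#' remains.
#'
#' @param samples list of four scenes (`$image`, `$boxes`).
#' @param canvas_size output side length.
#' @param seed seed for the centre draw.
#' @param center optional `c(x, y)` to force the mosaic centre.
#' @return a scene list (`$image`, `$boxes`).
#' @export
mosaic_augment <- function(samples, canvas_size, seed = 1L, center = NULL) {
  stopifnot(length(samples) == 4)
  s <- canvas_size
  if (is.null(center)) {
    center <- with_seed(as.integer(seed),
                        round(stats::runif(2, 0.3 * s, 0.7 * s)))
  }
  cx <- max(1, min(s - 1, round(center[1])))
  cy <- max(1, min(s - 1, round(center[2])))
  canvas <- array(0, c(s, s, 3))
  boxes <- NULL
  # quadrant layout: (x range, y range, which corner of the source)
  quads <- list(
    list(xs = 1:cx, ys = 1:cy, corner = "br"),
    list(xs = (cx + 1):s, ys = 1:cy, corner = "bl"),
    list(xs = 1:cx, ys = (cy + 1):s, corner = "tr"),
    list(xs = (cx + 1):s, ys = (cy + 1):s, corner = "tl")
  )
  for (q in seq_len(4)) {
    img <- samples[[q]]$image
    h <- dim(img)[1]; w <- dim(img)[2]
    qi <- quads[[q]]
    qw <- length(qi$xs); qh <- length(qi$ys)
    qw <- min(qw, w); qh <- min(qh, h)
    src_x <- switch(qi$corner, br = , tr = (w - qw + 1):w, bl = , tl = 1:qw)
    src_y <- switch(qi$corner, br = , bl = (h - qh + 1):h, tr = , tl = 1:qh)
    dst_x <- switch(qi$corner, br = , tr = qi$xs[(length(qi$xs) - qw + 1):length(qi$xs)],
                    bl = , tl = qi$xs[1:qw])
    dst_y <- switch(qi$corner, br = , bl = qi$ys[(length(qi$ys) - qh + 1):length(qi$ys)],
                    tr = , tl = qi$ys[1:qh])
    canvas[dst_y, dst_x, ] <- img[src_y, src_x, ]
    b <- samples[[q]]$boxes
    if (is.null(b) || nrow(b) == 0) next
    offx <- dst_x[1] - src_x[1]
    offy <- dst_y[1] - src_y[1]
    nb <- b
    nb$xmin <- b$xmin + offx; nb$xmax <- b$xmax + offx
    nb$ymin <- b$ymin + offy; nb$ymax <- b$ymax + offy
    lim <- c(min(dst_x) - 1, min(dst_y) - 1, max(dst_x), max(dst_y))
    cxmin <- pmax(nb$xmin, lim[1]); cymin <- pmax(nb$ymin, lim[2])
    cxmax <- pmin(nb$xmax, lim[3]); cymax <- pmin(nb$ymax, lim[4])
    area0 <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
    area1 <- pmax(0, cxmax - cxmin) * pmax(0, cymax - cymin)
    keep <- area1 >= 0.1 * area0 & area1 > 0
    if (any(keep)) {
      kb <- data.frame(xmin = cxmin, ymin = cymin, xmax = cxmax, ymax = cymax,
                       class = b$class)[keep, , drop = FALSE]
      boxes <- rbind(boxes, kb)
    }
  }
  if (is.null(boxes))
    boxes <- data.frame(xmin = numeric(0), ymin = numeric(0),
                        xmax = numeric(0), ymax = numeric(0), class = integer(0))
  list(image = canvas, boxes = boxes)
}

# one SGD step with momentum, decoupled weight decay and global-norm clipping
sgd_step <- function(ctx, lr, momentum, weight_decay, clip = 10) {
  gn2 <- 0
  for (p in ctx$params) if (!is.null(p$g)) gn2 <- gn2 + sum(p$g^2)
  scale <- if (gn2 > clip^2) clip / sqrt(gn2) else 1
  for (p in ctx$params) {
    if (is.null(p$g)) next
    g <- p$g * scale
    if (isTRUE(p$decay)) g <- g + weight_decay * p$v
    if (is.null(p$mom)) p$mom <- g * 0
    p$mom <- momentum * p$mom + g
    p$v <- p$v - lr * p$mom
    p$g <- NULL
  }
  invisible(NULL)
}

lr_at <- function(cfg, epoch, frac_in_epoch = 0) {
  t <- epoch - 1 + frac_in_epoch
  if (t < cfg$warmup_epochs && cfg$epochs > cfg$warmup_epochs)
    return(cfg$initial_lr * (0.1 + 0.9 * t / cfg$warmup_epochs))
  span <- max(1, cfg$epochs - cfg$warmup_epochs)
  prog <- min(1, max(0, (t - cfg$warmup_epochs) / span))
  cfg$initial_lr * (0.01 + 0.99 * 0.5 * (1 + cos(pi * prog)))
}

#' Train a detector on annotated scenes
#'
#' Runs the full loop: mosaic augmentation (disabled for the last
#' `mosaic_disable_last` epochs), the composite CIoU/BCE/DFL loss, SGD with
#' momentum and warmup + cosine learning-rate decay, optional early stopping
#' on validation AP50, and per-step loss logging. The whole run is
#' deterministic for a fixed seed.
#'
#' @param scenes training scenes (list of `$image` + `$boxes`).
#' @param config a [run_config()].
#' @param val_scenes optional validation scenes for early stopping.
#' @param log_path optional JSON-lines file receiving one record per step.
#' @param verbose print per-epoch means.
#' @return a trained `seanet_model` with `$history`.
#' @export
seanet_train <- function(scenes, config = run_config("tiny"),
                         val_scenes = NULL, log_path = NULL, verbose = FALSE) {
  stopifnot(length(scenes) >= 1)
  if (dim(scenes[[1]]$image)[1] != config$image_size)
    stop("scene size does not match config$image_size")
  model <- seanet_model(n_classes = config$n_classes,
                        width_mult = config$width_mult,
                        reg_max = config$reg_max, seed = config$seed)
  n <- length(scenes)
  set.seed(config$seed + 1L)
  hist <- list()
  con <- if (!is.null(log_path)) file(log_path, open = "w") else NULL
  on.exit(if (!is.null(con)) close(con))
  best_ap <- -Inf; best_state <- NULL; stale <- 0L
  ema <- if (config$use_ema) lapply(model$ctx$params, function(p) p$v) else NULL
  ema_t <- 0L
  for (epoch in seq_len(config$epochs)) {
    mosaic_on <- epoch <= config$epochs - config$mosaic_disable_last
    ord <- sample.int(n)
    sums <- c(box = 0, cls = 0, dfl = 0, total = 0); nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      batch <- lapply(idx, function(i) {
        if (mosaic_on) {
          others <- sample.int(n, 3, replace = TRUE)
          mosaic_augment(scenes[c(i, others)], config$image_size,
                         center = round(stats::runif(2, 0.3, 0.7) * config$image_size))
        } else scenes[[i]]
      })
      ag_reset()
      ls <- model_loss(model, lapply(batch, `[[`, "image"),
                       lapply(batch, `[[`, "boxes"), training = TRUE,
                       cls_literal = config$cls_literal)
      stopifnot(is.finite(vl(ls$total)))
      ag_backward(ls$total)
      lr <- lr_at(config, epoch, (start - 1) / n)
      sgd_step(model$ctx, lr, config$momentum, config$weight_decay)
      if (!is.null(ema)) {
        ema_t <- ema_t + 1L
        d <- min(0.995, (1 + ema_t) / (20 + ema_t))
        for (pi in seq_along(ema))
          ema[[pi]] <- d * ema[[pi]] + (1 - d) * model$ctx$params[[pi]]$v
      }
      row <- c(box = as.numeric(vl(ls$box)), cls = as.numeric(vl(ls$cls)),
               dfl = as.numeric(vl(ls$dfl)), total = as.numeric(vl(ls$total)))
      if (!all(is.finite(row))) stop("loss diverged (non-finite); aborting")
      sums <- sums + row; nb <- nb + 1L
      if (!is.null(con))
        writeLines(jsonlite::toJSON(c(list(epoch = epoch, step = nb, lr = lr),
                                      as.list(row)),
                                    auto_unbox = TRUE, digits = NA), con)
    }
    m <- sums / nb
    hist[[epoch]] <- c(epoch = epoch, m, mosaic = as.numeric(mosaic_on))
    if (verbose)
      message(sprintf("epoch %3d  box %.3f cls %.3f dfl %.3f total %.3f",
                      epoch, m["box"], m["cls"], m["dfl"], m["total"]))
    if (!is.null(val_scenes) && is.finite(config$early_stopping_patience)) {
      ev <- seanet_evaluate(model, val_scenes)
      if (ev$ap50 > best_ap) {
        best_ap <- ev$ap50; best_state <- ctx_state(model$ctx); stale <- 0L
      } else stale <- stale + 1L
      if (stale >= config$early_stopping_patience) {
        if (!is.null(best_state)) ctx_restore(model$ctx, best_state)
        break
      }
    }
  }
  if (!is.null(ema) && is.null(best_state)) {
    for (pi in seq_along(ema)) model$ctx$params[[pi]]$v <- ema[[pi]]
  }
  h <- as.data.frame(do.call(rbind, hist))
  model$history <- h
  model$trained_epochs <- nrow(h)
  model$config <- config
  model
}

#' Evaluate a detector on scenes, optionally under degradation
#'
#' The degradation (if any) is applied to the evaluation images only, after
#' annotation, so the ground truth is untouched.
#'
#' @param model a trained `seanet_model`.
#' @param scenes evaluation scenes.
#' @param degradation optional [degradation_spec()].
#' @param seed seed for stochastic degradations.
#' @param conf_threshold confidence floor for predictions.
#' @return a `seanet_eval` result.
#' @export
seanet_evaluate <- function(model, scenes, degradation = NULL, seed = 1L,
                            conf_threshold = 0.001) {
  imgs <- lapply(seq_along(scenes), function(i) {
    im <- scenes[[i]]$image
    if (!is.null(degradation)) im <- apply_degradation(im, degradation, seed + i)
    im
  })
  preds <- predict(model, imgs, conf_threshold = conf_threshold)
  gts <- lapply(scenes, `[[`, "boxes")
  ev <- evaluate_detections(preds, gts, model$n_classes)
  if (!is.null(degradation)) {
    ev$degradation <- list(kind = degradation$kind,
                           severity = degradation$severity,
                           noise_std = degradation$noise_std,
                           blur_kernel = degradation$blur_kernel)
  }
  ev
}

#' Robustness sweep over the degradation ladder
#'
#' Evaluates the model under both degradation kinds at severities 1--5
#' (Gaussian noise std 10..50; motion-blur kernels 5..21), yielding one row
#' per (kind, severity).
#'
#' @param model a trained `seanet_model`.
#' @param scenes evaluation scenes.
#' @param seed seed for the noise fields.
#' @param csv_path optional path for a CSV of the table.
#' @return data frame with columns `kind, severity, noise_std, blur_kernel,
#'   ap, ap50, ap75`, of class `seanet_sweep`.
#' @export
robustness_sweep <- function(model, scenes, seed = 1L, csv_path = NULL) {
  rows <- list()
  for (kind in c("gaussian_noise", "motion_blur")) {
    for (s in 1:5) {
      dg <- degradation_spec(kind, s)
      ev <- seanet_evaluate(model, scenes, dg, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, severity = s,
        noise_std = if (kind == "gaussian_noise") dg$noise_std else NA,
        blur_kernel = if (kind == "motion_blur") dg$blur_kernel else NA,
        ap = ev$ap, ap50 = ev$ap50, ap75 = ev$ap75)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("seanet_sweep", class(out))
  if (!is.null(csv_path)) utils::write.csv(out, csv_path, row.names = FALSE)
  out
}

#' Plot a robustness sweep
#'
#' @param x a `seanet_sweep` table.
#' @param ... passed to [graphics::plot()].
#' @export
plot.seanet_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  for (kind in c("gaussian_noise", "motion_blur")) {
    d <- x[x$kind == kind, ]
    graphics::plot(d$severity, d$ap50, type = "b", ylim = c(0, 1),
                   xlab = "severity", ylab = "AP50", main = kind, ...)
    graphics::lines(d$severity, d$ap, type = "b", lty = 2)
    graphics::legend("topright", c("AP50", "AP"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
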
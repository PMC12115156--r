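# Staged backbone with efficient layer-aggregation blocks and the
# multi-scale detail amplification block at the stride-4 stage, exposing
# taps at strides 8, 16 and 32 for the pyramid.

# CSP/ELAN-style split-transform-merge block (shape preserving)
new_elan <- function(ctx, channels, depth = 1L, name = "elan") {
  half <- max(2L, channels %/% 2L)
  s1 <- cbs_bn(ctx, channels, half, 1L, name = paste0(name, ".s1"))
  s2 <- cbs_bn(ctx, channels, half, 1L, name = paste0(name, ".s2"))
  chain <- lapply(seq_len(depth), function(i)
    cbs_bn(ctx, half, half, 3L, name = sprintf("%s.c%d", name, i)))
  merge <- cbs_bn(ctx, 2L * half, channels, 1L, name = paste0(name, ".merge"))
  list(fwd = function(x, training = TRUE) {
    a <- s1$fwd(x, training)
    b <- s2$fwd(x, training)
    for (cv in chain) b <- cv$fwd(b, training)
    merge$fwd(op_concat_c(list(a, b)), training)
  })
}

#' Backbone configuration
#'
#' @param stage_widths channel widths of the five stages at strides
#'   2, 4, 8, 16, 32. The last three are the tap widths fed to the pyramid.
#' @param stage_depths depths of the aggregation blocks at strides 8/16/32.
#' @param width_mult width multiplier; widths are scaled and rounded to
#'   multiples of 4 (minimum 8).
#' @param mdam_stage_index index of the stage replaced by the multi-scale
#'   detail amplification block (default 2, the stride-4 stage).
#' @param use_mdam set `FALSE` to keep a plain aggregation block instead
#'   (ablation switch).
#' @return an object of class `backbone_config`.
#' @export
backbone_config <- function(stage_widths = c(32L, 64L, 64L, 128L, 256L),
                            stage_depths = c(1L, 1L, 1L),
                            width_mult = 1,
                            mdam_stage_index = 2L,
                            use_mdam = TRUE) {
  stopifnot(length(stage_widths) == 5, width_mult > 0,
            mdam_stage_index >= 1, mdam_stage_index <= 5)
  w <- pmax(8L, as.integer(round(stage_widths * width_mult / 4) * 4))
  structure(list(stage_widths = w, stage_depths = as.integer(stage_depths),
                 width_mult = width_mult,
                 mdam_stage_index = as.integer(mdam_stage_index),
                 use_mdam = isTRUE(use_mdam)),
            class = "backbone_config")
}

new_backbone <- function(ctx, cfg = backbone_config()) {
  w <- cfg$stage_widths
  d <- cfg$stage_depths
  stem <- cbs_bn(ctx, 3L, w[1], 3L, stride = 2L, name = "bb.stem")
  down2 <- cbs_bn(ctx, w[1], w[2], 3L, stride = 2L, name = "bb.down2")
  stage2 <- if (cfg$use_mdam && cfg$mdam_stage_index == 2L)
    new_mdam(ctx, mdam_config(w[2], w[2]))
  else new_elan(ctx, w[2], 1L, "bb.elan2")
  down3 <- cbs_bn(ctx, w[2], w[3], 3L, stride = 2L, name = "bb.down3")
  stage3 <- new_elan(ctx, w[3], d[1], "bb.elan3")
  down4 <- cbs_bn(ctx, w[3], w[4], 3L, stride = 2L, name = "bb.down4")
  stage4 <- new_elan(ctx, w[4], d[2], "bb.elan4")
  down5 <- cbs_bn(ctx, w[4], w[5], 3L, stride = 2L, name = "bb.down5")
  stage5 <- new_elan(ctx, w[5], d[3], "bb.elan5")
  list(cfg = cfg, tap_widths = w[3:5],
       fwd = function(x, training = TRUE) {
         x <- stem$fwd(x, training)                    # stride 2
         x <- stage2$fwd(down2$fwd(x, training), training)  # stride 4 (MDAM)
         p4 <- stage3$fwd(down3$fwd(x, training), training) # stride 8
         p6 <- stage4$fwd(down4$fwd(p4, training), training) # stride 16
         p9 <- stage5$fwd(down5$fwd(p6, training), training) # stride 32
         list(p4 = p4, p6 = p6, p9 = p9)
       })
}

#' Backbone forward pass
#'
#' @param images numeric array `c(batch, 3, height, width)` with values in
#'   `[0, 1]`; height and width must be divisible by 32.
#' @param cfg a [backbone_config()].
#' @param block optional pre-built backbone.
#' @param training logical; normalisation mode.
#' @return list of three taps `p4`, `p6`, `p9` at strides 8/16/32.
#' @export
backbone_forward <- function(images, cfg = backbone_config(), block = NULL,
                             training = FALSE) {
  images <- as_feature_map(images, 3L)
  d <- dim(images)
  if (d[3] %% 32 != 0 || d[4] %% 32 != 0)
    stop("input height and width must be divisible by 32; letterbox-pad the image first")
  if (is.null(block)) block <- new_backbone(new_ctx(), cfg)
  ag_no_grad(lapply(block$fwd(ag_const(images), training), vl))
}
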
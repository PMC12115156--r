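# Semantic enhancement feature pyramid: aligns the three backbone taps
# (strides 8/16/32) and fuses them through four Contrast Enhancement Module
# nodes into three detection features at the same strides. Fusion is plain
# unweighted channel concatenation; all learned fusion lives inside the CEMs
# and the alignment blocks.

# Scale/width alignment between pyramid levels. Upsampling hops use nearest-
# neighbour x2 followed by a 1x1 CBS to the target width; downsampling hops
# use a 3x3 stride-2 CBS; equal strides use a 1x1 CBS only.
new_align <- function(ctx, cin, cout, source_stride, target_stride, name = "align") {
  ratio <- source_stride / target_stride
  if (!(ratio %in% c(0.5, 1, 2))) stop("stride ratio per hop must be 2, 1 or 1/2")
  if (ratio == 2) {
    cv <- cbs_bn(ctx, cin, cout, 1L, name = name)
    fwd <- function(x, training = TRUE) cv$fwd(op_upsample2(x), training)
  } else if (ratio == 0.5) {
    cv <- cbs_bn(ctx, cin, cout, 3L, stride = 2L, name = name)
    fwd <- function(x, training = TRUE) cv$fwd(x, training)
  } else {
    cv <- cbs_bn(ctx, cin, cout, 1L, name = name)
    fwd <- function(x, training = TRUE) cv$fwd(x, training)
  }
  list(fwd = fwd)
}

#' Align a feature map to a neighbouring pyramid level
#'
#' @param f numeric array `c(batch, channels, height, width)`.
#' @param source_stride,target_stride powers of two; their ratio must be
#'   2, 1 or 1/2 (one pyramid hop).
#' @param target_width output channel width.
#' @param block optional pre-built alignment block.
#' @param training logical; normalisation mode.
#' @return the aligned feature map.
#' @export
align_to_level <- function(f, source_stride, target_stride, target_width,
                           block = NULL, training = FALSE) {
  f <- as_feature_map(f)
  if (is.null(block))
    block <- new_align(new_ctx(), dim(f)[2], target_width, source_stride, target_stride)
  ag_no_grad(vl(block$fwd(ag_const(f), training)))
}

# The adopted wiring (top-down then bottom-up, one backbone skip):
#   U4 = CEM(concat(P6, up(P9)))
#   D1 = CEM(concat(P4, up(U4)))
#   D2 = CEM(concat(down(D1), U4, P6))
#   D3 = CEM(concat(down(D2), P9))
new_sefpn <- function(ctx, widths = c(64L, 128L, 256L), cem_repeats = 3L) {
  w8 <- widths[1]; w16 <- widths[2]; w32 <- widths[3]
  up9 <- new_align(ctx, w32, w16, 32, 16, "fpn.up9")
  cem_u4 <- new_cem(ctx, 2L * w16, w16, cem_repeats, name = "fpn.cem_u4")
  up4 <- new_align(ctx, w16, w8, 16, 8, "fpn.up4")
  cem_d1 <- new_cem(ctx, 2L * w8, w8, cem_repeats, name = "fpn.cem_d1")
  down1 <- new_align(ctx, w8, w16, 8, 16, "fpn.down1")
  cem_d2 <- new_cem(ctx, 3L * w16, w16, cem_repeats, name = "fpn.cem_d2")
  down2 <- new_align(ctx, w16, w32, 16, 32, "fpn.down2")
  cem_d3 <- new_cem(ctx, 2L * w32, w32, cem_repeats, name = "fpn.cem_d3")
  list(widths = widths, n_cem = 4L,
       fwd = function(p4, p6, p9, training = TRUE) {
         u4 <- cem_u4$fwd(op_concat_c(list(p6, up9$fwd(p9, training))), training)
         d1 <- cem_d1$fwd(op_concat_c(list(p4, up4$fwd(u4, training))), training)
         d2 <- cem_d2$fwd(op_concat_c(list(down1$fwd(d1, training), u4, p6)), training)
         d3 <- cem_d3$fwd(op_concat_c(list(down2$fwd(d2, training), p9)), training)
         list(d1 = d1, d2 = d2, d3 = d3)
       })
}

#' Semantic enhancement feature pyramid forward pass
#'
#' @param p4,p6,p9 backbone taps at strides 8, 16 and 32 with channel widths
#'   `widths[1:3]`.
#' @param widths per-level channel widths.
#' @param block optional pre-built pyramid.
#' @param training logical; normalisation mode.
#' @return list of three feature maps `d1`, `d2`, `d3` at strides 8/16/32.
#' @export
sefpn_forward <- function(p4, p6, p9, widths = c(64L, 128L, 256L),
                          block = NULL, training = FALSE) {
  p4 <- as_feature_map(p4); p6 <- as_feature_map(p6); p9 <- as_feature_map(p9)
  if (is.null(block)) block <- new_sefpn(new_ctx(), as.integer(widths))
  w <- block$widths
  if (dim(p4)[2] != w[1] || dim(p6)[2] != w[2] || dim(p9)[2] != w[3])
    stop("backbone tap widths do not match the configured pyramid widths")
  if (any(dim(p4)[3:4] != 2L * dim(p6)[3:4]) || any(dim(p6)[3:4] != 2L * dim(p9)[3:4]))
    stop("spatial dims must halve exactly between consecutive levels")
  ag_no_grad({
    r <- block$fwd(ag_const(p4), ag_const(p6), ag_const(p9), training)
    lapply(r, vl)
  })
}
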
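# Contrast Enhancement Module and its parts: spatial-channel attention
# (SCAM), fore-background contrast attention (FBC), and the BottleRep
# residual block.

# Fore-background contrast attention. A 1-channel conv + batch-norm +
# leaky-ReLU ("CBLR") followed by a sigmoid yields the foreground activation
# map Ff in (0,1); the background map is its complement Fb = 1 - Ff. Both are
# pooled against the input by flattened matrix products into [B,1,C] vectors
# vf, vb, gated through independent affine maps + sigmoid into cf, cb, and
# the input is rescaled per channel by the gate difference: F' = F (cf - cb).
new_fbc <- function(ctx, channels, name = "fbc") {
  cv <- conv_layer(ctx, channels, 1L, 1L, bias = FALSE, name = paste0(name, ".cblr"))
  nm <- batch_norm_layer(ctx, 1L, name = paste0(name, ".cblr.bn"))
  rho_f <- linear_layer(ctx, channels, channels, name = paste0(name, ".rho_f"), w_sd = 0.01)
  rho_b <- linear_layer(ctx, channels, channels, name = paste0(name, ".rho_b"), w_sd = 0.01)
  list(
    channels = channels, rho_f = rho_f, rho_b = rho_b, cv = cv, nm = nm,
    fwd = function(x, training = TRUE, trace = FALSE) {
      ff <- op_sigmoid(op_leaky(nm$fwd(cv$fwd(x, training), training)))  # [B,1,H,W]
      fb <- op_rsubc(1, ff)
      vf <- op_attn_pool(ff, x)                 # [B,C]
      vb <- op_attn_pool(fb, x)
      cf <- op_sigmoid(rho_f$fwd(vf))
      cb <- op_sigmoid(rho_b$fwd(vb))
      out <- op_scale_channels(x, op_sub(cf, cb))
      if (trace) {
        d <- dim(vl(x))
        return(list(out = out, Ff = vl(ff), Fb = vl(fb),
                    vf = array(vl(vf), c(d[1], 1, d[2])),
                    vb = array(vl(vb), c(d[1], 1, d[2])),
                    cf = array(vl(cf), c(d[1], 1, d[2])),
                    cb = array(vl(cb), c(d[1], 1, d[2]))))
      }
      out
    }
  )
}

#' Fore-background contrast attention forward pass
#'
#' Applies a freshly initialised fore-background contrast attention block to
#' one feature map. The block splits attention into a foreground activation
#' map and its complement, pools both into per-channel vectors, gates them,
#' and rescales each channel by the gate difference, amplifying channels
#' whose response separates foreground from background.
#'
#' @param x numeric array `c(batch, channels, height, width)`.
#' @param block optionally a pre-built block (internal constructor).
#' @param training logical; normalisation mode.
#' @param trace if `TRUE`, also return the intermediate activation maps
#'   (`Ff`, `Fb`), pooled vectors (`vf`, `vb`, shape `[B,1,C]`) and gates
#'   (`cf`, `cb`).
#' @return the rescaled feature map, or a list of intermediates if `trace`.
#' @export
fbc_forward <- function(x, block = NULL, training = FALSE, trace = FALSE) {
  x <- as_feature_map(x)
  if (dim(x)[3] * dim(x)[4] == 0) stop("empty spatial extent")
  if (is.null(block)) block <- new_fbc(new_ctx(), dim(x)[2])
  if (dim(x)[2] != block$channels)
    stop("channel width does not match the block width")
  ag_no_grad({
    r <- block$fwd(ag_const(x), training, trace)
    if (trace) { r$out <- vl(r$out); r } else vl(r)
  })
}

# Spatial-channel attention: channel attention first (shared two-layer
# bottleneck over global average- and max-pooled descriptors, summed,
# sigmoid), then spatial attention (7x7 conv over the channelwise mean/max
# maps, sigmoid), applied as sequential gates.
new_scam <- function(ctx, channels, name = "scam") {
  hidden <- max(1L, channels %/% 8L)
  fc1 <- linear_layer(ctx, channels, hidden, name = paste0(name, ".fc1"))
  fc2 <- linear_layer(ctx, hidden, channels, name = paste0(name, ".fc2"))
  sp <- conv_layer(ctx, 2L, 1L, 7L, bias = TRUE, name = paste0(name, ".sp"))
  mlp <- function(v) fc2$fwd(op_relu(fc1$fwd(v)))
  list(channels = channels, fc2 = fc2, sp = sp,
       fwd = function(x, training = TRUE) {
         gc <- op_sigmoid(op_add(mlp(op_gap(x)), mlp(op_gmp(x))))
         x1 <- op_scale_channels(x, gc)
         gs <- op_sigmoid(sp$fwd(op_concat_c(list(op_chan_mean(x1), op_chan_max(x1)))))
         op_scale_spatial(x1, gs)
       },
       channel_gate = function(x) {
         ag_no_grad(vl(op_sigmoid(op_add(mlp(op_gap(ag_const(x))),
                                         mlp(op_gmp(ag_const(x)))))))
       })
}

#' Spatial-channel attention forward pass
#'
#' Channel attention is applied first, then spatial attention; both act as
#' multiplicative sigmoid gates, so the output has the shape of the input.
#'
#' @inheritParams fbc_forward
#' @return gated feature map with the same shape as `x`.
#' @export
scam_forward <- function(x, block = NULL, training = FALSE) {
  x <- as_feature_map(x)
  if (is.null(block)) block <- new_scam(new_ctx(), dim(x)[2])
  ag_no_grad(vl(block$fwd(ag_const(x), training)))
}

# YOLO-style residual block: two 3x3 conv+BN+SiLU blocks plus a learnable
# scalar-weighted identity shortcut (initial weight 1), shortcut active only
# when the input and output widths agree.
new_bottlerep <- function(ctx, cin, cout, name = "brep") {
  c1 <- cbs_bn(ctx, cin, cout, 3L, name = paste0(name, ".c1"))
  c2 <- cbs_bn(ctx, cout, cout, 3L, name = paste0(name, ".c2"))
  shortcut <- cin == cout
  alpha <- if (shortcut) ctx_add(ctx, ag_param(1, paste0(name, ".alpha"))) else NULL
  list(alpha = alpha, c1 = c1, c2 = c2, fwd = function(x, training = TRUE) {
    y <- c2$fwd(c1$fwd(x, training), training)
    if (shortcut) op_add(y, op_scale_scalar(x, alpha)) else y
  })
}

#' BottleRep residual block forward pass
#'
#' @inheritParams fbc_forward
#' @return feature map of the same spatial size.
#' @export
bottlerep_forward <- function(x, block = NULL, training = FALSE) {
  x <- as_feature_map(x)
  if (is.null(block)) block <- new_bottlerep(new_ctx(), dim(x)[2], dim(x)[2])
  ag_no_grad(vl(block$fwd(ag_const(x), training)))
}

# Contrast Enhancement Module:
#   x  <- SCAM(x)
#   y1 <- CBS1(x);  y1 <- FBC(y1) + y1
#   y2 <- CBS2(x);  mid_out <- [y1]
#   repeat n_reps times: y2 <- BottleRep(y2); append y2 to mid_out
#   y  <- CBS3(concat(mid_out))
new_cem <- function(ctx, cin, cout, n_reps = 3L, hidden = NULL, name = "cem") {
  if (is.null(hidden)) hidden <- max(2L, cout %/% 2L)
  scam <- new_scam(ctx, cin, paste0(name, ".scam"))
  cbs1 <- cbs_bn(ctx, cin, hidden, 1L, name = paste0(name, ".cbs1"))
  cbs2 <- cbs_bn(ctx, cin, hidden, 1L, name = paste0(name, ".cbs2"))
  fbc <- new_fbc(ctx, hidden, paste0(name, ".fbc"))
  reps <- lapply(seq_len(n_reps), function(i)
    new_bottlerep(ctx, hidden, hidden, sprintf("%s.rep%d", name, i)))
  cbs3 <- cbs_bn(ctx, hidden * (1L + n_reps), cout, 1L, name = paste0(name, ".cbs3"))
  list(cin = cin, cout = cout, hidden = hidden, n_reps = n_reps,
       scam = scam, cbs1 = cbs1, fbc = fbc,
       fwd = function(x, training = TRUE, trace = FALSE) {
         x <- scam$fwd(x, training)
         y1 <- cbs1$fwd(x, training)
         y1 <- op_add(fbc$fwd(y1, training), y1)
         y2 <- cbs2$fwd(x, training)
         mid_out <- list(y1)
         for (rep in reps) {
           y2 <- rep$fwd(y2, training)
           mid_out[[length(mid_out) + 1L]] <- y2
         }
         cc <- op_concat_c(mid_out)
         y <- cbs3$fwd(cc, training)
         if (trace) list(out = y, n_mid = length(mid_out),
                         concat_width = dim(vl(cc))[2], y1 = vl(mid_out[[1]]))
         else y
       })
}

#' Contrast Enhancement Module forward pass
#'
#' Runs the full module: spatial-channel attention, a fore-background
#' contrast branch with residual, `n_reps` BottleRep blocks collected
#' alongside it, and a final 1x1 block over their channel concatenation.
#'
#' @inheritParams fbc_forward
#' @param out_channels output width (default: input width).
#' @param n_reps number of BottleRep repetitions (default 3).
#' @param trace if `TRUE`, also return the number of concatenated feature
#'   maps and the concatenation width.
#' @return feature map `c(batch, out_channels, height, width)`.
#' @export
cem_forward <- function(x, block = NULL, out_channels = NULL, n_reps = 3L,
                        training = FALSE, trace = FALSE) {
  x <- as_feature_map(x)
  if (is.null(block)) {
    if (is.null(out_channels)) out_channels <- dim(x)[2]
    block <- new_cem(new_ctx(), dim(x)[2], out_channels, n_reps)
  }
  ag_no_grad({
    r <- block$fwd(ag_const(x), training, trace)
    if (trace) { r$out <- vl(r$out); r } else vl(r)
  })
}
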
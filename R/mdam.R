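#' Configuration for the multi-scale detail amplification block
#'
#' The multi-scale detail amplification module (MDAM) is a five-branch
#' convolutional block inserted early in the backbone. Branch 1 carries the
#' reduced input; branches 2--4 stack a \eqn{k_i \times 1} and a
#' \eqn{1 \times k_i} asymmetric convolution followed by a 3x3 convolution
#' dilated at rate \eqn{k_i}; branch 5 applies a 1x1 block to the raw input.
#' The kernel ladder follows \eqn{k_i = 2i - 1} for branch index
#' \eqn{i = 2, 3, 4}, giving (3, 5, 7) by default. Branches 2--5 each emit a
#' quarter of `reduced_channels` so their concatenation matches branch 1 for
#' the elementwise addition, and a final 3x3 block maps the sum to
#' `out_channels`. Every convolution here is followed by group normalisation
#' and a ReLU.
#'
#' @param in_channels,out_channels input/output channel widths.
#' @param reduced_channels width of the shared reduced representation;
#'   must be divisible by 4. Defaults to `in_channels`.
#' @param branch_kernels integer triple (k2, k3, k4) of odd kernel sizes,
#'   also used as the dilation rates of the per-branch dilated convolution.
#' @param dilated_kernel_size kernel size of the dilated convolution (odd).
#' @param norm_groups requested group count for group normalisation; reduced
#'   to a divisor of each normalised width.
#' @return an object of class `mdam_config`.
#' @export
mdam_config <- function(in_channels, out_channels,
                        reduced_channels = in_channels,
                        branch_kernels = c(3L, 5L, 7L),
                        dilated_kernel_size = 3L,
                        norm_groups = 8L) {
  stopifnot(in_channels >= 1, out_channels >= 1, reduced_channels >= 1,
            length(branch_kernels) == 3, dilated_kernel_size >= 3,
            dilated_kernel_size %% 2 == 1, norm_groups >= 1)
  branch_kernels <- as.integer(branch_kernels)
  if (any(branch_kernels < 3L) || any(branch_kernels %% 2L == 0L))
    stop("branch kernels must be odd and >= 3")
  if (reduced_channels %% 4L != 0L)
    stop("reduced_channels must be divisible by 4 (branches 2-5 each emit a quarter)")
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 reduced_channels = as.integer(reduced_channels),
                 branch_kernels = branch_kernels,
                 dilated_kernel_size = as.integer(dilated_kernel_size),
                 norm_groups = as.integer(norm_groups)),
            class = "mdam_config")
}

#' Build a multi-scale detail amplification block
#'
#' @param ctx parameter registry created by the enclosing model.
#' @param cfg an [mdam_config()].
#' @return a layer list with a `$fwd(x, training)` closure.
#' @keywords internal
new_mdam <- function(ctx, cfg) {
  stopifnot(inherits(cfg, "mdam_config"))
  rc <- cfg$reduced_channels
  qc <- rc %/% 4L
  g <- cfg$norm_groups
  reduce <- cbs_gn(ctx, cfg$in_channels, rc, 1L, groups = g, name = "mdam.reduce")
  branches <- lapply(cfg$branch_kernels, function(k) {
    list(
      a = cbs_gn(ctx, rc, qc, k, 1L, groups = g, name = sprintf("mdam.br%d.kx1", k)),
      b = cbs_gn(ctx, qc, qc, 1L, k, groups = g, name = sprintf("mdam.br%d.1xk", k)),
      d = cbs_gn(ctx, qc, qc, cfg$dilated_kernel_size, dil = k, groups = g,
                 name = sprintf("mdam.br%d.dil", k))
    )
  })
  br5 <- cbs_gn(ctx, cfg$in_channels, qc, 1L, groups = g, name = "mdam.br5")
  out <- cbs_gn(ctx, rc, cfg$out_channels, 3L, groups = g, name = "mdam.out")
  list(cfg = cfg, fwd = function(x, training = TRUE) {
    xr <- reduce$fwd(x, training)               # shared x' feeding branches 1-4
    br <- lapply(branches, function(bl)
      bl$d$fwd(bl$b$fwd(bl$a$fwd(xr, training), training), training))
    b5 <- br5$fwd(x, training)                  # branch 5 consumes the raw input
    fused <- op_add(xr, op_concat_c(c(br, list(b5))))
    out$fwd(fused, training)
  })
}

#' Forward pass of the multi-scale detail amplification block
#'
#' Convenience wrapper that builds a freshly initialised block from `cfg` and
#' applies it to one feature map. For use inside a model build the block once
#' with the internal constructor instead.
#'
#' @param x numeric array with dim `c(batch, channels, height, width)`.
#' @param cfg an [mdam_config()]; `cfg$in_channels` must match `dim(x)[2]`.
#' @param block optionally a pre-built block (overrides `cfg`).
#' @param training logical; normalisation mode.
#' @return numeric array `c(batch, out_channels, height, width)` with the
#'   spatial size of `x` preserved.
#' @export
mdam_forward <- function(x, cfg = NULL, block = NULL, training = FALSE) {
  if (is.null(block)) block <- new_mdam(new_ctx(), cfg)
  x <- as_feature_map(x, block$cfg$in_channels)
  ag_no_grad(vl(block$fwd(ag_const(x), training)))
}

#' Analytic one-axis receptive-field extents of the dilated branches
#'
#' For branch kernel \eqn{k} with a 3x3 dilated convolution at rate \eqn{k}
#' and the final 3x3 block, the extents of sequential convolutions telescope:
#' the asymmetric pair contributes \eqn{k - 1}, the dilated convolution
#' \eqn{2k}, and the final 3x3 another 2, giving \eqn{3k + 2} per axis.
#'
#' @param cfg an [mdam_config()].
#' @return named integer vector of per-branch extents.
#' @export
mdam_receptive_field <- function(cfg) {
  stopifnot(inherits(cfg, "mdam_config"))
  k <- cfg$branch_kernels
  ext <- 1L + (k - 1L) + (cfg$dilated_kernel_size - 1L) * k + 2L
  stats::setNames(as.integer(ext), paste0("branch", 2:4))
}

# validate and coerce a raw array into a [B,C,H,W] feature map
as_feature_map <- function(x, channels = NULL) {
  if (is.null(dim(x)) || length(dim(x)) != 4)
    stop("a feature map must be a rank-4 array [batch, channels, height, width]")
  if (!all(is.finite(x))) stop("feature map contains non-finite values")
  if (!is.null(channels) && dim(x)[2] != channels)
    stop(sprintf("expected %d channels, got %d", channels, dim(x)[2]))
  x
}
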
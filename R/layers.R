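# Layer constructors. A "ctx" is a parameter registry (environment holding a
# list of ag_param nodes); every layer registers its parameters there so the
# optimiser and serialiser can reach them. Layers are plain lists with a
# $fwd(x, training) closure operating on autograd nodes.

new_ctx <- function() {
  ctx <- new.env(parent = emptyenv())
  ctx$params <- list()
  ctx$bn <- list()
  ctx
}

ctx_add <- function(ctx, p) {
  ctx$params[[length(ctx$params) + 1L]] <- p
  p
}

n_params <- function(ctx) sum(vapply(ctx$params, function(p) length(p$v), numeric(1)))

# Kaiming-normal conv weight [O, C, kh, kw]
init_conv_w <- function(o, c, kh, kw) {
  fan_in <- c * kh * kw
  array(stats::rnorm(o * c * kh * kw, sd = sqrt(2 / fan_in)), c(o, c, kh, kw))
}

conv_layer <- function(ctx, cin, cout, kh, kw = kh, stride = 1L, dil = 1L,
                       bias = TRUE, name = "conv") {
  w <- ctx_add(ctx, ag_param(init_conv_w(cout, cin, kh, kw), paste0(name, ".w"), decay = TRUE))
  b <- if (bias) ctx_add(ctx, ag_param(numeric(cout), paste0(name, ".b"))) else NULL
  pad <- c(((kh - 1L) * dil) %/% 2L, ((kw - 1L) * dil) %/% 2L)  # "same" at stride 1
  list(
    w = w, b = b, cin = cin, cout = cout,
    fwd = function(x, training = TRUE)
      op_conv(x, w, b, stride = c(stride, stride), pad = pad, dil = c(dil, dil))
  )
}

linear_layer <- function(ctx, fin, fout, name = "fc", w_sd = NULL) {
  sd <- if (is.null(w_sd)) sqrt(2 / fin) else w_sd
  w <- ctx_add(ctx, ag_param(matrix(stats::rnorm(fin * fout, sd = sd), fin, fout),
                             paste0(name, ".w"), decay = TRUE))
  b <- ctx_add(ctx, ag_param(numeric(fout), paste0(name, ".b")))
  list(w = w, b = b, fwd = function(x, training = TRUE) op_linear(x, w, b))
}

# largest divisor of n_channels not exceeding the requested group count;
# keeps group normalisation well defined at tiny test widths
gn_groups <- function(channels, requested = 8L) {
  g <- min(requested, channels)
  while (channels %% g != 0L) g <- g - 1L
  g
}

group_norm_layer <- function(ctx, channels, groups = 8L, name = "gn") {
  g <- gn_groups(channels, groups)
  gamma <- ctx_add(ctx, ag_param(rep(1, channels), paste0(name, ".gamma")))
  beta <- ctx_add(ctx, ag_param(numeric(channels), paste0(name, ".beta")))
  list(gamma = gamma, beta = beta, groups = g,
       fwd = function(x, training = TRUE) op_group_norm(x, gamma, beta, g))
}

batch_norm_layer <- function(ctx, channels, name = "bn") {
  gamma <- ctx_add(ctx, ag_param(rep(1, channels), paste0(name, ".gamma")))
  beta <- ctx_add(ctx, ag_param(numeric(channels), paste0(name, ".beta")))
  state <- new.env(parent = emptyenv())
  state$rm <- numeric(channels)
  state$rv <- rep(1, channels)
  ctx$bn[[length(ctx$bn) + 1L]] <- state
  list(gamma = gamma, beta = beta, state = state,
       fwd = function(x, training = TRUE)
         op_batch_norm(x, gamma, beta, state, training))
}

# CBS block, group-norm flavour: convolution + group normalisation + ReLU
# (used inside the multi-scale detail amplification block)
cbs_gn <- function(ctx, cin, cout, k = 3L, kw = k, stride = 1L, dil = 1L,
                   groups = 8L, name = "cbs") {
  cv <- conv_layer(ctx, cin, cout, k, kw, stride, dil, bias = FALSE, name = name)
  nm <- group_norm_layer(ctx, cout, groups, name = paste0(name, ".gn"))
  list(cout = cout, cv = cv, nm = nm, fwd = function(x, training = TRUE)
    op_relu(nm$fwd(cv$fwd(x, training), training)))
}

# CBS block, batch-norm flavour: convolution + batch normalisation + SiLU
# (used in the pyramid/neck and head)
cbs_bn <- function(ctx, cin, cout, k = 3L, stride = 1L, name = "cbs") {
  cv <- conv_layer(ctx, cin, cout, k, k, stride, 1L, bias = FALSE, name = name)
  nm <- batch_norm_layer(ctx, cout, name = paste0(name, ".bn"))
  list(cout = cout, cv = cv, nm = nm, fwd = function(x, training = TRUE)
    op_silu(nm$fwd(cv$fwd(x, training), training)))
}

# serialise / restore all parameters and batch-norm running stats of a ctx
ctx_state <- function(ctx) {
  list(params = lapply(ctx$params, function(p) list(v = p$v, name = p$name)),
       bn = lapply(ctx$bn, function(s) list(rm = s$rm, rv = s$rv)))
}

ctx_restore <- function(ctx, state) {
  stopifnot(length(state$params) == length(ctx$params))
  for (i in seq_along(ctx$params)) {
    v <- state$params[[i]]$v
    stopifnot(length(v) == length(ctx$params[[i]]$v))
    dim(v) <- dim(ctx$params[[i]]$v)
    ctx$params[[i]]$v <- v
  }
  for (i in seq_along(ctx$bn)) {
    ctx$bn[[i]]$rm <- state$bn[[i]]$rm
    ctx$bn[[i]]$rv <- state$bn[[i]]$rv
  }
  invisible(ctx)
}
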
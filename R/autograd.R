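# Minimal tape-based reverse-mode automatic differentiation over dense R
# arrays. Feature maps are stored as dim = c(B, C, H, W). Every operation
# records a node on a package-local tape; ag_backward() replays the tape in
# reverse creation order, which is already a topological order.

the <- new.env(parent = emptyenv())
the$tape <- NULL
the$tn <- 0L
the$grad_on <- TRUE

ag_reset <- function() {
  the$tape <- vector("list", 1024L)
  the$tn <- 0L
  invisible(NULL)
}

ag_no_grad <- function(expr) {
  old <- the$grad_on
  the$grad_on <- FALSE
  on.exit(the$grad_on <- old)
  expr
}

ag_push <- function(n) {
  if (is.null(the$tape)) ag_reset()
  i <- the$tn + 1L
  if (i > length(the$tape)) the$tape <- c(the$tape, vector("list", length(the$tape)))
  the$tape[[i]] <- n
  the$tn <- i
  invisible(NULL)
}

#' @keywords internal
node_new <- function(v, ps = list(), back = NULL) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$ps <- ps
  n$back <- back
  n$rg <- FALSE
  if (the$grad_on && length(ps)) {
    for (p in ps) if (isTRUE(p$rg)) { n$rg <- TRUE; break }
    if (n$rg && !is.null(back)) ag_push(n)
  }
  n
}

ag_param <- function(v, name = "", decay = FALSE) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$rg <- TRUE
  n$name <- name
  n$decay <- decay
  n
}

ag_const <- function(v) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$g <- NULL
  n$rg <- FALSE
  n
}

vl <- function(x) x$v

acc_grad <- function(p, g) {
  if (isTRUE(p$rg)) {
    if (is.null(p$g)) {
      # stored by reference: may alias another node's grad, not yet owned
      p$g <- if (is.logical(g)) g + 0 else g
      p$gown <- FALSE
    } else if (!isTRUE(p$gown)) {
      p$g <- p$g + g
      p$gown <- TRUE
    } else {
      # privately owned buffer: accumulate in place
      add_inplace(p$g, g)
    }
  }
  invisible(NULL)
}

ag_backward <- function(root) {
  root$g <- array(1, dim = if (is.null(dim(root$v))) length(root$v) else dim(root$v))
  if (the$tn < 1L) return(invisible(NULL))
  for (i in the$tn:1L) {
    n <- the$tape[[i]]
    if (!is.null(n$g) && !is.null(n$back)) n$back(n)
    the$tape[i] <- list(NULL)  # free
  }
  the$tn <- 0L
  invisible(NULL)
}

# ---- elementwise arithmetic ------------------------------------------------

op_add <- function(a, b) {
  node_new(a$v + b$v, list(a, b), function(n) {
    acc_grad(n$ps[[1]], n$g); acc_grad(n$ps[[2]], n$g)
  })
}

op_sub <- function(a, b) {
  node_new(a$v - b$v, list(a, b), function(n) {
    acc_grad(n$ps[[1]], n$g); acc_grad(n$ps[[2]], -n$g)
  })
}

op_mul <- function(a, b) {
  node_new(a$v * b$v, list(a, b), function(n) {
    acc_grad(n$ps[[1]], n$g * n$ps[[2]]$v)
    acc_grad(n$ps[[2]], n$g * n$ps[[1]]$v)
  })
}

op_div <- function(a, b) {
  node_new(a$v / b$v, list(a, b), function(n) {
    acc_grad(n$ps[[1]], n$g / n$ps[[2]]$v)
    acc_grad(n$ps[[2]], -n$g * n$ps[[1]]$v / (n$ps[[2]]$v^2))
  })
}

op_addc <- function(a, k) node_new(a$v + k, list(a), function(n) acc_grad(n$ps[[1]], n$g))
op_mulc <- function(a, k) node_new(a$v * k, list(a), function(n) acc_grad(n$ps[[1]], n$g * get("k", environment(n$back))))
op_rsubc <- function(k, a) node_new(k - a$v, list(a), function(n) acc_grad(n$ps[[1]], -n$g))

# y = a * mulv + addv with constant vectors (recycled elementwise)
op_affine_const <- function(a, mulv, addv = 0) {
  node_new(a$v * mulv + addv, list(a), function(n)
    acc_grad(n$ps[[1]], n$g * get("mulv", environment(n$back))))
}

op_square <- function(a) node_new(a$v^2, list(a), function(n) acc_grad(n$ps[[1]], 2 * n$ps[[1]]$v * n$g))

op_atan <- function(a) node_new(atan(a$v), list(a), function(n)
  acc_grad(n$ps[[1]], n$g / (1 + n$ps[[1]]$v^2)))

op_pmax <- function(a, b) {
  m <- a$v >= b$v
  node_new(pmax(a$v, b$v), list(a, b), function(n) {
    mm <- get("m", environment(n$back))
    acc_grad(n$ps[[1]], n$g * mm)
    acc_grad(n$ps[[2]], n$g * !mm)
  })
}

op_pmin <- function(a, b) {
  m <- a$v <= b$v
  node_new(pmin(a$v, b$v), list(a, b), function(n) {
    mm <- get("m", environment(n$back))
    acc_grad(n$ps[[1]], n$g * mm)
    acc_grad(n$ps[[2]], n$g * !mm)
  })
}

op_pmaxc <- function(a, k) {
  m <- a$v > k
  node_new(pmax(a$v, k), list(a), function(n)
    acc_grad(n$ps[[1]], n$g * get("m", environment(n$back))))
}

# multiply an array node by a scalar parameter node (learnable shortcut gain)
op_scale_scalar <- function(x, s) {
  node_new(x$v * as.numeric(s$v), list(x, s), function(n) {
    acc_grad(n$ps[[1]], n$g * as.numeric(n$ps[[2]]$v))
    acc_grad(n$ps[[2]], sum(n$g * n$ps[[1]]$v))
  })
}

# ---- activations -----------------------------------------------------------

op_relu <- function(a) {
  node_new(relu_fwd(a$v), list(a), function(n)
    acc_grad(n$ps[[1]], relu_bwd(n$g, n$ps[[1]]$v)))
}

op_leaky <- function(a, slope = 0.1) {
  m <- a$v > 0
  node_new(ifelse_fast(m, a$v, slope * a$v), list(a), function(n) {
    mm <- get("m", environment(n$back)); s <- get("slope", environment(n$back))
    acc_grad(n$ps[[1]], n$g * (mm + s * !mm))
  })
}

ifelse_fast <- function(m, a, b) { r <- b; r[m] <- a[m]; r }

op_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  node_new(s, list(a), function(n) {
    ss <- get("s", environment(n$back))
    acc_grad(n$ps[[1]], n$g * ss * (1 - ss))
  })
}

op_silu <- function(a) {
  r <- silu_fwd(a$v)
  node_new(r$y, list(a), function(n) {
    e <- environment(n$back)
    acc_grad(n$ps[[1]], silu_bwd(n$g, n$ps[[1]]$v, get("r", e)$s))
  })
}

# ---- reductions ------------------------------------------------------------

op_sum <- function(a) node_new(sum(a$v), list(a), function(n) {
  p <- n$ps[[1]]
  acc_grad(p, array(as.numeric(n$g), dim = dim_of(p$v)))
})

op_mean <- function(a) {
  k <- length(a$v)
  node_new(sum(a$v) / k, list(a), function(n) {
    p <- n$ps[[1]]
    acc_grad(p, array(as.numeric(n$g) / get("k", environment(n$back)), dim = dim_of(p$v)))
  })
}

dim_of <- function(v) if (is.null(dim(v))) length(v) else dim(v)

# weighted sum of scalar nodes
op_wsum <- function(xs, ws) {
  v <- 0
  for (i in seq_along(xs)) v <- v + ws[i] * xs[[i]]$v
  node_new(v, xs, function(n) {
    w <- get("ws", environment(n$back))
    for (i in seq_along(n$ps)) acc_grad(n$ps[[i]], n$g * w[i])
  })
}

# ---- structural ops on [B,C,H,W] feature maps ------------------------------

op_conv <- function(x, w, b = NULL, stride = c(1L, 1L), pad = c(0L, 0L), dil = c(1L, 1L)) {
  xd <- dim(x$v); wd <- dim(w$v)
  bias <- if (is.null(b)) numeric(0) else b$v
  keep <- the$grad_on && (isTRUE(x$rg) || isTRUE(w$rg))
  r <- conv2d_fwd_cache(x$v, as.integer(xd), w$v, as.integer(wd),
                        bias, as.integer(stride), as.integer(pad),
                        as.integer(dil), keep)
  cols <- if (keep) r$cols else NULL
  ps <- if (is.null(b)) list(x, w) else list(x, w, b)
  node_new(r$y, ps, function(n) {
    e <- environment(n$back)
    xn <- n$ps[[1]]; wn <- n$ps[[2]]
    res <- conv2d_bwd_cpp(get("cols", e), as.integer(get("xd", e)),
                          wn$v, as.integer(get("wd", e)),
                          n$g, as.integer(get("stride", e)),
                          as.integer(get("pad", e)), as.integer(get("dil", e)),
                          isTRUE(xn$rg))
    if (isTRUE(xn$rg)) acc_grad(xn, res$gx)
    acc_grad(wn, res$gw)
    if (length(n$ps) == 3L) acc_grad(n$ps[[3]], res$gb)
  })
}

op_concat_c <- function(xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(dims, `[`, integer(1), 2L)
  d0 <- dims[[1]]
  out <- array(0, c(d0[1], sum(cs), d0[3], d0[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, off + seq_len(cs[i]), , ] <- xs[[i]]$v
    off <- off + cs[i]
  }
  node_new(out, xs, function(n) {
    cs2 <- get("cs", environment(n$back))
    off2 <- 0L
    for (i in seq_along(n$ps)) {
      acc_grad(n$ps[[i]], n$g[, off2 + seq_len(cs2[i]), , , drop = FALSE])
      off2 <- off2 + cs2[i]
    }
  })
}

op_upsample2 <- function(x) {
  d <- dim(x$v)
  y <- x$v[, , rep(seq_len(d[3]), each = 2), rep(seq_len(d[4]), each = 2), drop = FALSE]
  node_new(y, list(x), function(n) {
    d2 <- dim(n$ps[[1]]$v)
    g <- n$g
    ih1 <- seq(1L, 2L * d2[3], by = 2L); ih2 <- ih1 + 1L
    iw1 <- seq(1L, 2L * d2[4], by = 2L); iw2 <- iw1 + 1L
    gx <- g[, , ih1, iw1, drop = FALSE] + g[, , ih1, iw2, drop = FALSE] +
      g[, , ih2, iw1, drop = FALSE] + g[, , ih2, iw2, drop = FALSE]
    acc_grad(n$ps[[1]], gx)
  })
}

# multiply feature map by a per-(batch,channel) gate [B,C]
op_scale_channels <- function(x, gate) {
  d <- dim(x$v)
  y <- x$v * as.numeric(gate$v)  # recycles over H,W (b fastest, then c)
  node_new(y, list(x, gate), function(n) {
    xd <- dim(n$ps[[1]]$v)
    acc_grad(n$ps[[1]], n$g * as.numeric(n$ps[[2]]$v))
    gg <- .rowSums(n$g * n$ps[[1]]$v, xd[1] * xd[2], xd[3] * xd[4])
    acc_grad(n$ps[[2]], matrix(gg, xd[1], xd[2]))
  })
}

# multiply feature map by a spatial gate [B,1,H,W]
op_scale_spatial <- function(x, gate) {
  d <- dim(x$v)
  ge <- gate$v[, rep(1L, d[2]), , , drop = FALSE]
  y <- x$v * ge
  node_new(y, list(x, gate), function(n) {
    xd <- dim(n$ps[[1]]$v)
    ge2 <- n$ps[[2]]$v[, rep(1L, xd[2]), , , drop = FALSE]
    acc_grad(n$ps[[1]], n$g * ge2)
    gs <- n$g * n$ps[[1]]$v
    gsum <- colSums(aperm(gs, c(2, 1, 3, 4)))  # [B,H,W]
    acc_grad(n$ps[[2]], array(gsum, c(xd[1], 1, xd[3], xd[4])))
  })
}

op_gap <- function(x) {
  d <- dim(x$v)
  y <- matrix(.rowSums(x$v, d[1] * d[2], d[3] * d[4]) / (d[3] * d[4]), d[1], d[2])
  node_new(y, list(x), function(n) {
    xd <- dim(n$ps[[1]]$v)
    g <- array(as.numeric(n$g) / (xd[3] * xd[4]), xd)  # recycles over H,W
    acc_grad(n$ps[[1]], g)
  })
}

op_gmp <- function(x) {
  d <- dim(x$v)
  m <- matrix(x$v, d[1] * d[2])
  idx <- max.col(m, ties.method = "first")
  y <- matrix(m[cbind(seq_len(nrow(m)), idx)], d[1], d[2])
  node_new(y, list(x), function(n) {
    xd <- dim(n$ps[[1]]$v)
    e <- environment(n$back)
    gx <- matrix(0, xd[1] * xd[2], xd[3] * xd[4])
    ii <- get("idx", e)
    gx[cbind(seq_along(ii), ii)] <- as.numeric(n$g)
    acc_grad(n$ps[[1]], array(gx, xd))
  })
}

op_chan_mean <- function(x) {
  d <- dim(x$v)
  y <- colSums(aperm(x$v, c(2, 1, 3, 4))) / d[2]  # [B,H,W]
  node_new(array(y, c(d[1], 1, d[3], d[4])), list(x), function(n) {
    xd <- dim(n$ps[[1]]$v)
    acc_grad(n$ps[[1]], n$g[, rep(1L, xd[2]), , , drop = FALSE] / xd[2])
  })
}

op_chan_max <- function(x) {
  d <- dim(x$v)
  xm <- matrix(aperm(x$v, c(2, 1, 3, 4)), nrow = d[2])  # C x (B*H*W)
  idx <- max.col(t(xm), ties.method = "first")
  y <- xm[cbind(idx, seq_along(idx))]
  node_new(array(y, c(d[1], 1, d[3], d[4])), list(x), function(n) {
    xd <- dim(n$ps[[1]]$v)
    e <- environment(n$back)
    gm <- matrix(0, xd[2], xd[1] * xd[3] * xd[4])
    ii <- get("idx", e)
    gm[cbind(ii, seq_along(ii))] <- as.numeric(n$g)
    acc_grad(n$ps[[1]], aperm(array(gm, c(xd[2], xd[1], xd[3], xd[4])), c(2, 1, 3, 4)))
  })
}

# attention-weighted spatial pooling: a [B,1,H,W], f [B,C,H,W] -> [B,C]
# v[b,c] = sum_{h,w} a[b,1,h,w] * f[b,c,h,w]  (flattened matrix product)
op_attn_pool <- function(a, f) {
  d <- dim(f$v)
  ae <- a$v[, rep(1L, d[2]), , , drop = FALSE]
  y <- matrix(.rowSums(ae * f$v, d[1] * d[2], d[3] * d[4]), d[1], d[2])
  node_new(y, list(a, f), function(n) {
    fd <- dim(n$ps[[2]]$v)
    g4 <- array(as.numeric(n$g), fd)  # recycles grad over H,W
    ae2 <- n$ps[[1]]$v[, rep(1L, fd[2]), , , drop = FALSE]
    acc_grad(n$ps[[2]], g4 * ae2)
    ga <- colSums(aperm(g4 * n$ps[[2]]$v, c(2, 1, 3, 4)))  # [B,H,W]
    acc_grad(n$ps[[1]], array(ga, c(fd[1], 1, fd[3], fd[4])))
  })
}

# ---- normalisation ---------------------------------------------------------

# expand a [B, G] per-group vector to a per-(b, c) vector (recycled over H, W)
.bg_expand <- function(m, cg) as.vector(m[, rep(seq_len(ncol(m)), each = cg)])

op_group_norm <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x$v)
  B <- d[1]; C <- d[2]; HW <- d[3] * d[4]
  cg <- C %/% groups
  n_el <- cg * HW
  agg <- kronecker(diag(groups), rep(1, cg))      # [C x G] channel->group fold
  ss <- bc_sums(x$v, x$v, B * C)
  mu <- (matrix(ss$s, B, C) %*% agg) / n_el       # [B, G]
  va <- (matrix(ss$sx, B, C) %*% agg) / n_el - mu^2
  sd_inv <- 1 / sqrt(va + eps)
  mu_e <- .bg_expand(mu, cg)                      # per (b, c)
  si_e <- .bg_expand(sd_inv, cg)
  gam_e <- rep(gamma$v, each = B)
  y <- bc_affine(x$v, si_e * gam_e, rep(beta$v, each = B) - mu_e * si_e * gam_e)
  node_new(y, list(x, gamma, beta), function(n) {
    e <- environment(n$back)
    d2 <- get("d", e); B2 <- d2[1]; C2 <- d2[2]
    cg2 <- get("cg", e); G2 <- get("groups", e); nel <- get("n_el", e)
    si2 <- get("si_e", e); mu2 <- get("mu_e", e); agg2 <- get("agg", e)
    g <- n$g
    xv <- n$ps[[1]]$v
    sgs <- bc_sums(g, xv, B2 * C2)
    sgxh_bc <- (sgs$sx - mu2 * sgs$s) * si2       # per (b,c) sum of g*xhat
    acc_grad(n$ps[[2]], .colSums(sgxh_bc, B2, C2))
    acc_grad(n$ps[[3]], .colSums(sgs$s, B2, C2))
    if (isTRUE(n$ps[[1]]$rg)) {
      gam <- rep(n$ps[[2]]$v, each = B2)
      # per-group means of g*gamma and g*gamma*xhat
      mg <- .bg_expand((matrix(gam * sgs$s, B2, C2) %*% agg2) / nel, cg2)
      mgxh <- .bg_expand((matrix(gam * sgxh_bc, B2, C2) %*% agg2) / nel, cg2)
      gx <- bc_lincomb(g, xv, si2 * gam, -si2^2 * mgxh,
                       si2 * (-mg + mu2 * si2 * mgxh))
      acc_grad(n$ps[[1]], gx)
    }
  })
}

# fold a per-(b,c) vector into per-channel sums
.fold_b <- function(s, B, C) .colSums(s, B, C)

op_batch_norm <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(x$v)
  B <- d[1]; C <- d[2]
  n_el <- B * d[3] * d[4]
  if (training) {
    ss <- bc_sums(x$v, x$v, B * C)
    mu <- .fold_b(ss$s, B, C) / n_el
    va <- .fold_b(ss$sx, B, C) / n_el - mu^2
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    state$rv <- (1 - momentum) * state$rv + momentum * va * n_el / max(1, n_el - 1)
  } else {
    mu <- state$rm
    va <- state$rv
  }
  sd_inv <- 1 / sqrt(va + eps)
  # y = x * s + t with per-(b,c) recycling over H,W
  s <- rep(gamma$v * sd_inv, each = B)
  t_ <- rep(beta$v - gamma$v * sd_inv * mu, each = B)
  y <- bc_affine(x$v, s, t_)
  node_new(y, list(x, gamma, beta), function(n) {
    e <- environment(n$back)
    d2 <- get("d", e); B2 <- d2[1]; C2 <- d2[2]
    si <- get("sd_inv", e); tr <- get("training", e)
    mu2 <- get("mu", e); nel <- get("n_el", e)
    g <- n$g
    xv <- n$ps[[1]]$v
    # per-channel sums of g and g*x in one pass; sum g*xhat follows by algebra
    sgs <- bc_sums(g, xv, B2 * C2)
    sg <- .fold_b(sgs$s, B2, C2)
    sgx <- .fold_b(sgs$sx, B2, C2)
    sgxh <- (sgx - mu2 * sg) * si
    acc_grad(n$ps[[2]], sgxh)
    acc_grad(n$ps[[3]], sg)
    if (isTRUE(n$ps[[1]]$rg)) {
      gam <- n$ps[[2]]$v
      if (tr) {
        mg <- sg / nel
        mgxh <- sgxh / nel
        # gx = si*gamma*(g - mg - xhat*mgxh) = a*g + b*x + c per channel
        a <- si * gam
        bb <- -si^2 * gam * mgxh
        cc <- si * gam * (-mg + mu2 * si * mgxh)
        gx <- bc_lincomb(g, xv, rep(a, each = B2), rep(bb, each = B2),
                         rep(cc, each = B2))
      } else {
        sc <- rep(si * gam, each = B2)
        gx <- bc_affine(g, sc, numeric(length(sc)))
      }
      acc_grad(n$ps[[1]], gx)
    }
  })
}

# ---- dense / row-wise ops --------------------------------------------------

op_linear <- function(x, w, b = NULL) {
  y <- x$v %*% w$v
  if (!is.null(b)) y <- sweep(y, 2, b$v, "+")
  ps <- if (is.null(b)) list(x, w) else list(x, w, b)
  node_new(y, ps, function(n) {
    xn <- n$ps[[1]]; wn <- n$ps[[2]]
    if (isTRUE(xn$rg)) acc_grad(xn, n$g %*% t(wn$v))
    acc_grad(wn, t(xn$v) %*% n$g)
    if (length(n$ps) == 3L) acc_grad(n$ps[[3]], colSums(n$g))
  })
}

# flatten [B,C,H,W] into prediction rows [B*H*W, C]
# row index r = (b-1)*H*W + (h-1)*W + w
op_flatten_preds <- function(x) {
  d <- dim(x$v)
  y <- matrix(aperm(x$v, c(4, 3, 1, 2)), nrow = d[1] * d[3] * d[4], ncol = d[2])
  node_new(y, list(x), function(n) {
    d2 <- dim(n$ps[[1]]$v)
    g <- array(n$g, c(d2[4], d2[3], d2[1], d2[2]))
    acc_grad(n$ps[[1]], aperm(g, c(3, 4, 2, 1)))
  })
}

op_rows <- function(x, idx) {
  node_new(x$v[idx, , drop = FALSE], list(x), function(n) {
    d2 <- dim(n$ps[[1]]$v)
    gx <- matrix(0, d2[1], d2[2])
    ii <- get("idx", environment(n$back))
    for (k in seq_along(ii)) gx[ii[k], ] <- gx[ii[k], ] + n$g[k, ]
    acc_grad(n$ps[[1]], gx)
  })
}

op_vcat <- function(xs) {
  ns <- vapply(xs, function(x) nrow(x$v), integer(1))
  node_new(do.call(rbind, lapply(xs, vl)), xs, function(n) {
    ns2 <- get("ns", environment(n$back))
    off <- 0L
    for (i in seq_along(n$ps)) {
      acc_grad(n$ps[[i]], n$g[off + seq_len(ns2[i]), , drop = FALSE])
      off <- off + ns2[i]
    }
  })
}

# gather scalar elements x[cbind(r, c)] from a matrix node
op_gather <- function(x, rc) {
  node_new(x$v[rc], list(x), function(n) {
    d2 <- dim(n$ps[[1]]$v)
    gx <- matrix(0, d2[1], d2[2])
    rc2 <- get("rc", environment(n$back))
    for (k in seq_len(nrow(rc2))) gx[rc2[k, 1], rc2[k, 2]] <- gx[rc2[k, 1], rc2[k, 2]] + n$g[k]
    acc_grad(n$ps[[1]], gx)
  })
}

row_max <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

op_softmax_rows <- function(x) {
  z <- x$v - row_max(x$v)
  ez <- exp(z)
  y <- ez / rowSums(ez)
  node_new(y, list(x), function(n) {
    yy <- get("y", environment(n$back))
    dot <- rowSums(n$g * yy)
    acc_grad(n$ps[[1]], yy * (n$g - dot))
  })
}

# y = x %*% v for a constant vector v (e.g. expectation over DFL bins)
op_matvec_const <- function(x, v) {
  node_new(as.numeric(x$v %*% v), list(x), function(n)
    acc_grad(n$ps[[1]], outer(as.numeric(n$g), get("v", environment(n$back)))))
}

# summed binary cross-entropy with logits against constant targets
op_bce_logits <- function(logits, targets) {
  l <- logits$v; t <- targets
  v <- sum(pmax(l, 0) - l * t + log1p(exp(-abs(l))))
  node_new(v, list(logits), function(n) {
    e <- environment(n$back)
    ll <- get("l", e); tt <- get("t", e)
    acc_grad(n$ps[[1]], as.numeric(n$g) * (1 / (1 + exp(-ll)) - tt))
  })
}

# distribution focal loss rows: logits [M,K], continuous targets t in [0, K-1]
# returns per-row losses [M]
op_dfl <- function(logits, t) {
  K <- ncol(logits$v)
  tl <- pmin(floor(t), K - 2)
  th <- tl + 1
  wl <- th - t
  wh <- t - tl
  z <- logits$v - row_max(logits$v)
  lse <- log(rowSums(exp(z)))
  logp <- z - lse
  M <- nrow(logits$v)
  v <- -(wl * logp[cbind(seq_len(M), tl + 1)] + wh * logp[cbind(seq_len(M), th + 1)])
  node_new(v, list(logits), function(n) {
    e <- environment(n$back)
    sm <- exp(get("logp", e))
    tgt <- matrix(0, get("M", e), get("K", e))
    tgt[cbind(seq_len(get("M", e)), get("tl", e) + 1)] <- get("wl", e)
    tgt[cbind(seq_len(get("M", e)), get("th", e) + 1)] <-
      tgt[cbind(seq_len(get("M", e)), get("th", e) + 1)] + get("wh", e)
    acc_grad(n$ps[[1]], (sm - tgt) * as.numeric(n$g))
  })
}
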
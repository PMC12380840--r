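# Minimal reverse-mode autodiff tape over dense matrices.
#
# A tensor node is an environment holding `v` (numeric matrix, tokens x
# channels; scalars are 1x1), `grad`, `parents`, a backward closure `bw`
# mapping the upstream gradient to a list of parent gradients, a creation
# `id` (tape order) and `rg` (requires-grad). Feature maps are stored as
# [H*W, D] matrices in row-major token order (token t = (i-1)*W + j);
# spatial dims travel alongside as plain integers. When gradients are
# disabled (evaluation mode) ops return detached leaves, so no tape is built.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L
.ad$grad <- TRUE

ad_leaf <- function(v, rg = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- list()
  e$bw <- NULL
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  e$rg <- rg && .ad$grad
  class(e) <- "adt"
  e
}

ad_const <- function(v) ad_leaf(v, rg = FALSE)

ad_op <- function(v, parents, bw) {
  if (!.ad$grad || !any(vapply(parents, function(p) p$rg, FALSE)))
    return(ad_leaf(v, rg = FALSE))
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  e$rg <- TRUE
  class(e) <- "adt"
  e
}

# Evaluate `expr` with the tape disabled (inference mode).
ad_no_grad <- function(expr) {
  old <- .ad$grad
  .ad$grad <- FALSE
  on.exit(.ad$grad <- old)
  expr
}

# Reverse pass from a (scalar) root. Gradients accumulate into node$grad.
ad_backward <- function(root, g = NULL) {
  if (is.null(g)) g <- matrix(1, nrow(root$v), ncol(root$v))
  nodes <- vector("list", 512L)
  nn <- 0L
  stack <- vector("list", 512L)
  sp <- 1L
  stack[[1L]] <- root
  seen <- new.env(hash = TRUE, parent = emptyenv())
  while (sp > 0L) {
    nd <- stack[[sp]]
    sp <- sp - 1L
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- nd
    for (p in nd$parents) {
      if (!p$rg) next
      sp <- sp + 1L
      if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
      stack[[sp]] <- p
    }
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, 0L)
  nodes <- nodes[order(ids, decreasing = TRUE)]
  root$grad <- if (is.null(root$grad)) g else root$grad + g
  for (nd in nodes) {
    if (is.null(nd$bw) || is.null(nd$grad)) next
    gs <- nd$bw(nd$grad)
    ps <- nd$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!p$rg || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    nd$bw <- NULL # free closure memory as we go
    if (length(nd$parents)) nd$grad <- NULL
    nd$parents <- list()
  }
  invisible(root)
}

ad_zero_grad <- function(x) {
  x$grad <- NULL
  invisible(x)
}

# ---- elementwise arithmetic (shapes must match) -------------------------

ad_add <- function(a, b)
  ad_op(a$v + b$v, list(a, b), function(g) list(g, g))

ad_sub <- function(a, b)
  ad_op(a$v - b$v, list(a, b), function(g) list(g, -g))

ad_mul <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av / bv, list(a, b), function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_scale <- function(a, k)
  ad_op(a$v * k, list(a), function(g) list(g * k))

ad_addc <- function(a, k)
  ad_op(a$v + k, list(a), function(g) list(g))

ad_neg <- function(a) ad_scale(a, -1)

ad_exp <- function(a) {
  ev <- exp(a$v)
  ad_op(ev, list(a), function(g) list(g * ev))
}

# ---- activations --------------------------------------------------------

ad_relu <- function(a) {
  m <- a$v > 0
  ad_op(a$v * m, list(a), function(g) list(g * m))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$v))
  ad_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_silu <- function(a) {
  av <- a$v
  s <- 1 / (1 + exp(-av))
  ad_op(av * s, list(a), function(g) list(g * s * (1 + av * (1 - s))))
}

ad_softplus <- function(a) {
  av <- a$v
  v <- pmax(av, 0) + log1p(exp(-abs(av))) # stable softplus
  s <- 1 / (1 + exp(-av))
  ad_op(v, list(a), function(g) list(g * s))
}

# ---- linear algebra -----------------------------------------------------

ad_matmul <- function(a, b) {
  av <- a$v; bv <- b$v
  ad_op(av %*% bv, list(a, b),
        function(g) list(g %*% t(bv), crossprod(av, g)))
}

# add a length-C row vector to every row of an [L, C] matrix
row_bcast_add <- function(v, b) v + rep(b, each = nrow(v))
row_bcast_mul <- function(v, b) v * rep(b, each = nrow(v))

# X [L, Din] %*% W [Din, Dout] + bias [1, Dout]
ad_linear <- function(x, w, b = NULL) {
  xv <- x$v; wv <- w$v
  v <- xv %*% wv
  if (is.null(b))
    return(ad_op(v, list(x, w),
                 function(g) list(tcrossprod(g, wv), crossprod(xv, g))))
  v <- row_bcast_add(v, as.numeric(b$v))
  ad_op(v, list(x, w, b), function(g)
    list(tcrossprod(g, wv), crossprod(xv, g), matrix(colSums(g), 1)))
}

ad_add_bias <- function(x, b) {
  v <- row_bcast_add(x$v, as.numeric(b$v))
  ad_op(v, list(x, b), function(g) list(g, matrix(colSums(g), 1)))
}

# broadcast multiplies: row vector w [1, C] or column vector s [L, 1]
ad_bmul_row <- function(x, w) {
  xv <- x$v; wv <- as.numeric(w$v)
  ad_op(row_bcast_mul(xv, wv), list(x, w), function(g)
    list(row_bcast_mul(g, wv), matrix(colSums(g * xv), 1)))
}

ad_bmul_col <- function(x, s) {
  xv <- x$v; sv <- as.numeric(s$v)
  ad_op(xv * sv, list(x, s), function(g)
    list(g * sv, matrix(rowSums(g * xv), ncol = 1)))
}

# ---- reductions ---------------------------------------------------------

ad_sum <- function(x) {
  d <- dim(x$v)
  ad_op(matrix(sum(x$v), 1, 1), list(x),
        function(g) list(matrix(g[1], d[1], d[2])))
}

ad_mean <- function(x) {
  d <- dim(x$v)
  n <- prod(d)
  ad_op(matrix(mean(x$v), 1, 1), list(x),
        function(g) list(matrix(g[1] / n, d[1], d[2])))
}

# global average pool over tokens: [L, C] -> [1, C]
ad_gap <- function(x) {
  L <- nrow(x$v)
  ad_op(matrix(colMeans(x$v), 1), list(x),
        function(g) list(matrix(g / L, L, length(g), byrow = TRUE)))
}

# channelwise mean / max maps: [L, C] -> [L, 1]
ad_chan_mean <- function(x) {
  C <- ncol(x$v)
  ad_op(matrix(rowMeans(x$v), ncol = 1), list(x),
        function(g) list(matrix(g / C, nrow(x$v), C)))
}

ad_chan_max <- function(x) {
  xv <- x$v
  idx <- max.col(xv, ties.method = "first")
  L <- nrow(xv)
  v <- matrix(xv[cbind(seq_len(L), idx)], ncol = 1)
  ad_op(v, list(x), function(g) {
    gx <- matrix(0, L, ncol(xv))
    gx[cbind(seq_len(L), idx)] <- g
    list(gx)
  })
}

ad_cbind <- function(a, b) {
  ca <- ncol(a$v)
  ad_op(cbind(a$v, b$v), list(a, b), function(g)
    list(g[, seq_len(ca), drop = FALSE], g[, -seq_len(ca), drop = FALSE]))
}

# ---- reorderings --------------------------------------------------------

# bijective row permutation: out[r, ] = x[idx[r], ]
ad_rows <- function(x, idx) {
  ad_op(x$v[idx, , drop = FALSE], list(x), function(g) {
    gx <- g
    gx[idx, ] <- g
    list(gx)
  })
}

# duplicate-free row selection: out[r, ] = x[idx[r], ], idx a subset
ad_select_rows <- function(x, idx) {
  d <- dim(x$v)
  ad_op(x$v[idx, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, d[1], d[2])
    gx[idx, ] <- g
    list(gx)
  })
}

# bijective element gather into a new shape: out = matrix(x[idx], nr, nc)
ad_gather <- function(x, idx, nr, nc) {
  d <- dim(x$v)
  ad_op(matrix(x$v[idx], nr, nc), list(x), function(g) {
    gx <- numeric(prod(d))
    gx[idx] <- g
    list(matrix(gx, d[1], d[2]))
  })
}

# pixel-shuffle index table: maps a [H*W, r^2*D2] token matrix to a
# [rH*rW, D2] matrix where each token's channels fill an r x r spatial
# block (sub-positions in row-major order). Bijective; memoized.
.shuffle_memo <- new.env(hash = TRUE, parent = emptyenv())

pixel_shuffle_index <- function(H, W, r, D2) {
  key <- paste(H, W, r, D2, sep = "_")
  hit <- .shuffle_memo[[key]]
  if (!is.null(hit)) return(hit)
  Hr <- r * H
  Wr <- r * W
  L2 <- Hr * Wr
  L <- H * W
  i2 <- rep(seq_len(Hr), each = Wr)
  j2 <- rep.int(seq_len(Wr), Hr)
  i <- (i2 - 1L) %/% r + 1L
  j <- (j2 - 1L) %/% r + 1L
  di <- i2 - (i - 1L) * r
  dj <- j2 - (j - 1L) * r
  blk <- (di - 1L) * r + dj
  t <- (i - 1L) * W + j
  base <- (blk - 1L) * D2
  idx <- integer(L2 * D2)
  for (c in seq_len(D2))
    idx[((c - 1L) * L2 + 1L):(c * L2)] <- t + (base + c - 1L) * L
  .shuffle_memo[[key]] <- idx
  idx
}

# ---- normalization / softmax -------------------------------------------

# Layer normalization across channels per token, with affine gamma/beta [1, C].
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$v
  C <- ncol(xv)
  if (length(gamma$v) != C || length(beta$v) != C)
    stop("layer norm affine size mismatch: ", length(gamma$v), " vs ", C)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$v)
  v <- row_bcast_add(row_bcast_mul(xhat, gv), as.numeric(beta$v))
  ad_op(v, list(x, gamma, beta), function(g) {
    dxhat <- row_bcast_mul(g, gv)
    m1 <- rowSums(dxhat)
    m2 <- rowSums(dxhat * xhat)
    gx <- (inv / C) * (C * dxhat - m1 - xhat * m2)
    list(gx, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

row_max <- function(m) do.call(pmax, lapply(seq_len(ncol(m)), function(j) m[, j]))

# row-wise softmax
ad_softmax <- function(x) {
  xv <- x$v
  m <- row_max(xv)
  e <- exp(xv - m)
  p <- e / rowSums(e)
  ad_op(p, list(x), function(g) {
    list(p * (g - rowSums(g * p)))
  })
}

# fused mean cross-entropy with (possibly soft) target probabilities;
# `y` is a constant matrix whose rows sum to 1.
ad_ce <- function(logits, y) {
  xv <- logits$v
  L <- nrow(xv)
  m <- row_max(xv)
  e <- exp(xv - m)
  se <- rowSums(e)
  logp <- (xv - m) - log(se)
  v <- matrix(-sum(y * logp) / L, 1, 1)
  p <- e / se
  ad_op(v, list(logits), function(g) {
    list((g[1] / L) * (p * rowSums(y) - y))
  })
}

# ---- convolutions -------------------------------------------------------

# memoized kernel-offset index tables for same-padded convolution
.conv_memo <- new.env(hash = TRUE, parent = emptyenv())

conv_offsets <- function(H, W, k, dil = 1L) {
  key <- paste(H, W, k, dil, sep = "_")
  hit <- .conv_memo[[key]]
  if (!is.null(hit)) return(hit)
  c0 <- (k - 1L) %/% 2L
  ii <- rep(seq_len(H), each = W)
  jj <- rep.int(seq_len(W), H)
  out <- vector("list", k * k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      di <- (a - 1L - c0) * dil
      dj <- (b - 1L - c0) * dil
      si <- ii + di
      sj <- jj + dj
      ok <- si >= 1L & si <= H & sj >= 1L & sj <= W
      out[[(a - 1L) * k + b]] <-
        list(dst = which(ok), src = ((si - 1L) * W + sj)[ok])
    }
  }
  .conv_memo[[key]] <- out
  out
}

# dense 2D convolution, stride 1, zero same-padding; w is [k, k, Cin, Cout]
ad_conv2d <- function(x, w, b = NULL, H, W, dil = 1L) {
  wv <- w$v
  k <- dim(wv)[1]
  Cin <- dim(wv)[3]
  Cout <- dim(wv)[4]
  L <- H * W
  offs <- conv_offsets(H, W, k, dil)
  xv <- x$v
  v <- matrix(0, L, Cout)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    o <- offs[[(a - 1L) * k + bb]]
    Wm <- matrix(wv[a, bb, , ], Cin, Cout)
    if (length(o$dst) == L) v <- v + xv[o$src, , drop = FALSE] %*% Wm
    else v[o$dst, ] <- v[o$dst, , drop = FALSE] +
        xv[o$src, , drop = FALSE] %*% Wm
  }
  parents <- list(x, w)
  if (!is.null(b)) {
    v <- row_bcast_add(v, as.numeric(b$v))
    parents <- list(x, w, b)
  }
  ad_op(v, parents, function(g) {
    gx <- matrix(0, L, Cin)
    gw <- array(0, dim(wv))
    for (a in seq_len(k)) for (bb in seq_len(k)) {
      o <- offs[[(a - 1L) * k + bb]]
      Wm <- matrix(wv[a, bb, , ], Cin, Cout)
      gd <- if (length(o$dst) == L) g else g[o$dst, , drop = FALSE]
      gw[a, bb, , ] <- crossprod(xv[o$src, , drop = FALSE], gd)
      gx[o$src, ] <- gx[o$src, , drop = FALSE] + tcrossprod(gd, Wm)
    }
    out <- list(gx, gw)
    if (!is.null(b)) out[[3]] <- matrix(colSums(g), 1)
    out
  })
}

# depthwise k x k convolution (per-channel), zero same-padding; w is [k, k, C]
ad_dwconv2d <- function(x, w, b = NULL, H, W, dil = 1L) {
  wv <- w$v
  k <- dim(wv)[1]
  C <- dim(wv)[3]
  L <- H * W
  offs <- conv_offsets(H, W, k, dil)
  xv <- x$v
  v <- matrix(0, L, C)
  for (a in seq_len(k)) for (bb in seq_len(k)) {
    o <- offs[[(a - 1L) * k + bb]]
    wk <- wv[a, bb, ]
    if (length(o$dst) == L)
      v <- v + row_bcast_mul(xv[o$src, , drop = FALSE], wk)
    else v[o$dst, ] <- v[o$dst, , drop = FALSE] +
        row_bcast_mul(xv[o$src, , drop = FALSE], wk)
  }
  parents <- list(x, w)
  if (!is.null(b)) {
    v <- row_bcast_add(v, as.numeric(b$v))
    parents <- list(x, w, b)
  }
  ad_op(v, parents, function(g) {
    gx <- matrix(0, L, C)
    gw <- array(0, dim(wv))
    for (a in seq_len(k)) for (bb in seq_len(k)) {
      o <- offs[[(a - 1L) * k + bb]]
      wk <- wv[a, bb, ]
      gd <- if (length(o$dst) == L) g else g[o$dst, , drop = FALSE]
      xs <- xv[o$src, , drop = FALSE]
      gw[a, bb, ] <- colSums(xs * gd)
      gx[o$src, ] <- gx[o$src, , drop = FALSE] + row_bcast_mul(gd, wk)
    }
    out <- list(gx, gw)
    if (!is.null(b)) out[[3]] <- matrix(colSums(g), 1)
    out
  })
}

# ---- parameter-tree helpers --------------------------------------------

# wrap a nested list of numeric arrays into gradient-tracking leaves
wrap_params <- function(p) {
  if (is.list(p)) lapply(p, wrap_params) else ad_leaf(p, rg = TRUE)
}

# extract accumulated gradients (zeros where a parameter was unused)
grad_tree <- function(wp) {
  if (is.list(wp)) return(lapply(wp, grad_tree))
  g <- wp$grad
  if (is.null(g)) {
    g <- wp$v
    g[] <- 0
  }
  if (!identical(dim(g), dim(wp$v))) dim(g) <- dim(wp$v)
  g
}
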
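# 2D selective scan (SS2D): directional sequence expansion, the selective
# state-space recurrence (S6), and merging scanned sequences back to a map.
#
# Feature maps are [H, W, D] arrays at the module boundary; internally they
# are [H*W, D] token matrices in row-major order (token t = (i-1)*W + j).

#' Flatten a feature map to a token matrix (row-major)
#' @param x numeric array `[H, W, D]`
#' @return numeric matrix `[H*W, D]`
#' @keywords internal
map_to_tokens <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' @keywords internal
tokens_to_map <- function(m, H, W) {
  aperm(array(m, c(W, H, ncol(m))), c(2, 1, 3))
}

# Traversal orders of the four scan paths; each entry is the vector of
# row-major token indices in visit order.
scan_orders <- function(H, W) {
  L <- H * W
  row_fwd <- seq_len(L)
  col_fwd <- as.integer(outer((0L:(H - 1L)) * W, 1L:W, "+")) # col-major walk
  list(row_fwd = row_fwd,
       row_rev = rev(row_fwd),
       col_fwd = col_fwd,
       col_rev = rev(col_fwd))
}

#' Expand a feature map into four directional scan sequences
#'
#' Decomposes a `[H, W, D]` feature map into four 1D token sequences, one per
#' traversal direction (row-major forward/reverse, column-major
#' forward/reverse). The expansion is a lossless reordering: applying
#' [scan_merge()] with identity per-sequence transforms recovers `4 * x`.
#'
#' @param x numeric array `[H, W, D]` with `H, W, D >= 1`.
#' @return An object of class `directional_sequences`: a list with `seqs`
#'   (list of four `[H*W, D]` matrices), `order` (the token visit order of
#'   each path), `directions`, and the spatial dims `H`, `W`, `D`.
#' @examples
#' x <- array(1:8, c(2, 2, 2))
#' s <- scan_expand(x)
#' names(s$seqs)
#' @export
scan_expand <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a [H, W, D] array")
  d <- dim(x)
  if (any(d < 1L) || prod(d[1:2]) < 1L) stop("empty input")
  m <- map_to_tokens(x)
  ord <- scan_orders(d[1], d[2])
  structure(list(
    seqs = lapply(ord, function(o) m[o, , drop = FALSE]),
    order = ord,
    directions = names(ord),
    H = d[1], W = d[2], D = d[3]
  ), class = "directional_sequences")
}

#' Merge scanned directional sequences back into a feature map
#'
#' Each sequence is inverse-permuted to spatial layout and the four maps are
#' summed elementwise.
#'
#' @param ys a `directional_sequences` object (possibly with transformed
#'   `seqs`, e.g. after [selective_scan()]).
#' @return numeric array `[H, W, D]`.
#' @export
scan_merge <- function(ys) {
  if (!inherits(ys, "directional_sequences"))
    stop("expected a directional_sequences object")
  L <- ys$H * ys$W
  acc <- matrix(0, L, ys$D)
  for (k in seq_along(ys$seqs)) {
    s <- ys$seqs[[k]]
    if (nrow(s) != L || ncol(s) != ys$D)
      stop("sequence length mismatch: expected ", L, " x ", ys$D)
    back <- matrix(0, L, ys$D)
    back[ys$order[[k]], ] <- s
    acc <- acc + back
  }
  tokens_to_map(acc, ys$H, ys$W)
}

#' Selective state-space (S6) recurrence over one token sequence
#'
#' Runs the input-dependent linear recurrence
#' \deqn{h_t = \bar A_t h_{t-1} + \bar B_t x_t, \quad
#'       y_t = C_t \cdot h_t + D_{skip} x_t}
#' with zero-order-hold discretization \eqn{\bar A_t = \exp(\delta_t A)} and
#' \eqn{\bar B_t = \delta_t B_t}, state initialized at zero. The transition
#' matrix is parameterized as \eqn{A = -\exp(A_{log})} so its entries are
#' negative and the discretized transition lies in (0, 1].
#'
#' @param seq numeric matrix `[L, D]`, the token sequence.
#' @param params list with `A_log` `[D, N]`, `D_skip` length-`D`,
#'   `delta` `[L, D]` (positive discretization steps), `B` `[L, N]` and
#'   `C` `[L, N]` (per-step input/output projections).
#' @return numeric matrix `[L, D]` of outputs.
#' @export
selective_scan <- function(seq, params) {
  seq <- as.matrix(seq)
  L <- nrow(seq); D <- ncol(seq)
  A_log <- as.matrix(params$A_log)
  N <- ncol(A_log)
  delta <- matrix(params$delta, L, D)
  if (any(delta <= 0)) stop("invalid discretization step")
  B <- matrix(params$B, L, N)
  Cm <- matrix(params$C, L, N)
  Dskip <- rep_len(as.numeric(params$D_skip), D)
  A <- -exp(A_log)
  ss_scan_fwd(seq, delta, A, B, Cm, Dskip, FALSE)$y
}

# Brute-force unrolled-sum oracle for the recurrence:
#   h_t = sum_{s<=t} (prod_{r=s+1..t} Abar_r) Bbar_s x_s
# Used as the independent reference in tests; O(L^2) on purpose.
selective_scan_ref <- function(seq, params) {
  seq <- as.matrix(seq)
  L <- nrow(seq); D <- ncol(seq)
  A_log <- as.matrix(params$A_log)
  N <- ncol(A_log)
  delta <- matrix(params$delta, L, D)
  B <- matrix(params$B, L, N)
  Cm <- matrix(params$C, L, N)
  Dskip <- rep_len(as.numeric(params$D_skip), D)
  A <- -exp(A_log)
  y <- matrix(0, L, D)
  for (t in seq_len(L)) {
    for (d in seq_len(D)) {
      acc <- 0
      for (n in seq_len(N)) {
        h <- 0
        for (s in seq_len(t)) {
          prodA <- 1
          r <- s + 1L
          while (r <= t) {
            prodA <- prodA * exp(delta[r, d] * A[d, n])
            r <- r + 1L
          }
          h <- h + prodA * delta[s, d] * B[s, n] * seq[s, d]
        }
        acc <- acc + Cm[t, n] * h
      }
      y[t, d] <- acc + Dskip[d] * seq[t, d]
    }
  }
  y
}

#' 2D selective scan over a feature map
#'
#' Expands the map along the four traversal directions, runs the selective
#' recurrence independently on each sequence (with per-direction parameters),
#' and merges the scanned outputs back by inverse permutation and summation.
#' Output shape equals input shape.
#'
#' @param x numeric array `[H, W, D]`.
#' @param params a list of four parameter sets as in [selective_scan()], one
#'   per direction (recycled if a single set is given, i.e. tied parameters).
#' @return numeric array `[H, W, D]`.
#' @export
ss2d <- function(x, params) {
  s <- scan_expand(x)
  if (!is.null(params$A_log)) params <- list(params) # single set -> tied
  params <- rep_len(params, length(s$seqs))
  s$seqs <- lapply(seq_along(s$seqs), function(k)
    selective_scan(s$seqs[[k]], params[[k]]))
  scan_merge(s)
}

# ---- autodiff path ------------------------------------------------------

# selective scan as a tape op; parents: u, delta, A, B, C, Dskip([1,D])
ad_selective_scan <- function(u, delta, A, B, Cc, Dskip) {
  need <- .ad$grad &&
    any(vapply(list(u, delta, A, B, Cc, Dskip), function(p) p$rg, FALSE))
  res <- ss_scan_fwd(u$v, delta$v, A$v, B$v, Cc$v, as.numeric(Dskip$v), need)
  if (!need) return(ad_leaf(res$y, rg = FALSE))
  uv <- u$v; dv <- delta$v; Av <- A$v; Bv <- B$v; Cv <- Cc$v
  Dv <- as.numeric(Dskip$v); Hst <- res$H
  ad_op(res$y, list(u, delta, A, B, Cc, Dskip), function(g) {
    bb <- ss_scan_bwd(g, uv, dv, Av, Bv, Cv, Dv, Hst)
    list(bb$gu, bb$gdelta, bb$gA, bb$gB, bb$gC, matrix(bb$gD, 1))
  })
}

# Parameters of an input-dependent SS2D layer on D channels, N states.
# Per direction: delta/B/C produced by learned linear maps of the token,
# delta through a low-rank projection (rank ~ D/16, the usual selective-SSM
# economy) and softplus; A stored as A_log with the S4D-real init
# log(1..N); D_skip initialized at 1. `tied` shares one set across paths.
init_ss2d <- function(D, N = 16L, tied = FALSE, std = 0.02) {
  R <- max(1L, as.integer(ceiling(D / 16)))
  one <- function() {
    dt <- stats::runif(D, 0.001, 0.1) # target initial step sizes
    list(
      A_log = matrix(log(seq_len(N)), D, N, byrow = TRUE),
      D_skip = matrix(1, 1, D),
      w_delta_down = trunc_normal(c(D, R), std),
      w_delta_up = trunc_normal(c(R, D), std),
      b_delta = matrix(log(expm1(dt)), 1, D), # softplus^{-1}(dt)
      w_B = trunc_normal(c(D, N), std),
      w_C = trunc_normal(c(D, N), std)
    )
  }
  ps <- if (tied) rep(list(one()), 4L) else list(one(), one(), one(), one())
  names(ps) <- c("row_fwd", "row_rev", "col_fwd", "col_rev")
  ps
}

# forward of the SS2D layer on a token-matrix node; wp = wrapped init_ss2d;
# K restricts to the first K of the four scan paths
fw_ss2d <- function(x, H, W, wp, K = 4L) {
  ord <- scan_orders(H, W)[seq_len(K)]
  L <- H * W
  acc <- NULL
  for (k in seq_along(ord)) {
    p <- wp[[k]]
    u <- ad_rows(x, ord[[k]])
    delta <- ad_softplus(ad_linear(ad_matmul(u, p$w_delta_down),
                                   p$w_delta_up, p$b_delta))
    B <- ad_matmul(u, p$w_B)
    Cc <- ad_matmul(u, p$w_C)
    A <- ad_neg(ad_exp(p$A_log))
    y <- ad_selective_scan(u, delta, A, B, Cc, p$D_skip)
    inv <- integer(L)
    inv[ord[[k]]] <- seq_len(L)
    back <- ad_rows(y, inv)
    acc <- if (is.null(acc)) back else ad_add(acc, back)
  }
  acc
}

# truncated-normal initializer (clipped at 2 sd)
trunc_normal <- function(dm, std = 0.02) {
  v <- stats::rnorm(prod(dm), 0, std)
  v <- pmin(pmax(v, -2 * std), 2 * std)
  array(v, dm)
}
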
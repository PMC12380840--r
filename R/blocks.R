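# Composite blocks: depthwise-separable convolution, squeeze-excitation,
# the visual state-space (VSS) block, the multiscale convolution set (MSDC),
# the multiscale VSS encoder block, the dilated-attention bottleneck (MSAA)
# and the channel-aware attentional skip (CAVSS).
#
# Each block has an `init_*` constructor drawing parameters from the current
# RNG and a tape-level `fw_*` forward; the exported functions run the forward
# in inference mode on [H, W, D] arrays.

#' VSS block configuration
#'
#' @param expand inner expansion ratio of the block's first linear layer.
#' @param dw_kernel depthwise convolution kernel size (odd).
#' @param se_reduction squeeze-excitation bottleneck reduction ratio.
#' @param state_size state dimension N of the selective scan.
#' @param scan_paths number of scan directions used (1..4).
#' @param tied_directions share one parameter set across scan directions.
#' @export
vss_config <- function(expand = 2L, dw_kernel = 3L, se_reduction = 8L,
                       state_size = 16L, scan_paths = 4L,
                       tied_directions = FALSE) {
  stopifnot(expand >= 1, dw_kernel %% 2 == 1, se_reduction >= 1,
            state_size >= 1, scan_paths >= 1, scan_paths <= 4)
  list(expand = as.integer(expand), dw_kernel = as.integer(dw_kernel),
       se_reduction = as.integer(se_reduction),
       state_size = as.integer(state_size),
       scan_paths = as.integer(scan_paths),
       tied_directions = isTRUE(tied_directions))
}

#' Multiscale convolution set configuration
#' @param kernels odd kernel sizes of the parallel branches.
#' @export
msdc_config <- function(kernels = c(1L, 3L, 5L)) {
  if (any(kernels %% 2 == 0)) stop("kernel sizes must be odd")
  list(kernels = as.integer(kernels))
}

#' Bottleneck attention (MSAA) configuration
#' @param dilations dilation rates of the parallel 3x3 branches.
#' @param gate_kernel spatial-gate convolution kernel size (odd).
#' @export
msaa_config <- function(dilations = c(1L, 3L, 5L), gate_kernel = 7L) {
  stopifnot(all(dilations >= 1), gate_kernel %% 2 == 1)
  list(dilations = as.integer(dilations), gate_kernel = as.integer(gate_kernel))
}

# ---- depthwise-separable convolution ------------------------------------

#' Initialize a depthwise-separable convolution (depthwise + pointwise)
#' @param D channels in; `Dout` channels out of the pointwise map.
#' @param k odd depthwise kernel size.
#' @param std truncated-normal init scale.
#' @export
init_dwconv <- function(D, k = 3L, Dout = D, std = 0.02) {
  if (k %% 2 == 0) stop("kernel size must be odd")
  list(dw = trunc_normal(c(k, k, D), std), dwb = matrix(0, 1, D),
       pw = trunc_normal(c(D, Dout), std), pwb = matrix(0, 1, Dout))
}

fw_dwconv <- function(x, H, W, wp) {
  ad_linear(ad_dwconv2d(x, wp$dw, wp$dwb, H, W), wp$pw, wp$pwb)
}

#' Depthwise-separable convolution of a feature map
#'
#' Per-channel k x k convolution (zero same-padding) followed by a 1x1
#' pointwise convolution; spatial shape is preserved.
#'
#' @param x numeric array `[H, W, D]`.
#' @param params parameters from [init_dwconv()].
#' @return numeric array `[H, W, Dout]`.
#' @export
dwconv <- function(x, params) run_block(x, function(m, H, W)
  fw_dwconv(m, H, W, wrap_params(params)))

# ---- squeeze-excitation -------------------------------------------------

#' Initialize a squeeze-excitation channel gate
#' @param D channels; `reduction` bottleneck ratio (>= 1).
#' @export
init_se <- function(D, reduction = 8L, std = 0.02) {
  if (reduction < 1) stop("reduction must be >= 1")
  h <- max(1L, D %/% as.integer(reduction))
  list(w1 = trunc_normal(c(D, h), std), b1 = matrix(0, 1, h),
       w2 = trunc_normal(c(h, D), std), b2 = matrix(0, 1, D))
}

fw_se <- function(x, wp) {
  g <- ad_sigmoid(ad_linear(ad_relu(ad_linear(ad_gap(x), wp$w1, wp$b1)),
                            wp$w2, wp$b2))
  ad_bmul_row(x, g)
}

#' Squeeze-excitation channel gating
#'
#' Global average pool per channel, two linear maps with a ReLU bottleneck,
#' sigmoid weights in (0,1), channelwise rescale of the input.
#'
#' @param x numeric array `[H, W, D]`.
#' @param params parameters from [init_se()].
#' @export
se_gate <- function(x, params) run_block(x, function(m, H, W)
  fw_se(m, wrap_params(params)))

# ---- VSS block ----------------------------------------------------------

#' Initialize a visual state-space block
#' @param D channels; `cfg` a [vss_config()].
#' @export
init_vss_block <- function(D, cfg = vss_config(), std = 0.02) {
  E <- D * cfg$expand
  list(
    ln1_g = matrix(1, 1, D), ln1_b = matrix(0, 1, D),
    lin_in_w = trunc_normal(c(D, E), std), lin_in_b = matrix(0, 1, E),
    dw = init_dwconv(E, cfg$dw_kernel, E, std),
    ss2d = init_ss2d(E, cfg$state_size, cfg$tied_directions, std),
    se = init_se(E, cfg$se_reduction, std),
    ln2_g = matrix(1, 1, E), ln2_b = matrix(0, 1, E),
    lin_out_w = matrix(0, E, D), lin_out_b = matrix(0, 1, D)
  )
}

fw_vss <- function(x, H, W, wp, cfg) {
  h <- ad_layernorm(x, wp$ln1_g, wp$ln1_b)
  u <- ad_linear(h, wp$lin_in_w, wp$lin_in_b)
  u <- ad_silu(fw_dwconv(u, H, W, wp$dw))
  u <- fw_ss2d(u, H, W, wp$ss2d,
               if (is.null(cfg$scan_paths)) 4L else cfg$scan_paths)
  u <- fw_se(u, wp$se)
  u <- ad_layernorm(u, wp$ln2_g, wp$ln2_b)
  ad_add(ad_linear(u, wp$lin_out_w, wp$lin_out_b), x)
}

#' Visual state-space block
#'
#' Layer norm, linear expansion, depthwise-separable convolution with SiLU,
#' 2D selective scan, squeeze-excitation gate, layer norm, linear projection
#' back to the input width, and a residual connection. Shape preserving.
#' With a zero-initialized output projection the block is the identity.
#'
#' @param x numeric array `[H, W, D]`.
#' @param params parameters from [init_vss_block()].
#' @param cfg the [vss_config()] the parameters were built with.
#' @export
vss_block <- function(x, params, cfg = vss_config()) {
  if (ncol(params$lin_out_w) != dim(x)[3]) stop("channel mismatch")
  run_block(x, function(m, H, W) fw_vss(m, H, W, wrap_params(params), cfg))
}

# ---- multiscale convolution set (MSDC) ----------------------------------

#' Initialize the multiscale convolution set
#'
#' The 1x1 branch is a dense channel mix; larger kernels are depthwise
#' (per-channel), keeping the parameter count low; the dense 1x1 fusion
#' after the sum mixes channels across scales.
#' @param D channels; `cfg` a [msdc_config()].
#' @export
init_msdc <- function(D, cfg = msdc_config(), std = 0.02) {
  br <- lapply(cfg$kernels, function(k) {
    if (k == 1L)
      list(w = trunc_normal(c(D, D), std), b = matrix(0, 1, D))
    else
      list(w = trunc_normal(c(k, k, D), std), b = matrix(0, 1, D))
  })
  list(branches = br, fuse_w = matrix(0, D, D), fuse_b = matrix(0, 1, D))
}

fw_msdc <- function(x, H, W, wp) {
  acc <- NULL
  for (br in wp$branches) {
    nd <- length(dim(br$w$v))
    y <- if (nd == 2L) ad_linear(x, br$w, br$b)
         else if (nd == 3L) ad_dwconv2d(x, br$w, br$b, H, W)
         else ad_conv2d(x, br$w, br$b, H, W)
    acc <- if (is.null(acc)) y else ad_add(acc, y)
  }
  ad_linear(acc, wp$fuse_w, wp$fuse_b)
}

#' Multiscale convolution set
#'
#' Parallel convolution branches with kernel sizes 1/3/5 (zero same-padding;
#' the larger kernels depthwise), summed and fused by a 1x1 convolution back
#' to the input width.
#'
#' @param x numeric array `[H, W, D]`.
#' @param params parameters from [init_msdc()].
#' @export
msdc <- function(x, params) run_block(x, function(m, H, W)
  fw_msdc(m, H, W, wrap_params(params)))

# ---- multiscale VSS encoder block ---------------------------------------

#' Initialize a multiscale VSS encoder block
#'
#' A VSS block, a linear projection (identity at initialization), and the
#' multiscale convolution set with its own residual.
#' @param D channels.
#' @export
init_msvss <- function(D, cfg = vss_config(), mcfg = msdc_config(),
                       std = 0.02) {
  list(vss = init_vss_block(D, cfg, std),
       lp_w = diag(D), lp_b = matrix(0, 1, D),
       msdc = init_msdc(D, mcfg, std))
}

fw_msvss <- function(x, H, W, wp, cfg) {
  fv <- fw_vss(x, H, W, wp$vss, cfg)
  u <- ad_linear(fv, wp$lp_w, wp$lp_b)
  ad_add(fw_msdc(u, H, W, wp$msdc), u)
}

#' Multiscale VSS encoder block
#'
#' `u = LP(vss_block(x)); out = msdc(u) + u`. Shape preserving; an exact
#' identity at initialization (zero output projections, identity LP).
#'
#' @param x numeric array `[H, W, D]`.
#' @param params parameters from [init_msvss()].
#' @param cfg the [vss_config()] used at init.
#' @export
msvss_block <- function(x, params, cfg = vss_config()) {
  run_block(x, function(m, H, W) fw_msvss(m, H, W, wrap_params(params), cfg))
}

# ---- bottleneck attention (MSAA) ----------------------------------------

#' Initialize the multiscale attention aggregation bottleneck
#' @param D channels; `cfg` a [msaa_config()].
#' @export
init_msaa <- function(D, cfg = msaa_config(), std = 0.02) {
  gk <- cfg$gate_kernel
  p <- list(
    lin_in_w = diag(D), lin_in_b = matrix(0, 1, D),
    dil = lapply(cfg$dilations, function(r)
      list(w = trunc_normal(c(3, 3, D), std), b = matrix(0, 1, D))),
    gate_w = trunc_normal(c(gk, gk, 2, 1), std), gate_b = matrix(0, 1, 1),
    lin_out_w = matrix(0, D, D), lin_out_b = matrix(0, 1, D)
  )
  attr(p, "dilations") <- cfg$dilations
  p
}

fw_msaa <- function(x, H, W, wp, dilations) {
  p <- ad_linear(x, wp$lin_in_w, wp$lin_in_b)
  fd <- NULL
  for (i in seq_along(wp$dil)) {
    y <- ad_dwconv2d(p, wp$dil[[i]]$w, wp$dil[[i]]$b, H, W,
                     dil = dilations[i])
    fd <- if (is.null(fd)) y else ad_add(fd, y)
  }
  gm <- ad_cbind(ad_chan_mean(fd), ad_chan_max(fd))
  g <- ad_sigmoid(ad_conv2d(gm, wp$gate_w, wp$gate_b, H, W))
  gated <- ad_bmul_col(fd, g)
  ad_add(ad_linear(gated, wp$lin_out_w, wp$lin_out_b), p)
}

#' Multiscale attention aggregation bottleneck
#'
#' A 1x1 projection, three parallel depthwise dilated 3x3 convolutions
#' (rates 1/3/5) summed, a spatial sigmoid gate built from the channelwise
#' average and maximum maps (7x7 convolution to one channel), a gated 1x1
#' projection and a residual connection. Shape preserving.
#'
#' @param x numeric array `[H, W, D]` (the deepest encoder output).
#' @param params parameters from [init_msaa()].
#' @export
msaa_block <- function(x, params) {
  dil <- attr(params, "dilations")
  if (is.null(dil)) dil <- c(1L, 3L, 5L)
  run_block(x, function(m, H, W) fw_msaa(m, H, W, wrap_params(params), dil))
}

# ---- channel-aware attentional skip (CAVSS) -----------------------------

#' Initialize a channel-aware VSS skip block
#' @param D channels; `gate_kernel` odd spatial-gate kernel.
#' @export
init_cavss <- function(D, cfg = vss_config(), gate_kernel = 3L, std = 0.02) {
  stopifnot(gate_kernel %% 2 == 1)
  cv <- init_dwconv(D, 3L, D, std)
  cv$pw[] <- 0 # zero pointwise: the block passes F_vss through at init
  list(
    vss = init_vss_block(D, cfg, std),
    ln_g = matrix(1, 1, D), ln_b = matrix(0, 1, D),
    conv = cv,
    gate_w = trunc_normal(c(gate_kernel, gate_kernel, 2, 1), std),
    gate_b = matrix(0, 1, 1)
  )
}

fw_cavss <- function(x, H, W, wp, cfg) {
  fv <- fw_vss(x, H, W, wp$vss, cfg)
  fl <- fw_dwconv(ad_layernorm(fv, wp$ln_g, wp$ln_b), H, W, wp$conv)
  gm <- ad_cbind(ad_chan_mean(fl), ad_chan_max(fl))
  g <- ad_sigmoid(ad_conv2d(gm, wp$gate_w, wp$gate_b, H, W))
  ad_add(ad_bmul_col(fl, g), fv)
}

#' Channel-aware VSS skip connection
#'
#' `F_vss = vss_block(x); F_ln = conv3x3(LN(F_vss))`; a spatial sigmoid gate
#' over the pooled maps of `F_ln` multiplies `F_ln`, and `F_vss` is added
#' back. With the inner convolution zero-initialized the block passes
#' `F_vss` through unchanged. Shape preserving.
#'
#' @param x numeric array `[H, W, D]` (an encoder skip feature).
#' @param params parameters from [init_cavss()].
#' @param cfg the [vss_config()] used at init.
#' @export
cavss_block <- function(x, params, cfg = vss_config()) {
  run_block(x, function(m, H, W) fw_cavss(m, H, W, wrap_params(params), cfg))
}

# run a tape-level block function on a [H, W, D] array in inference mode
run_block <- function(x, fn) {
  d <- dim(x)
  ad_no_grad({
    out <- fn(ad_const(map_to_tokens(x)), d[1], d[2])
    tokens_to_map(out$v, d[1], d[2])
  })
}
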
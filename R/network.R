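# Full segmentation network: patch embedding, 4-stage multiscale-VSS encoder
# with patch merging, dilated-attention bottleneck, 4-stage VSS decoder with
# patch expanding, channel-aware attentional skips, and the pixel head.
#
# Stage resolution ladder for input H x W (divisible by 32), base width C:
#   encoder  H/4 x W/4 x C  ->  H/8 x W/8 x 2C  ->  H/16 x W/16 x 4C
#            ->  H/32 x W/32 x 8C
#   decoder  mirrors it back to H/4 x W/4 x C, then a 4x expansion and a
#   1x1 convolution produce per-pixel class logits at full resolution.

#' Model configuration
#'
#' @param base_channels base channel width C (even; the stage widths are
#'   C, 2C, 4C, 8C). Default 96.
#' @param patch_size side of the square non-overlapping embedding patches.
#' @param enc_depths,dec_depths number of blocks per encoder/decoder stage.
#' @param n_classes number of segmentation classes (>= 2).
#' @param state_size selective-scan state dimension N.
#' @param expand,dw_kernel,se_reduction,scan_paths,tied_directions passed to
#'   [vss_config()].
#' @param msdc_kernels kernel sizes of the multiscale convolution set.
#' @param msaa_dilations,msaa_gate_kernel bottleneck attention settings.
#' @param cavss_gate_kernel spatial-gate kernel of the attentional skips.
#' @param use_msvss,use_msaa,use_cavss ablation switches: plain VSS encoder
#'   blocks, no bottleneck attention, plain additive skips.
#' @return a validated config list of class `pestseg_config`.
#' @export
model_config <- function(base_channels = 96L, patch_size = 4L,
                         enc_depths = c(2L, 2L, 2L, 2L),
                         dec_depths = c(2L, 2L, 2L, 2L),
                         n_classes = 2L, state_size = 16L, expand = 2L,
                         dw_kernel = 3L, se_reduction = 8L, scan_paths = 4L,
                         tied_directions = FALSE,
                         msdc_kernels = c(1L, 3L, 5L),
                         msaa_dilations = c(1L, 3L, 5L),
                         msaa_gate_kernel = 7L, cavss_gate_kernel = 3L,
                         use_msvss = TRUE, use_msaa = TRUE,
                         use_cavss = TRUE) {
  if (base_channels %% 2 != 0) stop("base_channels must be even")
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (length(enc_depths) != 4 || length(dec_depths) != 4)
    stop("depths must have 4 stages")
  if (any(enc_depths < 1) || any(dec_depths < 1)) stop("depths must be >= 1")
  cfg <- list(base_channels = as.integer(base_channels),
              patch_size = as.integer(patch_size),
              enc_depths = as.integer(enc_depths),
              dec_depths = as.integer(dec_depths),
              n_classes = as.integer(n_classes),
              state_size = as.integer(state_size),
              expand = as.integer(expand),
              dw_kernel = as.integer(dw_kernel),
              se_reduction = as.integer(se_reduction),
              scan_paths = as.integer(scan_paths),
              tied_directions = isTRUE(tied_directions),
              msdc_kernels = as.integer(msdc_kernels),
              msaa_dilations = as.integer(msaa_dilations),
              msaa_gate_kernel = as.integer(msaa_gate_kernel),
              cavss_gate_kernel = as.integer(cavss_gate_kernel),
              use_msvss = isTRUE(use_msvss),
              use_msaa = isTRUE(use_msaa),
              use_cavss = isTRUE(use_cavss))
  class(cfg) <- "pestseg_config"
  cfg
}

cfg_vss <- function(cfg) {
  vss_config(expand = cfg$expand, dw_kernel = cfg$dw_kernel,
             se_reduction = cfg$se_reduction, state_size = cfg$state_size,
             scan_paths = cfg$scan_paths,
             tied_directions = cfg$tied_directions)
}

#' Build a model with freshly initialized weights
#'
#' Linear and convolution weights are truncated-normal (sd 0.02); final
#' projections of every residual block are zero so each block starts as the
#' identity; the selective-scan transition uses the standard log-spaced
#' state init.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the initialization.
#' @return an object of class `pestseg_model`: list with `params`, `config`
#'   and `n_params`.
#' @export
build_model <- function(config = model_config(), seed = 42L) {
  stopifnot(inherits(config, "pestseg_config"))
  set.seed(seed)
  C <- config$base_channels
  vc <- cfg_vss(config)
  mc <- msdc_config(config$msdc_kernels)
  widths <- C * c(1L, 2L, 4L, 8L)
  enc_block <- function(D)
    if (config$use_msvss) init_msvss(D, vc, mc) else init_vss_block(D, vc)
  params <- list(
    embed = list(
      w = trunc_normal(c(config$patch_size^2 * 3L, C)),
      b = matrix(0, 1, C),
      ln_g = matrix(1, 1, C), ln_b = matrix(0, 1, C)),
    enc = lapply(1:4, function(s)
      lapply(seq_len(config$enc_depths[s]), function(i) enc_block(widths[s]))),
    merge = lapply(1:3, function(s) list(
      ln_g = matrix(1, 1, 4L * widths[s]), ln_b = matrix(0, 1, 4L * widths[s]),
      w = trunc_normal(c(4L * widths[s], 2L * widths[s])))),
    dec = lapply(4:1, function(s)
      lapply(seq_len(config$dec_depths[5L - s]), function(i)
        init_vss_block(widths[s], vc))),
    expand = lapply(3:1, function(s) list(
      w = trunc_normal(c(2L * widths[s], 4L * widths[s])),
      ln_g = matrix(1, 1, widths[s]), ln_b = matrix(0, 1, widths[s]))),
    final = list(
      w = trunc_normal(c(C, 16L * C)),
      ln_g = matrix(1, 1, C), ln_b = matrix(0, 1, C),
      head_w = trunc_normal(c(C, config$n_classes)),
      head_b = matrix(0, 1, config$n_classes))
  )
  if (config$use_msaa)
    params$msaa <- init_msaa(widths[4],
                             msaa_config(config$msaa_dilations,
                                         config$msaa_gate_kernel))
  if (config$use_cavss)
    params$skips <- lapply(1:4, function(s)
      init_cavss(widths[s], vc, config$cavss_gate_kernel))
  m <- structure(list(params = params, config = config), class = "pestseg_model")
  m$n_params <- count_params(m)
  m
}

#' Number of learnable parameters of a model
#' @param model a `pestseg_model`.
#' @export
count_params <- function(model) {
  n <- 0L
  walk <- function(p) {
    if (is.list(p)) lapply(p, walk) else n <<- n + length(p)
    invisible(NULL)
  }
  walk(model$params)
  n
}

# ---- patch embedding / merging / expanding ------------------------------

# gather non-overlapping p x p patches into tokens: [H*W, Cin] -> rows
# (H/p)*(W/p), columns p^2 * Cin (sub-positions row-major, channels fastest)
patch_tokens <- function(img, p) {
  H <- dim(img)[1]; W <- dim(img)[2]; Cin <- dim(img)[3]
  if (H %% p != 0 || W %% p != 0)
    stop("image dims (", H, "x", W, ") must be divisible by patch size ", p)
  Ho <- H %/% p; Wo <- W %/% p
  m <- map_to_tokens(img)
  out <- matrix(0, Ho * Wo, p * p * Cin)
  io <- rep(seq_len(Ho), each = Wo)
  jo <- rep.int(seq_len(Wo), Ho)
  for (di in seq_len(p)) for (dj in seq_len(p)) {
    blk <- (di - 1L) * p + dj
    src <- ((io - 1L) * p + di - 1L) * W + (jo - 1L) * p + dj
    out[, ((blk - 1L) * Cin + 1L):(blk * Cin)] <- m[src, ]
  }
  out
}

#' Initialize the patch-embedding layer
#' @param C output channel width; `patch` the patch side.
#' @export
init_patch_embed <- function(C, patch = 4L, std = 0.02) {
  list(w = trunc_normal(c(patch^2 * 3L, C), std), b = matrix(0, 1, C),
       ln_g = matrix(1, 1, C), ln_b = matrix(0, 1, C))
}

#' Patch embedding
#'
#' Maps each non-overlapping `patch x patch x 3` block linearly to a `C`-dim
#' token, arranged as an `[H/patch, W/patch, C]` map, then layer-normalizes.
#'
#' @param img numeric array `[H, W, 3]`, dims divisible by `patch`.
#' @param params parameters from [init_patch_embed()].
#' @param patch patch side length.
#' @export
patch_embed <- function(img, params, patch = 4L) {
  P <- patch_tokens(img, patch)
  ad_no_grad({
    wp <- wrap_params(params)
    out <- ad_layernorm(ad_linear(ad_const(P), wp$w, wp$b), wp$ln_g, wp$ln_b)
    tokens_to_map(out$v, dim(img)[1] %/% patch, dim(img)[2] %/% patch)
  })
}

fw_patch_merge <- function(x, H, W, wp) {
  if (H %% 2 != 0 || W %% 2 != 0) stop("patch merge needs even dims")
  Ho <- H %/% 2L; Wo <- W %/% 2L
  io <- rep(seq_len(Ho), each = Wo)
  jo <- rep.int(seq_len(Wo), Ho)
  idx <- function(di, dj) ((io - 1L) * 2L + di - 1L) * W + (jo - 1L) * 2L + dj
  cat4 <- ad_cbind(
    ad_cbind(ad_select_rows(x, idx(1, 1)), ad_select_rows(x, idx(1, 2))),
    ad_cbind(ad_select_rows(x, idx(2, 1)), ad_select_rows(x, idx(2, 2))))
  ad_linear(ad_layernorm(cat4, wp$ln_g, wp$ln_b), wp$w)
}

#' Initialize a patch-merging layer (downsampling)
#' @param D input channels; projects 4D -> 2D.
#' @export
init_patch_merge <- function(D, std = 0.02) {
  list(ln_g = matrix(1, 1, 4L * D), ln_b = matrix(0, 1, 4L * D),
       w = trunc_normal(c(4L * D, 2L * D), std))
}

#' Patch merging
#'
#' Concatenates each 2x2 neighborhood (top-left, top-right, bottom-left,
#' bottom-right) into 4D channels, layer-normalizes, and linearly projects
#' to 2D channels: `[H, W, D] -> [H/2, W/2, 2D]`.
#'
#' @param x numeric array `[H, W, D]` with even `H`, `W`.
#' @param params parameters from [init_patch_merge()].
#' @export
patch_merge <- function(x, params) {
  d <- dim(x)
  ad_no_grad({
    out <- fw_patch_merge(ad_const(map_to_tokens(x)), d[1], d[2],
                          wrap_params(params))
    tokens_to_map(out$v, d[1] %/% 2L, d[2] %/% 2L)
  })
}

fw_patch_expand <- function(x, H, W, wp) {
  x2 <- ad_linear(x, wp$w) # D -> 2D
  D2 <- ncol(x2$v) %/% 4L  # = D/2 channels per sub-position
  idx <- pixel_shuffle_index(H, W, 2L, D2)
  out <- ad_gather(x2, idx, 4L * H * W, D2)
  ad_layernorm(out, wp$ln_g, wp$ln_b)
}

#' Initialize a patch-expanding layer (upsampling)
#' @param D input channels (even); produces D/2 channels at 2x resolution.
#' @export
init_patch_expand <- function(D, std = 0.02) {
  if (D %% 2 != 0) stop("channel count must be divisible by 2")
  list(w = trunc_normal(c(D, 2L * D), std),
       ln_g = matrix(1, 1, D %/% 2L), ln_b = matrix(0, 1, D %/% 2L))
}

#' Patch expanding
#'
#' Linearly projects to 2D channels and rearranges each token's vector into
#' a 2x2 spatial block of D/2 channels: `[H, W, D] -> [2H, 2W, D/2]`.
#'
#' @param x numeric array `[H, W, D]`, `D` even.
#' @param params parameters from [init_patch_expand()].
#' @export
patch_expand <- function(x, params) {
  d <- dim(x)
  if (d[3] %% 2 != 0) stop("channel count must be divisible by 2")
  ad_no_grad({
    out <- fw_patch_expand(ad_const(map_to_tokens(x)), d[1], d[2],
                           wrap_params(params))
    tokens_to_map(out$v, 2L * d[1], 2L * d[2])
  })
}

# ---- full forward -------------------------------------------------------

# tape-level forward; wp = wrapped params; returns logits node [H*W, n]
fw_network <- function(wp, img, cfg) {
  H <- dim(img)[1]; W <- dim(img)[2]
  p <- cfg$patch_size
  if (H %% (p * 8L) != 0 || W %% (p * 8L) != 0)
    stop("input dims (", H, "x", W, ") must be divisible by ", p * 8L)
  vc <- cfg_vss(cfg)
  x <- ad_const(patch_tokens(img, p))
  x <- ad_layernorm(ad_linear(x, wp$embed$w, wp$embed$b),
                    wp$embed$ln_g, wp$embed$ln_b)
  h <- H %/% p; w_ <- W %/% p
  skips <- vector("list", 4L)
  hw <- vector("list", 4L)
  for (s in 1:4) {
    for (b in seq_len(cfg$enc_depths[s]))
      x <- if (cfg$use_msvss) fw_msvss(x, h, w_, wp$enc[[s]][[b]], vc)
           else fw_vss(x, h, w_, wp$enc[[s]][[b]], vc)
    skips[[s]] <- x
    hw[[s]] <- c(h, w_)
    if (s < 4) {
      x <- fw_patch_merge(x, h, w_, wp$merge[[s]])
      h <- h %/% 2L; w_ <- w_ %/% 2L
    }
  }
  d <- if (cfg$use_msaa) fw_msaa(x, h, w_, wp$msaa, cfg$msaa_dilations) else x
  for (s in 4:1) {
    sk <- if (cfg$use_cavss)
      fw_cavss(skips[[s]], hw[[s]][1], hw[[s]][2], wp$skips[[s]], vc)
    else skips[[s]]
    d <- ad_add(d, sk)
    for (b in seq_len(cfg$dec_depths[5L - s]))
      d <- fw_vss(d, h, w_, wp$dec[[5L - s]][[b]], vc)
    if (s > 1) {
      d <- fw_patch_expand(d, h, w_, wp$expand[[5L - s]])
      h <- h * 2L; w_ <- w_ * 2L
    }
  }
  # 4x expansion back to full resolution, then the 1x1 head
  d <- ad_linear(d, wp$final$w) # C -> 16C
  Cb <- cfg$base_channels
  idx <- pixel_shuffle_index(h, w_, 4L, Cb)
  d <- ad_gather(d, idx, 16L * h * w_, Cb)
  d <- ad_layernorm(d, wp$final$ln_g, wp$final$ln_b)
  ad_linear(d, wp$final$head_w, wp$final$head_b)
}

# model-forward hook so the training harness can drive any model object
# carrying its own `fw` function (used for stubbed models in tests); must
# return the logits node [H*W, n] for a [H, W, 3] image
fw_model <- function(model, wp, img, ...) {
  if (is.function(model$fw)) return(model$fw(model, wp, img, ...))
  fw_network(wp, img, model$config)
}

#' Run the network on one image
#'
#' @param model a `pestseg_model` from [build_model()].
#' @param img numeric array `[H, W, 3]` with values in `[0, 1]`, `H` and `W`
#'   divisible by 32.
#' @return per-pixel class logits, numeric array `[H, W, n_classes]`.
#' @export
model_forward <- function(model, img) {
  ad_no_grad({
    out <- fw_model(model, wrap_params(model$params), img)
    tokens_to_map(out$v, dim(img)[1], dim(img)[2])
  })
}

#' Predict a segmentation mask
#'
#' Applies softmax to the logits and takes the per-pixel argmax.
#'
#' @inheritParams model_forward
#' @return integer matrix `[H, W]` with class codes `0..n-1`.
#' @export
predict_mask <- function(model, img) {
  lg <- model_forward(model, img)
  d <- dim(lg)
  m <- matrix(lg, d[1] * d[2], d[3])
  cls <- max.col(m, ties.method = "first") - 1L
  matrix(as.integer(cls), d[1], d[2])
}

#' Per-stage encoder/decoder features (shape inspection)
#'
#' Runs the encoder and decoder and returns the list of stage feature maps,
#' for verifying the resolution ladder.
#'
#' @inheritParams model_forward
#' @return list with `encoder` and `decoder` lists of `[h, w, d]` arrays and
#'   `logits`.
#' @export
stage_features <- function(model, img) {
  cfg <- model$config
  ad_no_grad({
    wp <- wrap_params(model$params)
    H <- dim(img)[1]; W <- dim(img)[2]
    p <- cfg$patch_size
    vc <- cfg_vss(cfg)
    x <- ad_const(patch_tokens(img, p))
    x <- ad_layernorm(ad_linear(x, wp$embed$w, wp$embed$b),
                      wp$embed$ln_g, wp$embed$ln_b)
    h <- H %/% p; w_ <- W %/% p
    enc <- vector("list", 4L)
    skips <- vector("list", 4L)
    hw <- vector("list", 4L)
    for (s in 1:4) {
      for (b in seq_len(cfg$enc_depths[s]))
        x <- if (cfg$use_msvss) fw_msvss(x, h, w_, wp$enc[[s]][[b]], vc)
             else fw_vss(x, h, w_, wp$enc[[s]][[b]], vc)
      enc[[s]] <- tokens_to_map(x$v, h, w_)
      skips[[s]] <- x
      hw[[s]] <- c(h, w_)
      if (s < 4) {
        x <- fw_patch_merge(x, h, w_, wp$merge[[s]])
        h <- h %/% 2L; w_ <- w_ %/% 2L
      }
    }
    d <- if (cfg$use_msaa) fw_msaa(x, h, w_, wp$msaa, cfg$msaa_dilations)
         else x
    dec <- vector("list", 4L)
    for (s in 4:1) {
      sk <- if (cfg$use_cavss)
        fw_cavss(skips[[s]], hw[[s]][1], hw[[s]][2], wp$skips[[s]], vc)
      else skips[[s]]
      d <- ad_add(d, sk)
      for (b in seq_len(cfg$dec_depths[5L - s]))
        d <- fw_vss(d, h, w_, wp$dec[[5L - s]][[b]], vc)
      dec[[5L - s]] <- tokens_to_map(d$v, h, w_)
      if (s > 1) {
        d <- fw_patch_expand(d, h, w_, wp$expand[[5L - s]])
        h <- h * 2L; w_ <- w_ * 2L
      }
    }
    d <- ad_linear(d, wp$final$w)
    Cb <- cfg$base_channels
    idx <- pixel_shuffle_index(h, w_, 4L, Cb)
    d <- ad_gather(d, idx, 16L * h * w_, Cb)
    d <- ad_layernorm(d, wp$final$ln_g, wp$final$ln_b)
    d <- ad_linear(d, wp$final$head_w, wp$final$head_b)
    list(encoder = enc, decoder = dec,
         logits = tokens_to_map(d$v, H, W))
  })
}

# ---- config file I/O ----------------------------------------------------

#' Write a model configuration to a YAML file
#' @param config a [model_config()]; `path` output file.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "pestseg_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a model configuration from a YAML file
#' @param path YAML file written by [write_model_config()] (unknown keys
#'   are rejected).
#' @export
read_model_config <- function(path) {
  v <- yaml::read_yaml(path)
  known <- names(formals(model_config))
  bad <- setdiff(names(v), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(model_config, v)
}
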
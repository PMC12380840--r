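# Paired image/mask augmentation: geometric ops transform image and mask
# identically (nearest-neighbour for the mask, so class codes survive);
# photometric ops touch the image only. Mixup and CutMix mix two samples.

# ---- geometric primitives ----------------------------------------------

flip_h_img <- function(img) img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
flip_v_img <- function(img) img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
flip_h_mask <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v_mask <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

# exact counter-clockwise quarter-turn rotations (lossless permutations)
rot90_mask <- function(m, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

rot90_img <- function(img, k = 1L) {
  k <- ((k %% 4) + 4) %% 4
  for (i in seq_len(k)) {
    d <- dim(img)
    out <- array(0, c(d[2], d[1], d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- rot90_mask(img[, , ch], 1L)
    img <- out
  }
  img
}

# reflect out-of-range indices back into 1..n (reflection padding)
reflect_idx <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n - 2L
  m <- ((idx - 1L) %% period + period) %% period
  ifelse(m < n, m + 1L, period - m + 1L)
}

# bilinear sampling of one channel at fractional coords (clamped to edges)
sample_bilinear <- function(ch, si, sj) {
  H <- nrow(ch); W <- ncol(ch)
  si <- pmin(pmax(si, 1), H)
  sj <- pmin(pmax(sj, 1), W)
  i0 <- floor(si); j0 <- floor(sj)
  i1 <- pmin(i0 + 1, H); j1 <- pmin(j0 + 1, W)
  fi <- si - i0; fj <- sj - j0
  ch[cbind(i0, j0)] * (1 - fi) * (1 - fj) +
    ch[cbind(i1, j0)] * fi * (1 - fj) +
    ch[cbind(i0, j1)] * (1 - fi) * fj +
    ch[cbind(i1, j1)] * fi * fj
}

# nearest-neighbour mask sampling; coords outside the canvas give 0
sample_nearest_mask <- function(m, si, sj) {
  H <- nrow(m); W <- ncol(m)
  i <- round(si); j <- round(sj)
  ok <- i >= 1 & i <= H & j >= 1 & j <= W
  out <- integer(length(si))
  out[ok] <- m[cbind(i[ok], j[ok])]
  out
}

# inverse-map a pair through source coordinate fields (matrices si, sj)
warp_pair <- function(image, mask, si, sj) {
  H <- nrow(mask); W <- ncol(mask)
  out <- array(0, dim(image))
  for (ch in seq_len(dim(image)[3]))
    out[, , ch] <- matrix(sample_bilinear(image[, , ch], as.vector(si),
                                          as.vector(sj)), H, W)
  mk <- matrix(sample_nearest_mask(mask, as.vector(si), as.vector(sj)), H, W)
  list(image = out, mask = mk)
}

#' Rotate an image/mask pair
#'
#' Exact multiples of 90 degrees use lossless index permutations; other
#' angles use inverse-mapped sampling (bilinear for the image, nearest
#' neighbour for the mask, with 0-fill outside the canvas).
#'
#' @param image numeric `[H, W, 3]`; `mask` integer `[H, W]`.
#' @param angle rotation in degrees, counter-clockwise.
#' @export
rotate_pair <- function(image, mask, angle) {
  angle <- angle %% 360
  if (angle %% 90 == 0) {
    k <- as.integer(angle %/% 90)
    return(list(image = rot90_img(image, k), mask = rot90_mask(mask, k)))
  }
  H <- nrow(mask); W <- ncol(mask)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  ii <- matrix(rep(seq_len(H), W), H, W)
  jj <- matrix(rep(seq_len(W), each = H), H, W)
  # inverse rotation of output coords gives the source coords
  si <- cy + cos(th) * (ii - cy) - sin(th) * (jj - cx)
  sj <- cx + sin(th) * (ii - cy) + cos(th) * (jj - cx)
  warp_pair(image, mask, si, sj)
}

#' Shift an image/mask pair with reflection padding
#' @param dy,dx shift in pixels (positive moves content down/right).
#' @inheritParams rotate_pair
#' @export
shift_pair <- function(image, mask, dy, dx) {
  H <- nrow(mask); W <- ncol(mask)
  ri <- reflect_idx(seq_len(H) - as.integer(round(dy)), H)
  rj <- reflect_idx(seq_len(W) - as.integer(round(dx)), W)
  list(image = image[ri, rj, , drop = FALSE], mask = mask[ri, rj, drop = FALSE])
}

#' Crop a window and resize back to the original size
#' @param top,left,ch,cw crop window (1-based corner and size).
#' @inheritParams rotate_pair
#' @export
crop_resize_pair <- function(image, mask, top, left, ch, cw) {
  H <- nrow(mask); W <- ncol(mask)
  si <- matrix(rep(seq(top, top + ch - 1, length.out = H), W), H, W)
  sj <- matrix(rep(seq(left, left + cw - 1, length.out = W), each = H), H, W)
  warp_pair(image, mask, si, sj)
}

#' Brightness/contrast jitter (photometric; image only)
#' @param image numeric `[H, W, 3]`.
#' @param brightness additive offset; `contrast` multiplicative factor
#'   applied around mid-gray.
#' @export
enhance_image <- function(image, brightness = 0, contrast = 1) {
  clamp01((image - 0.5) * contrast + 0.5 + brightness)
}

# ---- augmentation pipeline ----------------------------------------------

#' Augmentation specification
#'
#' @param ops subset of `c("crop", "hflip", "vflip", "enhance", "rotate",
#'   "shift")` applied (each with probability `p`) in that order.
#' @param p per-op application probability.
#' @param crop_min_area minimum retained area fraction of the random crop.
#' @param rotate_range maximum absolute rotation in degrees.
#' @param shift_frac maximum shift as a fraction of each dimension.
#' @param jitter maximum brightness offset / contrast deviation.
#' @param seed RNG seed; same seed, same augmentation.
#' @export
augment_spec <- function(ops = c("crop", "hflip", "vflip", "enhance",
                                 "rotate", "shift"),
                         p = 0.5, crop_min_area = 0.8, rotate_range = 30,
                         shift_frac = 0.1, jitter = 0.2, seed = NULL) {
  stopifnot(p >= 0, p <= 1, crop_min_area > 0, crop_min_area <= 1)
  list(ops = match.arg(ops, several.ok = TRUE), p = p,
       crop_min_area = crop_min_area, rotate_range = rotate_range,
       shift_frac = shift_frac, jitter = jitter, seed = seed)
}

#' Apply the augmentation suite to an image/mask pair
#'
#' Geometric ops transform image and mask identically (mask by nearest
#' neighbour, codes stay in {0, 1}); photometric jitter touches the image
#' only. Deterministic given the spec's seed.
#'
#' @inheritParams rotate_pair
#' @param spec an [augment_spec()].
#' @return list with `image` and `mask`.
#' @export
augment <- function(image, mask, spec = augment_spec()) {
  if (!all(dim(image)[1:2] == dim(mask))) stop("image/mask shape mismatch")
  with_seed(spec$seed, {
    pr <- list(image = image, mask = mask)
    H <- nrow(mask); W <- ncol(mask)
    for (op in spec$ops) {
      if (stats::runif(1) > spec$p) next
      pr <- switch(op,
        crop = {
          f <- sqrt(stats::runif(1, spec$crop_min_area, 1))
          ch <- max(2L, round(H * f)); cw <- max(2L, round(W * f))
          top <- sample.int(H - ch + 1L, 1L)
          left <- sample.int(W - cw + 1L, 1L)
          crop_resize_pair(pr$image, pr$mask, top, left, ch, cw)
        },
        hflip = list(image = flip_h_img(pr$image),
                     mask = flip_h_mask(pr$mask)),
        vflip = list(image = flip_v_img(pr$image),
                     mask = flip_v_mask(pr$mask)),
        enhance = list(image = enhance_image(pr$image,
                         stats::runif(1, -spec$jitter, spec$jitter),
                         1 + stats::runif(1, -spec$jitter, spec$jitter)),
                       mask = pr$mask),
        rotate = rotate_pair(pr$image, pr$mask,
                             stats::runif(1, -spec$rotate_range,
                                          spec$rotate_range)),
        shift = shift_pair(pr$image, pr$mask,
                           stats::runif(1, -spec$shift_frac, spec$shift_frac) * H,
                           stats::runif(1, -spec$shift_frac, spec$shift_frac) * W))
    }
    pr
  })
}

# ---- sample mixing ------------------------------------------------------

onehot_mask <- function(m, n = 2L) {
  H <- nrow(m); W <- ncol(m)
  out <- array(0, c(H, W, n))
  for (c in seq_len(n)) out[, , c] <- (m == c - 1L) * 1
  out
}

#' Mixup of two image/mask pairs
#'
#' Convex combination of the images and of the one-hot masks; the soft
#' mask is meant to be consumed by losses that accept probability-valued
#' targets. At `lam = 1` (`0`) the first (second) pair is returned
#' unchanged with its hard mask.
#'
#' @param pair1,pair2 lists with `image` and `mask` of identical shape.
#' @param lam mixing weight in `[0, 1]`.
#' @param n_classes classes for the one-hot expansion.
#' @export
mixup <- function(pair1, pair2, lam, n_classes = 2L) {
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  if (!all(dim(pair1$image) == dim(pair2$image))) stop("shape mismatch")
  if (lam == 1) return(pair1)
  if (lam == 0) return(pair2)
  list(image = lam * pair1$image + (1 - lam) * pair2$image,
       mask = lam * onehot_mask(pair1$mask, n_classes) +
         (1 - lam) * onehot_mask(pair2$mask, n_classes))
}

#' CutMix of two image/mask pairs
#'
#' Copies a uniformly placed rectangle of area about `area_frac * H * W`
#' (image and mask jointly) from `pair2` into `pair1`; the mask stays hard.
#'
#' @inheritParams mixup
#' @param area_frac target area fraction of the transplanted box, in (0, 1).
#' @param seed RNG seed (same seed, same box).
#' @export
cutmix <- function(pair1, pair2, area_frac, seed = NULL) {
  if (area_frac <= 0 || area_frac >= 1) stop("area_frac must be in (0, 1)")
  if (!all(dim(pair1$image) == dim(pair2$image))) stop("shape mismatch")
  with_seed(seed, {
    H <- nrow(pair1$mask); W <- ncol(pair1$mask)
    A <- area_frac * H * W
    bh <- bw <- 0L
    for (try in 1:20) {
      ar <- stats::runif(1, 0.5, 2) # aspect ratio jitter
      bh <- min(H, max(0L, as.integer(round(sqrt(A / ar)))))
      if (bh >= 1L) bw <- min(W, max(0L, as.integer(round(A / bh))))
      if (bh >= 1L && bw >= 1L) break
    }
    if (bh < 1L || bw < 1L) stop("degenerate cutmix rectangle")
    top <- sample.int(H - bh + 1L, 1L)
    left <- sample.int(W - bw + 1L, 1L)
    img <- pair1$image
    msk <- pair1$mask
    ri <- top:(top + bh - 1L)
    rj <- left:(left + bw - 1L)
    img[ri, rj, ] <- pair2$image[ri, rj, ]
    msk[ri, rj] <- pair2$mask[ri, rj]
    list(image = img, mask = msk, box = c(top, left, bh, bw))
  })
}
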
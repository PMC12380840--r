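# Synthetic pest-scene generator. Emulates the statistical structure of
# field pest imagery: small elliptical insect bodies with thin protruding
# appendages (legs/antennae), several scales per image, low contrast
# against a textured vegetation-like background, and strong class
# imbalance (pests cover a few percent of pixels).

# evaluate expr under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  expr
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Scene specification for the synthetic pest generator
#'
#' @param height,width canvas size in pixels.
#' @param n_pests number of pests; a single count or a `c(min, max)` range.
#' @param scale_range pest body diameter as a fraction of the image
#'   diagonal, in `(0, 0.5]`.
#' @param appendage_count `c(min, max)` thin appendages per pest.
#' @param appendage_thickness `c(min, max)` appendage thickness in px
#'   (>= 1).
#' @param eccentricity `c(min, max)` body axis ratio.
#' @param base_color background RGB base (vegetation green by default).
#' @param noise_amplitude background texture/noise strength.
#' @param gradient_amplitude background illumination gradient strength.
#' @param contrast pest-versus-background blending factor (> 0; small
#'   values give barely visible pests).
#' @param overlap allow pests to overlap; when `FALSE` (default) pests are
#'   placed with a clearance gap so each forms its own connected component.
#' @param min_gap clearance in px between pests when `overlap = FALSE`.
#' @param max_tries placement retries before giving up with an error.
#' @param seed RNG seed; the same spec and seed give bit-identical scenes.
#' @export
scene_spec <- function(height = 64L, width = 64L, n_pests = c(2L, 5L),
                       scale_range = c(0.04, 0.11),
                       appendage_count = c(4L, 8L),
                       appendage_thickness = c(1, 2),
                       eccentricity = c(1.4, 2.8),
                       base_color = c(0.33, 0.46, 0.24),
                       noise_amplitude = 0.05, gradient_amplitude = 0.12,
                       contrast = 0.4, overlap = FALSE, min_gap = 2,
                       max_tries = 60L, seed = NULL) {
  if (any(scale_range <= 0) || any(scale_range > 0.5))
    stop("scale_range must lie in (0, 0.5]")
  if (any(appendage_thickness < 1)) stop("appendage thickness must be >= 1 px")
  if (contrast <= 0) stop("contrast factor must be positive")
  list(height = as.integer(height), width = as.integer(width),
       n_pests = as.integer(n_pests), scale_range = scale_range,
       appendage_count = as.integer(appendage_count),
       appendage_thickness = appendage_thickness,
       eccentricity = eccentricity, base_color = base_color,
       noise_amplitude = noise_amplitude,
       gradient_amplitude = gradient_amplitude, contrast = contrast,
       overlap = isTRUE(overlap), min_gap = min_gap,
       max_tries = as.integer(max_tries), seed = seed)
}

rand_in <- function(r) if (length(r) > 1) stats::runif(1, r[1], r[2]) else r
rand_int_in <- function(r) {
  if (length(r) > 1) sample(seq.int(r[1], r[2]), 1L) else as.integer(r)
}

# mark all pixels within `rad` of the segment p0-p1 (coordinates are
# (row, col)); returns updated logical matrix
draw_segment <- function(m, p0, p1, rad) {
  H <- nrow(m); W <- ncol(m)
  len <- sqrt(sum((p1 - p0)^2))
  nstep <- max(2L, ceiling(len / 0.5))
  ts <- seq(0, 1, length.out = nstep)
  for (t in ts) {
    p <- p0 + t * (p1 - p0)
    i0 <- max(1L, floor(p[1] - rad)); i1 <- min(H, ceiling(p[1] + rad))
    j0 <- max(1L, floor(p[2] - rad)); j1 <- min(W, ceiling(p[2] + rad))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - p[1])^2, (jj - p[2])^2, "+")
    m[ii, jj] <- m[ii, jj] | (d2 <= rad^2)
  }
  m
}

#' Generate one synthetic pest scene
#'
#' Renders a textured background (base color, illumination gradient,
#' band-limited texture, pixel noise) and `n_pests` elliptical bodies with
#' thin polyline appendages. The mask is 1 exactly where a pest primitive
#' was rendered. Deterministic given the spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (numeric `[H, W, 3]` in `[0, 1]`) and `mask`
#'   (integer `[H, W]` matrix with codes {0, 1}).
#' @export
generate_scene <- function(spec = scene_spec()) {
  with_seed(spec$seed, {
    H <- spec$height; W <- spec$width
    dg <- sqrt(H^2 + W^2)
    yy <- matrix(rep(seq_len(H), W), H, W) / H - 0.5
    xx <- matrix(rep(seq_len(W), each = H), H, W) / W - 0.5
    gdir <- stats::runif(1, 0, 2 * pi)
    grad <- (cos(gdir) * yy + sin(gdir) * xx) * spec$gradient_amplitude
    tex <- matrix(0, H, W)
    for (k in 1:3) {
      f <- stats::runif(2, 2, 12)
      ph <- stats::runif(2, 0, 2 * pi)
      tex <- tex + sin(2 * pi * f[1] * yy + ph[1]) *
        sin(2 * pi * f[2] * xx + ph[2])
    }
    tex <- tex / 3 * spec$noise_amplitude
    img <- array(0, c(H, W, 3))
    cj <- stats::runif(3, -0.03, 0.03)
    for (ch in 1:3)
      img[, , ch] <- clamp01(spec$base_color[ch] + cj[ch] + grad + tex +
        matrix(stats::rnorm(H * W, 0, spec$noise_amplitude * 0.5), H, W))
    mask <- matrix(FALSE, H, W)
    n_p <- rand_int_in(spec$n_pests)
    placed <- matrix(numeric(0), ncol = 3) # cy, cx, radius
    for (p in seq_len(n_p)) {
      ok <- FALSE
      for (try in seq_len(spec$max_tries)) {
        s <- rand_in(spec$scale_range) * dg  # body diameter
        a <- s / 2
        ecc <- rand_in(spec$eccentricity)
        b <- max(a / ecc, 0.8)
        reach <- 2 * a + max(spec$appendage_thickness) # body + appendages
        if (1 + a >= H - a || 1 + a >= W - a) next # body cannot fit
        cy <- stats::runif(1, 1 + a, H - a)
        cx <- stats::runif(1, 1 + a, W - a)
        if (!spec$overlap && nrow(placed)) {
          dd <- sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)
          if (any(dd < placed[, 3] + reach + spec$min_gap)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) stop("could not place pest ", p, " after ", spec$max_tries,
                    " tries (canvas too crowded or too small)")
      placed <- rbind(placed, c(cy, cx, reach))
      th <- stats::runif(1, 0, pi)
      pm <- matrix(FALSE, H, W)
      i0 <- max(1L, floor(cy - a)); i1 <- min(H, ceiling(cy + a))
      j0 <- max(1L, floor(cx - a)); j1 <- min(W, ceiling(cx + a))
      ii <- i0:i1; jj <- j0:j1
      dy <- outer(ii - cy, rep(1, length(jj)))
      dx <- outer(rep(1, length(ii)), jj - cx)
      u <- dy * cos(th) + dx * sin(th)
      v <- -dy * sin(th) + dx * cos(th)
      pm[ii, jj] <- (u / a)^2 + (v / b)^2 <= 1
      n_app <- rand_int_in(spec$appendage_count)
      for (ap in seq_len(n_app)) {
        phi <- stats::runif(1, 0, 2 * pi)
        # boundary point of the (rotated) ellipse in direction phi
        r0 <- 0.9 / sqrt((cos(phi - th) / a)^2 + (sin(phi - th) / b)^2)
        p0 <- c(cy + r0 * cos(phi), cx + r0 * sin(phi))
        thick <- rand_in(spec$appendage_thickness)
        dir <- phi
        for (seg in 1:2) {
          len <- stats::runif(1, 0.25, 0.5) * a + 1
          p1 <- p0 + len * c(cos(dir), sin(dir))
          pm <- draw_segment(pm, p0, p1, thick / 2)
          p0 <- p1
          dir <- dir + stats::runif(1, -0.6, 0.6)
        }
      }
      # paint the pest: blend a dark chitin tone over the background
      pc <- clamp01(c(0.26, 0.19, 0.12) + stats::runif(3, -0.06, 0.06))
      idx <- which(pm)
      for (ch in 1:3) {
        pl <- img[, , ch]
        pl[idx] <- pl[idx] * (1 - spec$contrast) + pc[ch] * spec$contrast
        img[, , ch] <- pl
      }
      mask <- mask | pm
    }
    list(image = img, mask = matrix(as.integer(mask), H, W))
  })
}
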
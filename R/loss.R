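# Hybrid segmentation loss: lambda * cross-entropy + (1 - lambda) * soft
# Dice, with soft (probability-valued) targets supported throughout so
# Mixup-style labels can be consumed directly.

#' Loss configuration
#'
#' @param lambda mixing weight of the cross-entropy term, in `[0, 1]`.
#'   Default 0.4.
#' @param eps Dice smoothing constant (positive). Default 0.001.
#' @param n_classes number of classes.
#' @export
loss_config <- function(lambda = 0.4, eps = 0.001, n_classes = 2L) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (eps <= 0) stop("eps must be positive")
  list(lambda = lambda, eps = eps, n_classes = as.integer(n_classes))
}

# coerce a target (integer mask matrix with codes 0..n-1, or an already
# one-hot/soft [H, W, n] array / [L, n] matrix) to an [L, n] row-stochastic
# matrix in row-major token order
target_matrix <- function(target, n) {
  if (length(dim(target)) == 3L) {
    if (dim(target)[3] != n) stop("target class dim mismatch")
    return(map_to_tokens(target))
  }
  tm <- as.matrix(target)
  if (ncol(tm) == n && (isTRUE(attr(target, "soft")) || any(tm %% 1 != 0))) {
    if (any(tm < -1e-8 | tm > 1 + 1e-8) ||
        any(abs(rowSums(tm) - 1) > 1e-6))
      stop("soft target rows must be probabilities summing to 1")
    return(tm)
  }
  # integer class-code mask, flattened in row-major token order
  tv <- as.integer(t(tm))
  if (any(tv < 0L | tv >= n)) stop("invalid class code in target")
  y <- matrix(0, length(tv), n)
  y[cbind(seq_along(tv), tv + 1L)] <- 1
  y
}

logits_matrix <- function(logits) {
  if (length(dim(logits)) == 3L) map_to_tokens(logits) else as.matrix(logits)
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(p * y) / (sum(p) + sum(y) + eps)`, sums running over all
#' classes and pixels. In `[0, 1]`; 0 in the perfect-match limit, 1 for
#' disjoint prediction.
#'
#' @param probs per-pixel class probabilities, `[H, W, n]` array or `[L, n]`
#'   matrix with rows summing to 1.
#' @param target integer mask (codes `0..n-1`), one-hot array, or soft
#'   label matrix.
#' @param eps smoothing constant.
#' @export
dice_loss <- function(probs, target, eps = 0.001) {
  p <- logits_matrix(probs)
  if (any(p < -1e-8) || any(p > 1 + 1e-8)) stop("probs must lie in [0, 1]")
  y <- target_matrix(target, ncol(p))
  if (!all(dim(p) == dim(y))) stop("shape mismatch between probs and target")
  1 - 2 * sum(p * y) / (sum(p) + sum(y) + eps)
}

#' Mean cross-entropy loss
#'
#' Mean over pixels of minus the log softmax-probability of the true class;
#' accepts soft targets (rows summing to 1).
#'
#' @param logits per-pixel class logits, `[H, W, n]` array or `[L, n]` matrix.
#' @param target integer mask, one-hot array, or soft label matrix.
#' @export
ce_loss <- function(logits, target) {
  x <- logits_matrix(logits)
  y <- target_matrix(target, ncol(x))
  if (!all(dim(x) == dim(y))) stop("shape mismatch between logits and target")
  m <- row_max(x)
  logp <- (x - m) - log(rowSums(exp(x - m)))
  -sum(y * logp) / nrow(x)
}

#' Hybrid Dice + cross-entropy loss
#'
#' `lambda * CE + (1 - lambda) * Dice` with the Dice term computed on the
#' softmax probabilities of the logits.
#'
#' @inheritParams ce_loss
#' @param cfg a [loss_config()].
#' @export
hybrid_loss <- function(logits, target, cfg = loss_config()) {
  x <- logits_matrix(logits)
  m <- row_max(x)
  e <- exp(x - m)
  p <- e / rowSums(e)
  cfg$lambda * ce_loss(x, target) +
    (1 - cfg$lambda) * dice_loss(p, target, cfg$eps)
}

# tape-level hybrid loss; y is a constant [L, n] row-stochastic matrix
fw_hybrid_loss <- function(logits, y, cfg) {
  ce <- ad_ce(logits, y)
  p <- ad_softmax(logits)
  inter <- ad_sum(ad_mul(p, ad_const(y)))
  denom <- ad_addc(ad_sum(p), sum(y) + cfg$eps)
  dice <- ad_addc(ad_scale(ad_div(inter, denom), -2), 1)
  ad_add(ad_scale(ce, cfg$lambda), ad_scale(dice, 1 - cfg$lambda))
}
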
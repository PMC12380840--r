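# Independent brute-force oracles used across the test suite. These stay
# deliberately naive (explicit loops) so they cannot share bugs with the
# vectorized implementations they check.

# pixelwise double-loop confusion matrix
cm_oracle <- function(pred, true, n) {
  cm <- matrix(0L, n, n)
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      cm[true[i, j] + 1L, pred[i, j] + 1L] <-
        cm[true[i, j] + 1L, pred[i, j] + 1L] + 1L
    }
  }
  cm
}

pa_oracle <- function(pred, true) {
  hits <- 0L
  for (i in seq_len(nrow(pred)))
    for (j in seq_len(ncol(pred)))
      if (pred[i, j] == true[i, j]) hits <- hits + 1L
  hits / length(pred)
}

miou_oracle <- function(pred, true, n) {
  ious <- c()
  for (c in 0:(n - 1)) {
    inter <- 0L; uni <- 0L
    for (i in seq_len(nrow(pred)))
      for (j in seq_len(ncol(pred))) {
        p <- pred[i, j] == c; t <- true[i, j] == c
        if (p && t) inter <- inter + 1L
        if (p || t) uni <- uni + 1L
      }
    if (uni > 0) ious <- c(ious, inter / uni)
  }
  mean(ious)
}

# scalar-loop cross-entropy and Dice oracles
ce_oracle <- function(logits, y) {
  tot <- 0
  for (r in seq_len(nrow(logits))) {
    e <- exp(logits[r, ] - max(logits[r, ]))
    p <- e / sum(e)
    for (c in seq_len(ncol(logits))) tot <- tot - y[r, c] * log(p[c])
  }
  tot / nrow(logits)
}

dice_oracle <- function(probs, y, eps) {
  num <- 0; dp <- 0; dy <- 0
  for (r in seq_len(nrow(probs)))
    for (c in seq_len(ncol(probs))) {
      num <- num + probs[r, c] * y[r, c]
      dp <- dp + probs[r, c]
      dy <- dy + y[r, c]
    }
  1 - 2 * num / (dp + dy + eps)
}

# 8-connectivity connected-component count by flood fill
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  for (si in seq_len(H)) for (sj in seq_len(W)) {
    if (mask[si, sj] == 0 || seen[si, sj]) next
    ncomp <- ncomp + 1L
    stack <- list(c(si, sj))
    seen[si, sj] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- p[1] + di; nj <- p[2] + dj
        if (ni < 1 || ni > H || nj < 1 || nj > W) next
        if (mask[ni, nj] == 1 && !seen[ni, nj]) {
          seen[ni, nj] <- TRUE
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  ncomp
}

# random SSM parameter set for a length-L, D-channel, N-state scan
random_ssm_params <- function(L, D, N) {
  list(A_log = matrix(stats::rnorm(D * N), D, N),
       D_skip = stats::rnorm(D),
       delta = matrix(stats::runif(L * D, 0.01, 0.5), L, D),
       B = matrix(stats::rnorm(L * N), L, N),
       C = matrix(stats::rnorm(L * N), L, N))
}

# small random scene list for training smoke tests
make_scenes <- function(n, hw = 64L, seed0 = 100L) {
  lapply(seq_len(n), function(i)
    generate_scene(scene_spec(hw, hw, seed = seed0 + i)))
}

# central-difference gradient of f at x (numeric array), selected entries
num_grad_entry <- function(f, x, i, eps = 1e-6) {
  x1 <- x; x1[i] <- x1[i] + eps
  x2 <- x; x2[i] <- x2[i] - eps
  (f(x1) - f(x2)) / (2 * eps)
}
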
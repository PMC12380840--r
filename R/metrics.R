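# Pixel-level evaluation from an accumulated confusion matrix: entry (i, j)
# counts pixels of true class i predicted as class j. The matrix is additive
# across batches, so metrics are invariant to batch partitioning.

#' Create an empty n x n confusion matrix
#' @param n number of classes.
#' @export
confusion_matrix <- function(n = 2L) {
  matrix(0L, n, n, dimnames = list(true = 0:(n - 1), pred = 0:(n - 1)))
}

#' Accumulate pixel counts into a confusion matrix
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param pred,true integer masks of identical shape with class codes
#'   `0..n-1`.
#' @return the updated confusion matrix.
#' @export
update_confusion <- function(cm, pred, true) {
  n <- nrow(cm)
  if (!all(dim(pred) == dim(true))) stop("mask shape mismatch")
  pv <- as.integer(pred)
  tv <- as.integer(true)
  if (any(pv < 0L | pv >= n) || any(tv < 0L | tv >= n))
    stop("class code out of range")
  cm + matrix(tabulate(tv * n + pv + 1L, n * n), n, n, byrow = TRUE)
}

#' Pixel accuracy
#'
#' Trace over total of the confusion matrix, in `[0, 1]`.
#' @param cm an accumulated confusion matrix.
#' @export
pixel_accuracy <- function(cm) {
  tot <- sum(cm)
  if (tot <= 0) stop("empty confusion matrix")
  sum(diag(cm)) / tot
}

#' Mean intersection-over-union
#'
#' Mean over classes of `N_ii / (row_i + col_i - N_ii)`. Classes with empty
#' union (no true and no predicted pixels) are excluded from the mean.
#' @param cm an accumulated confusion matrix.
#' @export
mean_iou <- function(cm) {
  di <- diag(cm)
  union <- rowSums(cm) + colSums(cm) - di
  keep <- union > 0
  if (!any(keep)) stop("no class with nonzero union")
  mean(di[keep] / union[keep])
}

#' Evaluate a model on a dataset
#'
#' Accumulates one confusion matrix over all items and reports pixel
#' accuracy and mean IoU.
#'
#' @param model a model accepted by [predict_mask()].
#' @param data list of items, each a list with `image` (`[H, W, 3]`) and
#'   `mask` (integer matrix).
#' @param n_classes number of classes.
#' @return list with `pa`, `miou` and the confusion matrix `cm`.
#' @export
evaluate_model <- function(model, data, n_classes = 2L) {
  cm <- confusion_matrix(n_classes)
  for (item in data) {
    pred <- predict_mask(model, item$image)
    cm <- update_confusion(cm, pred, item$mask)
  }
  list(pa = pixel_accuracy(cm), miou = mean_iou(cm), cm = cm)
}
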
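# SGD training with momentum and weight decay, periodic validation, and
# checkpoint-on-best-validation (mean IoU, pixel accuracy as tie-break).

#' Training configuration
#'
#' Defaults: 3,000 iterations, batch size 24,
#' learning rate 0.001, momentum 0.9, weight decay 1e-4, validation every
#' 200 iterations.
#'
#' @param iterations number of optimizer steps.
#' @param batch_size images per step (sampled with replacement if the
#'   training set is smaller).
#' @param lr constant learning rate.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @param eval_period validate every this many iterations.
#' @param seed RNG seed for batch sampling.
#' @export
train_config <- function(iterations = 3000L, batch_size = 24L, lr = 0.001,
                         momentum = 0.9, weight_decay = 1e-4,
                         eval_period = 200L, seed = 1L) {
  stopifnot(iterations >= 1, batch_size >= 1, lr >= 0, momentum >= 0,
            momentum < 1, weight_decay >= 0, eval_period >= 1)
  list(iterations = as.integer(iterations),
       batch_size = as.integer(batch_size), lr = lr, momentum = momentum,
       weight_decay = weight_decay, eval_period = as.integer(eval_period),
       seed = as.integer(seed))
}

# nested-list parameter-tree helpers
tree_zeros <- function(p) {
  if (is.list(p)) return(lapply(p, tree_zeros))
  z <- p
  z[] <- 0
  z
}

tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- Map(function(x, y) tree_map2(x, y, f), a, b)
    attributes(out) <- attributes(a)
    return(out)
  }
  f(a, b)
}

tree_map3 <- function(a, b, c, f) {
  if (is.list(a)) {
    out <- Map(function(x, y, z) tree_map3(x, y, z, f), a, b, c)
    attributes(out) <- attributes(a)
    return(out)
  }
  f(a, b, c)
}

#' Train a segmentation model
#'
#' Runs SGD over the hybrid loss; every `eval_period` iterations computes
#' validation pixel accuracy and mean IoU from a freshly accumulated
#' confusion matrix and keeps the weights only on strict improvement of
#' mean IoU (ties broken by pixel accuracy).
#'
#' @param model a `pestseg_model` from [build_model()].
#' @param train_data,val_data lists of items, each with `image`
#'   (`[H, W, 3]`) and `mask` (integer matrix, or `[H, W, n]` soft labels
#'   for training items).
#' @param tcfg a [train_config()].
#' @param lcfg a [loss_config()].
#' @param out_dir optional directory for the checkpoint
#'   (`checkpoint.rds`) and the `history.csv` log.
#' @param verbose print progress lines.
#' @return an object of class `pestseg_fit`: `model` (best-validation
#'   weights), `final_model`, `history` (data.frame of validation
#'   evaluations), `loss` (per-iteration training loss) and `best`.
#' @export
train_model <- function(model, train_data, val_data = list(),
                        tcfg = train_config(), lcfg = loss_config(),
                        out_dir = NULL, verbose = FALSE) {
  if (!length(train_data)) stop("empty training set")
  set.seed(tcfg$seed)
  params <- model$params
  vel <- tree_zeros(params)
  n <- lcfg$n_classes
  best <- list(miou = -Inf, pa = -Inf, params = NULL, iteration = NA_integer_)
  hist_it <- integer(0)
  hist_loss <- hist_pa <- hist_miou <- numeric(0)
  loss_vec <- numeric(tcfg$iterations)
  for (it in seq_len(tcfg$iterations)) {
    idx <- sample.int(length(train_data), tcfg$batch_size,
                      replace = tcfg$batch_size > length(train_data))
    wp <- wrap_params(params)
    loss_node <- NULL
    for (i in idx) {
      item <- train_data[[i]]
      lg <- fw_model(model, wp, item$image)
      y <- target_matrix(item$mask, n)
      l <- fw_hybrid_loss(lg, y, lcfg)
      loss_node <- if (is.null(loss_node)) l else ad_add(loss_node, l)
    }
    loss_node <- ad_scale(loss_node, 1 / length(idx))
    lv <- loss_node$v[1]
    if (!is.finite(lv))
      stop("non-finite training loss at iteration ", it)
    loss_vec[it] <- lv
    ad_backward(loss_node)
    g <- grad_tree(wp)
    vel <- tree_map3(vel, g, params, function(v, gg, p)
      tcfg$momentum * v + gg + tcfg$weight_decay * p)
    params <- tree_map2(params, vel, function(p, v) p - tcfg$lr * v)
    if (it %% tcfg$eval_period == 0 && length(val_data)) {
      cur <- model
      cur$params <- params
      ev <- evaluate_model(cur, val_data, n)
      hist_it <- c(hist_it, it)
      hist_loss <- c(hist_loss, lv)
      hist_pa <- c(hist_pa, ev$pa)
      hist_miou <- c(hist_miou, ev$miou)
      if (ev$miou > best$miou ||
          (ev$miou == best$miou && ev$pa > best$pa)) {
        best <- list(miou = ev$miou, pa = ev$pa, params = params,
                     iteration = it)
        if (!is.null(out_dir)) {
          dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
          save_checkpoint(cur, file.path(out_dir, "checkpoint.rds"),
                          best = best[c("miou", "pa", "iteration")])
        }
      }
      if (verbose)
        message(sprintf("iter %d  loss %.4f  val PA %.4f  val MIoU %.4f",
                        it, lv, ev$pa, ev$miou))
    }
  }
  history <- data.frame(iteration = hist_it, loss = hist_loss,
                        pa = hist_pa, miou = hist_miou)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
  }
  if (is.null(best$params)) { # no validation ran
    best$params <- params
  }
  best_model <- model
  best_model$params <- best$params
  final_model <- model
  final_model$params <- params
  structure(list(model = best_model, final_model = final_model,
                 history = history, loss = loss_vec,
                 best = best[c("miou", "pa", "iteration")]),
            class = "pestseg_fit")
}

#' Save model weights and config to an RDS checkpoint
#' @param model a `pestseg_model`; `path` output file; `history`, `best`
#'   optional metadata stored alongside.
#' @export
save_checkpoint <- function(model, path, history = NULL, best = NULL) {
  saveRDS(list(params = model$params, config = model$config,
               n_params = model$n_params, history = history, best = best),
          path)
  invisible(path)
}

#' Load a model from a checkpoint written by [save_checkpoint()]
#' @param path checkpoint file.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  m <- structure(list(params = ck$params, config = ck$config,
                      n_params = ck$n_params), class = "pestseg_model")
  attr(m, "history") <- ck$history
  attr(m, "best") <- ck$best
  m
}
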
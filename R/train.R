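#' Training configuration
#'
#' Optimization protocol for the artifact-removal networks: Adam with MSE
#' loss, initial learning rate 0.005, batch size 4, 150 epochs and 10-fold
#' cross-validation by default (scale these down for CPU experiments).
#'
#' @param learning_rate Adam step size (constant; no schedule by default).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs per fold.
#' @param k_folds Number of cross-validation folds (>= 2).
#' @param seed Seed controlling shuffling and fold assignment.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.005, batch_size = 4L,
                         epochs = 150L, k_folds = 10L, seed = 1L) {
  stop_if(k_folds < 2, "k_folds must be >= 2")
  stop_if(learning_rate <= 0 || batch_size < 1 || epochs < 1,
          "learning_rate, batch_size and epochs must be positive")
  structure(list(optimizer = "adam", loss = "mse",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Disjoint k-fold assignment
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of `k` disjoint index vectors whose union is `1:n`.
#' @export
kfold_split <- function(n, k, seed = NULL) {
  stop_if(n < k, "fewer samples than folds")
  with_seed(seed, {
    idx <- sample.int(n)
    split(idx, rep_len(seq_len(k), n))
  })
}

# one forward/backward/Adam step on a batch; returns the batch loss
train_step <- function(model, xb, yb, lr) {
  tp <- new_tape(model$ps, training = TRUE, grad = TRUE)
  out <- model$fwd(tp, tp_input(tp, xb))
  loss <- tp_mse(tp, out, yb)
  ps_zero_grads(model$ps)
  tp_backward(tp, loss)
  adam_step(model$ps, lr)
  tp_value(tp, loss)
}

#' Train a network with Adam on MSE loss
#'
#' Updates the model's parameters in place and records the full history:
#' one loss per optimizer step plus per-epoch validation SSIM when a
#' validation set is given.
#'
#' @param model A `msdnet` (modified in place).
#' @param inputs,targets Training images, `H x W x N` arrays in \[0,1\].
#' @param cfg A `train_config` (its `k_folds` is ignored here).
#' @param val_inputs,val_targets Optional validation set.
#' @param on_epoch Optional callback `function(model, epoch, val_ssim)` run
#'   after every epoch (used e.g. for best-checkpoint tracking).
#' @param verbose Print one line per epoch.
#' @return An `msdnet_fit`: list with the model, per-step losses and a
#'   per-epoch data frame.
#' @export
train_network <- function(model, inputs, targets, cfg = train_config(),
                          val_inputs = NULL, val_targets = NULL,
                          on_epoch = NULL, verbose = FALSE) {
  if (is.matrix(inputs)) dim(inputs) <- c(dim(inputs), 1L)
  if (is.matrix(targets)) dim(targets) <- c(dim(targets), 1L)
  n <- dim(inputs)[3]
  stop_if(n == 0, "empty training set")
  d <- dim(inputs)[1:2]
  step_loss <- numeric(0)
  ep_rows <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (at in seq(1, n, by = cfg$batch_size)) {
        sel <- ord[at:min(n, at + cfg$batch_size - 1L)]
        xb <- inputs[, , sel, drop = FALSE]
        yb <- targets[, , sel, drop = FALSE]
        dim(xb) <- c(d, 1L, length(sel))
        dim(yb) <- c(d, 1L, length(sel))
        losses <- c(losses, train_step(model, xb, yb, cfg$learning_rate))
      }
      val_ssim <- NA_real_
      if (!is.null(val_inputs)) {
        val_ssim <- mean(metrics_report(predict(model, val_inputs),
                                        val_targets)$per_image$ssim)
      }
      step_loss <- c(step_loss, losses)
      ep_rows[[ep]] <- data.frame(epoch = ep, train_loss = mean(losses),
                                  val_ssim = val_ssim)
      if (!is.null(on_epoch)) on_epoch(model, ep, val_ssim)
      if (verbose) {
        message(sprintf("epoch %3d  loss %.5f  val ssim %s", ep, mean(losses),
                        ifelse(is.na(val_ssim), "-", sprintf("%.4f", val_ssim))))
      }
    }
  })
  structure(list(model = model, step_loss = step_loss,
                 epochs = do.call(rbind, ep_rows), config = cfg),
            class = "msdnet_fit")
}

#' @export
print.msdnet_fit <- function(x, ...) {
  ep <- x$epochs
  cat(sprintf("<msdnet_fit> %d epochs, %d steps, final loss %.5f%s\n",
              nrow(ep), length(x$step_loss), ep$train_loss[nrow(ep)],
              if (!is.na(ep$val_ssim[nrow(ep)]))
                sprintf(", final val SSIM %.4f", ep$val_ssim[nrow(ep)]) else ""))
  invisible(x)
}

#' k-fold cross-validated training
#'
#' Folds are drawn from the dataset's train+validation pool by a seeded
#' shuffle; the held-out test split is untouched. Each fold trains a fresh
#' model built by `model_builder`; the best checkpoint is the parameter
#' snapshot with the highest validation SSIM across all folds and epochs.
#'
#' @param dataset A `pat_dataset` (or a list with `inputs`/`targets`
#'   arrays, in which case all samples form the pool).
#' @param model_builder Zero-argument function returning a fresh `msdnet`.
#' @param cfg A `train_config`.
#' @param verbose Print per-epoch lines.
#' @return A `pat_cv`: per-fold `msdnet_fit` histories (without models),
#'   plus `best` (fold, epoch, val_ssim, model with the best weights).
#' @export
kfold_train <- function(dataset, model_builder, cfg = train_config(),
                        verbose = FALSE) {
  if (inherits(dataset, "pat_dataset")) {
    pool_idx <- sort(c(dataset$split$train, dataset$split$val))
    inputs <- dataset$inputs[, , pool_idx, drop = FALSE]
    targets <- dataset$targets[, , pool_idx, drop = FALSE]
  } else {
    inputs <- dataset$inputs
    targets <- dataset$targets
  }
  n <- dim(inputs)[3]
  stop_if(n < cfg$k_folds, "dataset smaller than the number of folds")
  folds <- kfold_split(n, cfg$k_folds, seed = cfg$seed)
  histories <- vector("list", cfg$k_folds)
  best <- list(val_ssim = -Inf, fold = NA, epoch = NA, values = NULL)
  for (f in seq_len(cfg$k_folds)) {
    val_idx <- folds[[f]]
    tr_idx <- setdiff(seq_len(n), val_idx)
    model <- model_builder()
    fit <- train_network(model,
                         inputs[, , tr_idx, drop = FALSE],
                         targets[, , tr_idx, drop = FALSE],
                         cfg,
                         val_inputs = inputs[, , val_idx, drop = FALSE],
                         val_targets = targets[, , val_idx, drop = FALSE],
                         on_epoch = function(m, ep, vs) {
                           if (!is.na(vs) && vs > best$val_ssim) {
                             best <<- list(val_ssim = vs, fold = f, epoch = ep,
                                           values = m$ps$values)
                           }
                         },
                         verbose = verbose)
    histories[[f]] <- fit[c("step_loss", "epochs")]
  }
  best_model <- model_builder()
  best_model$ps$values <- best$values
  structure(list(folds = histories,
                 best = list(fold = best$fold, epoch = best$epoch,
                             val_ssim = best$val_ssim, model = best_model),
                 config = cfg),
            class = "pat_cv")
}

#' @export
print.pat_cv <- function(x, ...) {
  cat(sprintf("<pat_cv> %d folds x %d epochs; best val SSIM %.4f (fold %d, epoch %d)\n",
              length(x$folds), x$config$epochs, x$best$val_ssim,
              x$best$fold, x$best$epoch))
  invisible(x)
}
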
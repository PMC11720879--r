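# Reverse-mode autodiff over 4D tensors (dim H x W x C x N, column-major).
#
# A tape records each operation's output together with a vector-Jacobian
# closure; backward() walks the tape in reverse creation order. Parameters
# live in a separate store shared by all tapes built from the same model, so
# gradients accumulate there and the Adam state persists across steps.

new_param_store <- function() {
  ps <- new.env(parent = emptyenv())
  ps$values <- list()
  ps$grads <- list()
  ps$trainable <- logical()
  ps$m <- list()
  ps$v <- list()
  ps$t <- 0L
  ps
}

ps_add <- function(ps, value, trainable = TRUE) {
  id <- length(ps$values) + 1L
  ps$values[[id]] <- value
  ps$grads[[id]] <- NULL
  ps$trainable[id] <- trainable
  id
}

ps_zero_grads <- function(ps) {
  ps$grads <- vector("list", length(ps$values))
  invisible(ps)
}

ps_accum <- function(ps, id, g) {
  cur <- ps$grads[[id]]
  ps$grads[[id]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

ps_n_params <- function(ps) {
  sum(vapply(which(ps$trainable), function(i) length(ps$values[[i]]), 0))
}

# One Adam update over all trainable parameters carrying a gradient.
adam_step <- function(ps, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  ps$t <- ps$t + 1L
  b1t <- 1 - beta1^ps$t
  b2t <- 1 - beta2^ps$t
  for (i in seq_along(ps$values)) {
    g <- ps$grads[[i]]
    if (is.null(g) || !ps$trainable[i]) next
    if (length(ps$m) < i || is.null(ps$m[[i]])) {
      ps$m[[i]] <- g * 0
      ps$v[[i]] <- g * 0
    }
    ps$m[[i]] <- beta1 * ps$m[[i]] + (1 - beta1) * g
    ps$v[[i]] <- beta2 * ps$v[[i]] + (1 - beta2) * g * g
    ps$values[[i]] <- ps$values[[i]] -
      lr * (ps$m[[i]] / b1t) / (sqrt(ps$v[[i]] / b2t) + eps)
  }
  invisible(ps)
}

new_tape <- function(ps, training = FALSE, grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 128L)
  tp$n <- 0L
  tp$ps <- ps
  tp$training <- training
  tp$grad <- grad
  tp
}

tp_push <- function(tp, value, parents = integer(), vjp = NULL) {
  force(value) # value/parent expressions may push nodes themselves
  force(parents)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(value = value, parents = parents,
                        vjp = if (tp$grad) vjp)
  tp$n <- n
  n
}

tp_value <- function(tp, id) {
  force(id) # ids may be expressions that push onto the tape themselves
  tp$nodes[[id]]$value
}

tp_input <- function(tp, x) tp_push(tp, x)

# Backpropagate from scalar node `id`; parameter gradients accumulate in the
# store, and the gradient w.r.t. any requested input node ids is returned.
tp_backward <- function(tp, id, want = integer()) {
  grads <- vector("list", tp$n)
  grads[[id]] <- 1
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    node <- tp$nodes[[i]]
    if (is.null(node$vjp)) next
    pg <- node$vjp(g)
    for (j in seq_along(node$parents)) {
      p <- node$parents[j]
      if (is.null(pg[[j]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
    if (!(i %in% want)) grads[[i]] <- NULL # free memory as we go
  }
  grads[want]
}

# ---- primitive ops ---------------------------------------------------------

# multi-input convolution: sum of per-source convolutions, equivalent to a
# single convolution over the channel concatenation of the sources
tp_conv_multi <- function(tp, xs, wids, bid, dil = 1L) {
  ps <- tp$ps
  xs <- as.integer(xs)
  vals <- lapply(xs, tp_value, tp = tp)
  ws <- lapply(wids, function(i) ps$values[[i]])
  y <- conv_multi_fwd(vals, ws, ps$values[[bid]], as.integer(dil), use_single())
  tp_push(tp, y, parents = xs, vjp = function(g) {
    r <- conv_multi_bwd(vals, ws, g, as.integer(dil), use_single())
    for (j in seq_along(wids)) ps_accum(ps, wids[j], r$gws[[j]])
    ps_accum(ps, bid, r$gb)
    r$gxs
  })
}

tp_conv <- function(tp, x, wid, bid, dil = 1L) {
  ps <- tp$ps
  xv <- tp_value(tp, x)
  w <- ps$values[[wid]]
  y <- conv2d_fwd(xv, w, ps$values[[bid]], as.integer(dil), use_single())
  tp_push(tp, y, parents = x, vjp = function(g) {
    r <- conv2d_bwd(xv, w, g, as.integer(dil), use_single())
    ps_accum(ps, wid, r$gw)
    ps_accum(ps, bid, r$gb)
    list(r$gx)
  })
}

tp_relu <- function(tp, x) {
  y <- relu_fwd(tp_value(tp, x))
  tp_push(tp, y, parents = x, vjp = function(g) list(relu_bwd(y, g)))
}

tp_sigmoid <- function(tp, x) {
  s <- sigmoid_fwd(tp_value(tp, x))
  tp_push(tp, s, parents = x, vjp = function(g) list(g * s * (1 - s)))
}

tp_add <- function(tp, a, b) {
  tp_push(tp, tp_value(tp, a) + tp_value(tp, b), parents = c(a, b),
          vjp = function(g) list(g, g))
}

tp_maxpool <- function(tp, x) {
  xv <- tp_value(tp, x)
  r <- maxpool2_fwd(xv)
  xd <- dim(xv)
  tp_push(tp, r$y, parents = x,
          vjp = function(g) list(maxpool2_bwd(r$idx, g, xd)))
}

tp_upsample <- function(tp, x) {
  xv <- tp_value(tp, x)
  tp_push(tp, upsample2x_fwd(xv), parents = x,
          vjp = function(g) list(upsample2x_bwd(g)))
}

tp_concat <- function(tp, ids) {
  if (length(ids) == 1L) return(ids[[1]])
  vals <- lapply(ids, tp_value, tp = tp)
  cs <- vapply(vals, function(v) dim(v)[3], 0)
  out <- concat_fwd(vals)
  tp_push(tp, out, parents = as.integer(ids), vjp = function(g) {
    at <- 0
    lapply(seq_along(cs), function(i) {
      s <- slice_channels(g, at + 1, cs[i])
      at <<- at + cs[i]
      s
    })
  })
}

# Batch normalization over (H, W, N) per channel (optionally fused with a
# ReLU); running statistics are updated in training mode and used verbatim
# in evaluation mode.
tp_bn <- function(tp, x, gid, bid, rmid, rvid, momentum = 0.1, eps = 1e-5,
                  relu = FALSE) {
  ps <- tp$ps
  xv <- tp_value(tp, x)
  r <- bn_relu_fwd(xv, ps$values[[gid]], ps$values[[bid]],
                   ps$values[[rmid]], ps$values[[rvid]],
                   tp$training, momentum, eps, relu)
  if (tp$training) {
    ps$values[[rmid]] <- r$rmean
    ps$values[[rvid]] <- r$rvar
  }
  y <- r$y
  train <- tp$training
  gamma <- ps$values[[gid]]
  tp_push(tp, y, parents = x, vjp = function(g) {
    b <- bn_relu_bwd(xv, y, g, gamma, r$mu, r$sd, train, relu)
    ps_accum(ps, gid, b$dgamma)
    ps_accum(ps, bid, b$dbeta)
    list(b$gx)
  })
}

tp_mse <- function(tp, y, target) {
  yv <- tp_value(tp, y)
  diff <- yv - target
  n <- length(diff)
  tp_push(tp, mean(diff * diff), parents = y,
          vjp = function(g) list(g * 2 * diff / n))
}
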
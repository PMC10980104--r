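# Minimal CPU neural-network core used by the GAN and classifier modules.
#
# Activations are numeric arrays with dim (H, W, C, N) for convolutional
# stages and plain (N, features) matrices for fully connected stages.
# Convolutions are evaluated as im2col (C++) followed by a BLAS matrix
# product; transposed convolutions reuse the same primitives with the roles
# of im2col/col2im exchanged. Layers are environments so that parameters and
# Adam state can be updated in place during training.

new_nn_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- character(0)
  e$decay_params <- character(0)
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

#' @keywords internal
init_weight <- function(dims, scheme = c("dcgan", "he"), fan_in = NULL) {
  scheme <- match.arg(scheme)
  sd <- if (scheme == "dcgan") 0.02 else sqrt(2 / fan_in)
  array(stats::rnorm(prod(dims), 0, sd), dim = dims)
}

nn_linear <- function(in_features, out_features, init = "dcgan") {
  l <- new_nn_layer("linear")
  l$W <- init_weight(c(in_features, out_features), init, fan_in = in_features)
  l$b <- numeric(out_features)
  l$param_names <- c("W", "b")
  l$decay_params <- "W"
  l
}

nn_conv <- function(in_ch, out_ch, k, stride = 1, pad = 0, init = "dcgan") {
  l <- new_nn_layer("conv")
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$in_ch <- in_ch; l$out_ch <- out_ch
  l$W <- init_weight(c(k, k, in_ch, out_ch), init, fan_in = k * k * in_ch)
  l$b <- numeric(out_ch)
  l$param_names <- c("W", "b")
  l$decay_params <- "W"
  l
}

nn_convT <- function(in_ch, out_ch, k, stride = 2, pad = 1, init = "dcgan") {
  l <- new_nn_layer("convT")
  l$k <- k; l$stride <- stride; l$pad <- pad
  l$in_ch <- in_ch; l$out_ch <- out_ch
  l$W <- init_weight(c(k, k, out_ch, in_ch), init, fan_in = k * k * in_ch)
  l$b <- numeric(out_ch)
  l$param_names <- c("W", "b")
  l$decay_params <- "W"
  l
}

nn_bn2d <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new_nn_layer("bn2d")
  l$gamma <- 1 + stats::rnorm(ch, 0, 0.02)
  l$beta <- numeric(ch)
  l$running_mean <- numeric(ch)
  l$running_var <- rep(1, ch)
  l$momentum <- momentum; l$eps <- eps
  l$param_names <- c("gamma", "beta")
  l
}

nn_relu <- function() new_nn_layer("relu")
nn_lrelu <- function(alpha = 0.2) { l <- new_nn_layer("lrelu"); l$alpha <- alpha; l }
nn_tanh <- function() new_nn_layer("tanh")
nn_maxpool <- function(k, stride, pad = 0) {
  l <- new_nn_layer("maxpool"); l$k <- k; l$stride <- stride; l$pad <- pad; l
}
nn_flatten <- function() new_nn_layer("flatten")
nn_reshape <- function(h, w, ch) {
  l <- new_nn_layer("reshape"); l$h <- h; l$w <- w; l$ch <- ch; l
}

nn_net <- function(...) structure(list(...), class = "cg_net")

conv_out_size <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

layer_forward <- function(l, x, training = TRUE) {
  switch(l$type,
    linear = {
      l$x <- x
      y <- x %*% l$W
      y + rep(as.numeric(l$b), each = nrow(y))
    },
    conv = {
      d <- dim(x)
      l$in_dim <- d
      cols <- cg_im2col(as.numeric(x), d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
      l$cols <- cols
      oh <- conv_out_size(d[1], l$k, l$stride, l$pad)
      ow <- conv_out_size(d[2], l$k, l$stride, l$pad)
      Wm <- matrix(l$W, l$k * l$k * l$in_ch, l$out_ch)
      y <- crossprod(Wm, cols) + as.numeric(l$b)
      aperm(array(y, c(l$out_ch, oh, ow, d[4])), c(2, 3, 1, 4))
    },
    convT = {
      d <- dim(x)
      l$in_dim <- d
      xm <- matrix(aperm(x, c(3, 1, 2, 4)), l$in_ch, d[1] * d[2] * d[4])
      l$xm <- xm
      Wm <- matrix(l$W, l$k * l$k * l$out_ch, l$in_ch)
      cols <- Wm %*% xm
      oh <- (d[1] - 1L) * l$stride - 2L * l$pad + l$k
      ow <- (d[2] - 1L) * l$stride - 2L * l$pad + l$k
      y <- array(cg_col2im(cols, oh, ow, l$out_ch, d[4], l$k, l$stride, l$pad),
                 c(oh, ow, l$out_ch, d[4]))
      for (c in seq_len(l$out_ch)) y[, , c, ] <- y[, , c, ] + l$b[c]
      y
    },
    bn2d = {
      d <- dim(x)
      l$in_dim <- d
      C <- d[3]
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), prod(d[c(1, 2, 4)]), C)
      if (training) {
        m <- colMeans(xm)
        v <- colMeans(xm^2) - m^2
        l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * m
        l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * v
      } else {
        m <- l$running_mean
        v <- l$running_var
      }
      invstd <- 1 / sqrt(v + l$eps)
      xhat <- sweep(sweep(xm, 2, m, "-"), 2, invstd, "*")
      if (training) { l$xhat <- xhat; l$invstd <- invstd }
      ym <- sweep(sweep(xhat, 2, l$gamma, "*"), 2, l$beta, "+")
      aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    },
    relu = { l$mask <- x > 0; x * l$mask },
    lrelu = { l$mask <- x > 0; ifelse(l$mask, x, l$alpha * x) },
    tanh = { y <- tanh(x); l$y <- y; y },
    maxpool = {
      d <- dim(x)
      l$in_dim <- d
      r <- cg_maxpool_fwd(as.numeric(x), d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
      l$idx <- r$idx
      oh <- conv_out_size(d[1], l$k, l$stride, l$pad)
      ow <- conv_out_size(d[2], l$k, l$stride, l$pad)
      array(r$y, c(oh, ow, d[3], d[4]))
    },
    flatten = {
      d <- dim(x)
      l$in_dim <- d
      t(matrix(x, prod(d[1:3]), d[4]))
    },
    reshape = {
      array(t(x), c(l$h, l$w, l$ch, nrow(x)))
    },
    stop("unknown layer type: ", l$type)
  )
}

layer_backward <- function(l, dy) {
  switch(l$type,
    linear = {
      l$dW <- crossprod(l$x, dy)
      l$db <- colSums(dy)
      dy %*% t(l$W)
    },
    conv = {
      d <- l$in_dim
      oh <- conv_out_size(d[1], l$k, l$stride, l$pad)
      ow <- conv_out_size(d[2], l$k, l$stride, l$pad)
      dym <- matrix(aperm(dy, c(3, 1, 2, 4)), l$out_ch, oh * ow * d[4])
      l$dW <- array(l$cols %*% t(dym), dim(l$W))
      l$db <- rowSums(dym)
      Wm <- matrix(l$W, l$k * l$k * l$in_ch, l$out_ch)
      dx <- cg_col2im(Wm %*% dym, d[1], d[2], d[3], d[4], l$k, l$stride, l$pad)
      l$cols <- NULL
      array(dx, d)
    },
    convT = {
      d <- l$in_dim
      dd <- dim(dy)
      dcols <- cg_im2col(as.numeric(dy), dd[1], dd[2], dd[3], dd[4], l$k, l$stride, l$pad)
      Wm <- matrix(l$W, l$k * l$k * l$out_ch, l$in_ch)
      l$dW <- array(dcols %*% t(l$xm), dim(l$W))
      db <- numeric(l$out_ch)
      for (c in seq_len(l$out_ch)) db[c] <- sum(dy[, , c, ])
      l$db <- db
      dxm <- crossprod(Wm, dcols)
      l$xm <- NULL
      aperm(array(dxm, c(l$in_ch, d[1], d[2], d[4])), c(2, 3, 1, 4))
    },
    bn2d = {
      d <- l$in_dim
      C <- d[3]
      M <- prod(d[c(1, 2, 4)])
      dym <- matrix(aperm(dy, c(1, 2, 4, 3)), M, C)
      l$dgamma <- colSums(dym * l$xhat)
      l$dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, l$gamma, "*")
      # standard batch-norm backward in terms of xhat
      t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
      t2 <- sweep(l$xhat, 2, colMeans(dxhat * l$xhat), "*")
      dxm <- sweep(t1 - t2, 2, l$invstd, "*")
      l$xhat <- NULL
      aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
    },
    relu = dy * l$mask,
    lrelu = ifelse(l$mask, dy, l$alpha * dy),
    tanh = dy * (1 - l$y^2),
    maxpool = {
      d <- l$in_dim
      dx <- cg_maxpool_bwd(as.numeric(dy), l$idx, prod(d))
      array(dx, d)
    },
    flatten = array(t(dy), l$in_dim),
    reshape = {
      d <- dim(dy)
      t(matrix(dy, prod(d[1:3]), d[4]))
    },
    stop("unknown layer type: ", l$type)
  )
}

nn_forward <- function(net, x, training = TRUE) {
  for (l in net) x <- layer_forward(l, x, training = training)
  x
}

nn_backward <- function(net, dy) {
  for (l in rev(net)) dy <- layer_backward(l, dy)
  dy
}

nn_n_params <- function(net) {
  sum(vapply(net, function(l) sum(vapply(l$param_names, function(p) length(l[[p]]), 0)), 0))
}

# ---- Adam -------------------------------------------------------------------

nn_adam_init <- function(net) {
  for (l in net) {
    l$adam <- lapply(stats::setNames(l$param_names, l$param_names), function(p) {
      # zero clones preserve the parameter's structure (vector vs array)
      list(m = l[[p]] * 0, v = l[[p]] * 0)
    })
  }
  invisible(net)
}

nn_adam_step <- function(net, t, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (l in net) {
    for (p in l$param_names) {
      g <- l[[paste0("d", p)]]
      if (is.null(g)) next
      if (weight_decay > 0 && p %in% l$decay_params) g <- g + weight_decay * l[[p]]
      st <- l$adam[[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      l$adam[[p]] <- st
      l[[p]] <- l[[p]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    }
  }
  invisible(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Save the gradients currently held by a net, e.g. to accumulate the real and
# fake halves of a discriminator update computed in two backward passes.
nn_collect_grads <- function(net) {
  lapply(net, function(l)
    lapply(stats::setNames(l$param_names, l$param_names),
           function(p) l[[paste0("d", p)]]))
}

nn_add_grads <- function(net, saved) {
  for (i in seq_along(net)) {
    l <- net[[i]]
    for (p in l$param_names) {
      g <- saved[[i]][[p]]
      if (!is.null(g)) l[[paste0("d", p)]] <- l[[paste0("d", p)]] + g
    }
  }
  invisible(net)
}

# ---- loss heads -------------------------------------------------------------

# Numerically stable sigmoid cross-entropy on logits with 0/1 targets.
# Returns the mean loss and the gradient with respect to the logits.
sigmoid_bce <- function(logits, targets) {
  p <- stats::plogis(logits)
  loss <- mean(pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits))))
  list(loss = loss, grad = (p - targets) / length(logits), prob = p)
}

# Softmax cross-entropy on an (N, K) logit matrix with integer labels in 1..K.
softmax_ce <- function(logits, labels) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  n <- nrow(logits)
  loss <- -mean(log(pmax(probs[cbind(seq_len(n), labels)], 1e-12)))
  grad <- probs
  grad[cbind(seq_len(n), labels)] <- grad[cbind(seq_len(n), labels)] - 1
  list(loss = loss, grad = grad / n, probs = probs)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# ---- serialization helpers --------------------------------------------------

nn_state <- function(net) {
  lapply(net, function(l) {
    s <- lapply(stats::setNames(l$param_names, l$param_names), function(p) l[[p]])
    if (l$type == "bn2d") {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

nn_load_state <- function(net, state) {
  stopifnot(length(net) == length(state))
  for (i in seq_along(net)) {
    for (p in names(state[[i]])) net[[i]][[p]] <- state[[i]][[p]]
  }
  invisible(net)
}
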
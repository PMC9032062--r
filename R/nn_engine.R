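# Internal neural-network engine.
#
# Layers are mutable environments exposing init/fwd/bwd closures; tensors in
# the convolutional stack are (H = time, W = electrode, C, N) arrays, the
# recurrent/dense stage uses (N, T, F) / (N, F). Heavy kernels live in
# src/nn_ops.cpp. The final dense layer emits logits; the binary
# cross-entropy loss and the sigmoid are fused in the training loop for
# numerical stability.

new_layer <- function(type) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- list()
  l$grads <- list()
  class(l) <- "nn_layer"
  l
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

layer_zeropad_time <- function(pad) {
  l <- new_layer("zeropad_time")
  l$pad <- as.integer(pad)
  l$init <- function(s) { l$in_shape <- s; c(s[1] + 2L * l$pad, s[2], s[3]) }
  l$fwd <- function(x, training) {
    d <- dim(x)
    y <- array(0, c(d[1] + 2L * l$pad, d[2], d[3], d[4]))
    y[l$pad + seq_len(d[1]), , , ] <- x
    l$xdim <- d
    y
  }
  l$bwd <- function(dy) dy[l$pad + seq_len(l$xdim[1]), , , , drop = FALSE]
  l
}

layer_batchnorm <- function(momentum = 0.9, eps = 1e-3,
                            activation_alpha = NULL) {
  l <- new_layer("batchnorm")
  l$momentum <- momentum; l$eps <- eps
  # when activation_alpha is set, a leaky rectifier is fused onto the output
  l$alpha <- if (is.null(activation_alpha)) -1 else activation_alpha
  l$init <- function(s) {
    C <- s[3]
    l$params <- list(gamma = rep(1, C), beta = rep(0, C))
    l$running_mean <- rep(0, C); l$running_var <- rep(1, C)
    s
  }
  l$fwd <- function(x, training) {
    if (training) {
      r <- nn_bn_fwd(x, l$params$gamma, l$params$beta, l$eps, l$alpha)
      l$x <- x; l$mean <- r$mean; l$var <- r$var
      m <- l$momentum
      l$running_mean <- m * l$running_mean + (1 - m) * r$mean
      l$running_var <- m * l$running_var + (1 - m) * r$var
      r$y
    } else {
      nn_bn_infer(x, l$params$gamma, l$params$beta,
                  l$running_mean, l$running_var, l$eps, l$alpha)
    }
  }
  l$bwd <- function(dy) {
    r <- nn_bn_bwd(l$x, dy, l$params$gamma, l$params$beta, l$mean, l$var,
                   l$eps, l$alpha)
    l$grads <- list(gamma = r$dgamma, beta = r$dbeta)
    l$x <- NULL
    r$dx
  }
  l
}

layer_conv2d <- function(filters, kernel) {
  l <- new_layer("conv2d")
  l$filters <- as.integer(filters); l$kernel <- as.integer(kernel)
  l$init <- function(s) {
    kh <- l$kernel[1]; kw <- l$kernel[2]; cin <- s[3]
    l$params <- list(
      W = glorot(kh * kw * cin, kh * kw * l$filters, c(kh, kw, cin, l$filters)),
      b = rep(0, l$filters))
    c(s[1], s[2], l$filters)
  }
  l$fwd <- function(x, training) {
    l$x <- x
    nn_conv2d_fwd(x, l$params$W, l$params$b)
  }
  l$bwd <- function(dy) {
    r <- nn_conv2d_bwd(l$x, l$params$W, dy, TRUE)
    l$grads <- list(W = r$dw, b = r$db)
    l$x <- NULL
    r$dx
  }
  l
}

layer_leakyrelu <- function(alpha = 0.3) {
  l <- new_layer("leakyrelu")
  l$alpha <- alpha
  l$init <- function(s) s
  l$fwd <- function(x, training) { l$x <- x; nn_leaky_fwd(x, l$alpha) }
  l$bwd <- function(dy) { dx <- nn_leaky_bwd(l$x, dy, l$alpha); l$x <- NULL; dx }
  l
}

layer_maxpool <- function(kernel, stride) {
  l <- new_layer("maxpool")
  l$kernel <- as.integer(kernel); l$stride <- as.integer(stride)
  l$init <- function(s) {
    c((s[1] - l$kernel[1]) %/% l$stride[1] + 1L,
      (s[2] - l$kernel[2]) %/% l$stride[2] + 1L, s[3])
  }
  l$fwd <- function(x, training) {
    r <- nn_maxpool_fwd(x, l$kernel[1], l$kernel[2], l$stride[1], l$stride[2])
    l$idx <- r$idx; l$xdim <- dim(x)
    r$y
  }
  l$bwd <- function(dy) {
    dx <- nn_maxpool_bwd(l$idx, dy, l$xdim)
    l$idx <- NULL
    dx
  }
  l
}

layer_dropout <- function(rate) {
  l <- new_layer("dropout")
  l$rate <- rate
  l$init <- function(s) s
  l$fwd <- function(x, training) {
    if (!training || l$rate <= 0) return(x)
    # in place: x is the private intermediate of the previous layer
    l$mask <- nn_dropout_fwd(x, l$rate, sample.int(2147483647L, 1L))
    x
  }
  l$bwd <- function(dy) {
    if (is.null(l$mask)) return(dy)
    dx <- nn_dropout_bwd(l$mask, dy, l$rate)
    l$mask <- NULL
    dx
  }
  l
}

## (T, 1, C, N) or (T, W, C, N) -> sequence (N, T, W*C)
layer_to_sequence <- function() {
  l <- new_layer("to_sequence")
  l$init <- function(s) { l$in_shape <- s; c(s[1], s[2] * s[3]) }
  l$fwd <- function(x, training) {
    d <- dim(x)
    dim(x) <- c(d[1], d[2] * d[3], d[4])
    aperm(x, c(3, 1, 2))
  }
  l$bwd <- function(dy) {
    s <- l$in_shape
    dx <- aperm(dy, c(2, 3, 1))
    dim(dx) <- c(s[1], s[2], s[3], dim(dy)[1])
    dx
  }
  l
}

## (T, ch, 1, N) -> (T, 1, ch, N): electrodes become input channels
layer_electrodes_to_channels <- function() {
  l <- new_layer("electrodes_to_channels")
  l$init <- function(s) c(s[1], s[3], s[2])
  l$fwd <- function(x, training) aperm(x, c(1, 3, 2, 4))
  l$bwd <- function(dy) aperm(dy, c(1, 3, 2, 4))
  l
}

sigm <- function(x) 1 / (1 + exp(-x))

layer_gru <- function(units, return_sequences = FALSE) {
  l <- new_layer("gru")
  l$units <- as.integer(units); l$return_sequences <- return_sequences
  l$init <- function(s) {          # s = (T, F)
    FF <- s[2]; U <- l$units
    l$params <- list(Wx = glorot(FF, U, c(FF, 3L * U)),
                     Wh = glorot(U, U, c(U, 3L * U)),
                     b = rep(0, 3L * U))
    if (l$return_sequences) c(s[1], U) else U
  }
  l$fwd <- function(x, training) {
    N <- dim(x)[1]; TT <- dim(x)[2]; U <- l$units
    iz <- seq_len(U); ir <- U + iz; ih <- 2L * U + iz
    Wx <- l$params$Wx; Wh <- l$params$Wh; b <- l$params$b
    h <- matrix(0, N, U)
    Hs <- array(0, c(N, TT, U))
    cache <- vector("list", TT)
    for (t in seq_len(TT)) {
      xt <- matrix(x[, t, ], N)
      g <- xt %*% Wx
      z <- sigm(g[, iz, drop = FALSE] + h %*% Wh[, iz] + rep(b[iz], each = N))
      r <- sigm(g[, ir, drop = FALSE] + h %*% Wh[, ir] + rep(b[ir], each = N))
      hh <- tanh(g[, ih, drop = FALSE] + (r * h) %*% Wh[, ih] + rep(b[ih], each = N))
      hn <- z * h + (1 - z) * hh
      cache[[t]] <- list(z = z, r = r, hh = hh, hprev = h)
      h <- hn
      Hs[, t, ] <- h
    }
    l$x <- x; l$cache <- cache
    if (l$return_sequences) Hs else h
  }
  l$bwd <- function(dy) {
    x <- l$x; cache <- l$cache
    N <- dim(x)[1]; TT <- dim(x)[2]; U <- l$units
    iz <- seq_len(U); ir <- U + iz; ih <- 2L * U + iz
    Wx <- l$params$Wx; Wh <- l$params$Wh
    dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(3L * U)
    dX <- array(0, dim(x))
    dh <- if (l$return_sequences) matrix(0, N, U) else matrix(dy, N)
    for (t in rev(seq_len(TT))) {
      if (l$return_sequences) dh <- dh + matrix(dy[, t, ], N)
      cc <- cache[[t]]
      z <- cc$z; r <- cc$r; hh <- cc$hh; hprev <- cc$hprev
      xt <- matrix(x[, t, ], N)
      dz <- dh * (hprev - hh)
      dhh <- dh * (1 - z)
      dhprev <- dh * z
      da_hh <- dhh * (1 - hh^2)
      drh <- da_hh %*% t(Wh[, ih])
      dr <- drh * hprev
      dhprev <- dhprev + drh * r
      da_z <- dz * z * (1 - z)
      da_r <- dr * r * (1 - r)
      dWx[, iz] <- dWx[, iz] + t(xt) %*% da_z
      dWx[, ir] <- dWx[, ir] + t(xt) %*% da_r
      dWx[, ih] <- dWx[, ih] + t(xt) %*% da_hh
      dWh[, iz] <- dWh[, iz] + t(hprev) %*% da_z
      dWh[, ir] <- dWh[, ir] + t(hprev) %*% da_r
      dWh[, ih] <- dWh[, ih] + t(r * hprev) %*% da_hh
      db[iz] <- db[iz] + colSums(da_z)
      db[ir] <- db[ir] + colSums(da_r)
      db[ih] <- db[ih] + colSums(da_hh)
      dhprev <- dhprev + da_z %*% t(Wh[, iz]) + da_r %*% t(Wh[, ir])
      dX[, t, ] <- da_z %*% t(Wx[, iz]) + da_r %*% t(Wx[, ir]) +
        da_hh %*% t(Wx[, ih])
      dh <- dhprev
    }
    l$grads <- list(Wx = dWx, Wh = dWh, b = db)
    l$x <- NULL; l$cache <- NULL
    dX
  }
  l
}

layer_lstm <- function(units, return_sequences = FALSE) {
  l <- new_layer("lstm")
  l$units <- as.integer(units); l$return_sequences <- return_sequences
  l$init <- function(s) {
    FF <- s[2]; U <- l$units
    b <- numeric(4L * U)
    b[U + seq_len(U)] <- 1          # forget-gate bias
    l$params <- list(Wx = glorot(FF, U, c(FF, 4L * U)),
                     Wh = glorot(U, U, c(U, 4L * U)), b = b)
    if (l$return_sequences) c(s[1], U) else U
  }
  l$fwd <- function(x, training) {
    N <- dim(x)[1]; TT <- dim(x)[2]; U <- l$units
    ii <- seq_len(U); i_f <- U + ii; ig <- 2L * U + ii; io <- 3L * U + ii
    Wx <- l$params$Wx; Wh <- l$params$Wh; b <- l$params$b
    h <- matrix(0, N, U); cs <- matrix(0, N, U)
    Hs <- array(0, c(N, TT, U))
    cache <- vector("list", TT)
    for (t in seq_len(TT)) {
      xt <- matrix(x[, t, ], N)
      g <- xt %*% Wx + h %*% Wh + rep(b, each = N)
      i <- sigm(g[, ii, drop = FALSE]); f <- sigm(g[, i_f, drop = FALSE])
      gg <- tanh(g[, ig, drop = FALSE]); o <- sigm(g[, io, drop = FALSE])
      cn <- f * cs + i * gg
      hn <- o * tanh(cn)
      cache[[t]] <- list(i = i, f = f, g = gg, o = o, cprev = cs, c = cn,
                         hprev = h)
      h <- hn; cs <- cn
      Hs[, t, ] <- h
    }
    l$x <- x; l$cache <- cache
    if (l$return_sequences) Hs else h
  }
  l$bwd <- function(dy) {
    x <- l$x; cache <- l$cache
    N <- dim(x)[1]; TT <- dim(x)[2]; U <- l$units
    ii <- seq_len(U); i_f <- U + ii; ig <- 2L * U + ii; io <- 3L * U + ii
    Wx <- l$params$Wx; Wh <- l$params$Wh
    dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4L * U)
    dX <- array(0, dim(x))
    dh <- if (l$return_sequences) matrix(0, N, U) else matrix(dy, N)
    dc <- matrix(0, N, U)
    for (t in rev(seq_len(TT))) {
      if (l$return_sequences) dh <- dh + matrix(dy[, t, ], N)
      cc <- cache[[t]]
      tc <- tanh(cc$c)
      do_ <- dh * tc
      dc <- dc + dh * cc$o * (1 - tc^2)
      di <- dc * cc$g; df <- dc * cc$cprev; dg <- dc * cc$i
      dcprev <- dc * cc$f
      da <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                  dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
      xt <- matrix(x[, t, ], N)
      dWx <- dWx + t(xt) %*% da
      dWh <- dWh + t(cc$hprev) %*% da
      db <- db + colSums(da)
      dX[, t, ] <- da %*% t(Wx)
      dh <- da %*% t(Wh)
      dc <- dcprev
    }
    l$grads <- list(Wx = dWx, Wh = dWh, b = db)
    l$x <- NULL; l$cache <- NULL
    dX
  }
  l
}

layer_flatten <- function() {
  l <- new_layer("flatten")
  l$init <- function(s) { l$in_shape <- s; prod(s) }
  l$fwd <- function(x, training) {
    d <- dim(x)
    l$xdim <- d
    t(matrix(x, prod(d[-length(d)]), d[length(d)]))
  }
  l$bwd <- function(dy) array(t(dy), l$xdim)
  l
}

layer_dense <- function(units, activation = c("linear", "relu")) {
  l <- new_layer("dense")
  l$units <- as.integer(units); l$activation <- match.arg(activation)
  l$init <- function(s) {
    FF <- s[1]
    l$params <- list(W = glorot(FF, l$units, c(FF, l$units)),
                     b = rep(0, l$units))
    l$units
  }
  l$fwd <- function(x, training) {
    l$x <- x
    y <- x %*% l$params$W + rep(l$params$b, each = nrow(x))
    if (l$activation == "relu") { l$pre <- y; y <- pmax(y, 0) }
    y
  }
  l$bwd <- function(dy) {
    if (l$activation == "relu") dy <- dy * (l$pre > 0)
    l$grads <- list(W = t(l$x) %*% dy, b = colSums(dy))
    dx <- dy %*% t(l$params$W)
    l$x <- NULL; l$pre <- NULL
    dx
  }
  l
}

## ---- network assembly -----------------------------------------------------

build_network <- function(layers, input_shape, seed = 1L) {
  set.seed(seed)
  shape <- input_shape
  shapes <- list(shape)
  for (l in layers) {
    shape <- l$init(shape)
    shapes[[length(shapes) + 1L]] <- shape
  }
  net <- new.env(parent = emptyenv())
  net$layers <- layers
  net$input_shape <- input_shape
  net$shapes <- shapes
  net$seed <- seed
  class(net) <- "nn_network"
  net
}

net_forward <- function(net, x, training = FALSE) {
  for (l in net$layers) x <- l$fwd(x, training)
  x
}

net_backward <- function(net, dz) {
  for (l in rev(net$layers)) dz <- l$bwd(dz)
  invisible(dz)
}

net_param_layers <- function(net)
  Filter(function(l) length(l$params) > 0L, net$layers)

net_n_params <- function(net)
  sum(vapply(net_param_layers(net),
             function(l) sum(vapply(l$params, length, numeric(1))), numeric(1)))

net_get_weights <- function(net) {
  lapply(net$layers, function(l)
    list(params = l$params,
         running_mean = l$running_mean, running_var = l$running_var))
}

net_set_weights <- function(net, w) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (length(w[[i]]$params)) l$params <- w[[i]]$params
    if (!is.null(w[[i]]$running_mean)) {
      l$running_mean <- w[[i]]$running_mean
      l$running_var <- w[[i]]$running_var
    }
  }
  invisible(net)
}

adam_init <- function(net) {
  for (l in net_param_layers(net)) {
    l$adam_m <- lapply(l$params, function(p) array(0, dim(p) %||% length(p)))
    l$adam_v <- lapply(l$params, function(p) array(0, dim(p) %||% length(p)))
  }
  invisible(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(net, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (l in net_param_layers(net)) {
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g * g
      l$params[[nm]] <- l$params[[nm]] -
        lr * (l$adam_m[[nm]] / c1) / (sqrt(l$adam_v[[nm]] / c2) + eps)
    }
  }
  invisible(net)
}

## stable binary cross-entropy on logits; returns loss and dL/dz (mean red.)
bce_logits <- function(z, y) {
  z <- as.numeric(z)
  loss <- mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
  list(loss = loss, dz = matrix((sigm(z) - y) / length(y), ncol = 1L))
}

slice_batch <- function(x, idx) {
  nd <- length(dim(x))
  if (nd == 4L) x[, , , idx, drop = FALSE] else x[idx, , drop = FALSE]
}

net_predict_prob <- function(net, x, batch = 64L) {
  n <- dim(x)[length(dim(x))]
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    idx <- i:min(n, i + batch - 1L)
    out[idx] <- sigm(as.numeric(net_forward(net, slice_batch(x, idx), FALSE)))
    i <- i + batch
  }
  out
}

## single-learning-rate fit with early stopping on validation accuracy
net_fit <- function(net, x, y, val_x, val_y, lr, epochs, batch_size = 32L,
                    patience = 10L, eval_every = NULL, seed = 1L,
                    verbose = FALSE) {
  set.seed(seed)
  adam_init(net)
  n <- dim(x)[length(dim(x))]
  best_acc <- -Inf; best_w <- NULL; since_best <- 0L
  hist <- list()
  step <- 0L
  evaluate <- function(epoch) {
    acc <- mean((net_predict_prob(net, val_x) >= 0.5) == (val_y == 1L))
    hist[[length(hist) + 1L]] <<- data.frame(epoch = epoch, step = step,
                                             val_accuracy = acc)
    if (acc > best_acc) {
      best_acc <<- acc; best_w <<- net_get_weights(net); since_best <<- 0L
    } else since_best <<- since_best + 1L
    if (verbose) message(sprintf("  step %d: val acc %.3f", step, acc))
    acc
  }
  stop_now <- FALSE
  for (epoch in seq_len(epochs)) {
    idx <- sample(n)
    nb <- max(1L, floor(n / batch_size))
    for (b in seq_len(nb)) {
      take <- idx[((b - 1L) * batch_size + 1L):min(n, b * batch_size)]
      z <- net_forward(net, slice_batch(x, take), TRUE)
      lb <- bce_logits(z, y[take])
      net_backward(net, lb$dz)
      step <- step + 1L
      adam_step(net, lr, step)
      if (!is.null(eval_every) && step %% eval_every == 0L) {
        evaluate(epoch)
        if (since_best >= patience) { stop_now <- TRUE; break }
      }
    }
    if (!stop_now && is.null(eval_every)) {
      evaluate(epoch)
      if (since_best >= patience) stop_now <- TRUE
    }
    if (stop_now) break
  }
  ## make sure the final parameter state competes for the best snapshot
  if (!stop_now && !is.null(eval_every) && step %% eval_every != 0L)
    evaluate(epochs)
  if (is.null(best_w)) evaluate(epochs)
  net_set_weights(net, best_w)
  list(best_val_accuracy = best_acc, history = do.call(rbind, hist))
}
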
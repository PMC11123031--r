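# Compact dense-network engine: fully connected layers, ReLU/sigmoid/linear
# activations, inverted dropout, Adam, mini-batch training with early
# stopping on a held-out fraction of rows. Deterministic given a seed.
# Used by the autoencoder (MSE loss) and the MLP classifier (BCE loss).

nn_init <- function(layer_sizes) {
  n <- length(layer_sizes) - 1L
  W <- vector("list", n)
  b <- vector("list", n)
  for (i in seq_len(n)) {
    fan_in <- layer_sizes[i]
    fan_out <- layer_sizes[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))  # Glorot uniform
    W[[i]] <- matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
    b[[i]] <- rep(0, fan_out)
  }
  list(W = W, b = b)
}

nn_act <- function(z, kind) {
  switch(kind,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z)
}

nn_act_grad <- function(a, kind) {
  # gradient expressed in terms of the activation output
  switch(kind,
         relu = (a > 0) * 1,
         sigmoid = a * (1 - a),
         linear = array(1, dim(a)))
}

# Forward pass; returns activations per layer. When training with dropout,
# inverted-dropout masks are applied to hidden activations.
nn_forward <- function(par, X, activations, dropout = 0, training = FALSE) {
  n <- length(par$W)
  A <- vector("list", n + 1L)
  masks <- vector("list", n)
  A[[1L]] <- X
  for (i in seq_len(n)) {
    z <- A[[i]] %*% par$W[[i]]
    z <- sweep(z, 2, par$b[[i]], "+")
    a <- nn_act(z, activations[i])
    if (training && dropout > 0 && i < n) {
      mask <- matrix(stats::rbinom(length(a), 1, 1 - dropout), nrow(a)) /
        (1 - dropout)
      a <- a * mask
      masks[[i]] <- mask
    }
    A[[i + 1L]] <- a
  }
  list(A = A, masks = masks)
}

# Backward pass for MSE or BCE; for BCE the output activation must be
# sigmoid (the delta simplifies to (pred - y)).
nn_backward <- function(par, fw, Y, activations, loss) {
  n <- length(par$W)
  A <- fw$A
  pred <- A[[n + 1L]]
  m <- nrow(Y)
  delta <- switch(loss,
                  mse = (pred - Y) * nn_act_grad(pred, activations[n]) * (2 / m),
                  bce = (pred - Y) / m)
  gW <- vector("list", n)
  gb <- vector("list", n)
  for (i in rev(seq_len(n))) {
    gW[[i]] <- crossprod(A[[i]], delta)
    gb[[i]] <- colSums(delta)
    if (i > 1L) {
      delta <- delta %*% t(par$W[[i]])
      if (!is.null(fw$masks[[i - 1L]])) delta <- delta * fw$masks[[i - 1L]]
      delta <- delta * nn_act_grad(A[[i]], activations[i - 1L])
    }
  }
  list(W = gW, b = gb)
}

nn_loss <- function(pred, Y, loss) {
  if (loss == "mse") {
    mean((pred - Y)^2)
  } else {
    eps <- 1e-12
    p <- pmin(pmax(pred, eps), 1 - eps)
    -mean(Y * log(p) + (1 - Y) * log(1 - p))
  }
}

# Train with Adam. Returns fitted parameters plus the per-epoch training
# loss history and the epoch at which the best validation loss occurred.
nn_train <- function(X, Y, hidden, activations_hidden = "relu",
                     activation_out = "linear", loss = c("mse", "bce"),
                     epochs = 100L, batch_size = 32L, learning_rate = 1e-3,
                     dropout = 0, val_fraction = 0.1, patience = 10L,
                     seed = 1L) {
  loss <- match.arg(loss)
  layer_sizes <- c(ncol(X), hidden, ncol(Y))
  n_layers <- length(layer_sizes) - 1L
  activations <- c(rep(activations_hidden, n_layers - 1L), activation_out)

  with_seed(seed, {
    par <- nn_init(layer_sizes)
    n <- nrow(X)
    n_val <- if (val_fraction > 0 && n >= 10L) max(1L, floor(val_fraction * n)) else 0L
    idx <- sample.int(n)
    val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer()
    tr_idx <- setdiff(idx, val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Xv <- X[val_idx, , drop = FALSE]; Yv <- Y[val_idx, , drop = FALSE]

    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t <- 0L
    history <- numeric(0)
    best_val <- Inf; best_par <- par; best_epoch <- 0L; stall <- 0L

    for (epoch in seq_len(epochs)) {
      ord <- sample.int(nrow(Xtr))
      starts <- seq(1L, nrow(Xtr), by = batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + batch_size - 1L, nrow(Xtr))]
        fw <- nn_forward(par, Xtr[rows, , drop = FALSE], activations,
                         dropout = dropout, training = TRUE)
        gr <- nn_backward(par, fw, Ytr[rows, , drop = FALSE], activations, loss)
        t <- t + 1L
        for (i in seq_len(n_layers)) {
          mW[[i]] <- beta1 * mW[[i]] + (1 - beta1) * gr$W[[i]]
          vW[[i]] <- beta2 * vW[[i]] + (1 - beta2) * gr$W[[i]]^2
          mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * gr$b[[i]]
          vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * gr$b[[i]]^2
          mhW <- mW[[i]] / (1 - beta1^t); vhW <- vW[[i]] / (1 - beta2^t)
          mhb <- mb[[i]] / (1 - beta1^t); vhb <- vb[[i]] / (1 - beta2^t)
          par$W[[i]] <- par$W[[i]] - learning_rate * mhW / (sqrt(vhW) + eps)
          par$b[[i]] <- par$b[[i]] - learning_rate * mhb / (sqrt(vhb) + eps)
        }
      }
      pred_tr <- nn_forward(par, Xtr, activations)$A[[n_layers + 1L]]
      history <- c(history, nn_loss(pred_tr, Ytr, loss))
      if (n_val > 0L) {
        pred_v <- nn_forward(par, Xv, activations)$A[[n_layers + 1L]]
        vl <- nn_loss(pred_v, Yv, loss)
        if (vl < best_val - 1e-9) {
          best_val <- vl; best_par <- par; best_epoch <- epoch; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= patience) break
        }
      } else {
        best_par <- par; best_epoch <- epoch
      }
    }
    list(par = best_par, activations = activations, history = history,
         best_epoch = best_epoch, layer_sizes = layer_sizes)
  })
}

nn_predict <- function(fit, X, upto_layer = NULL) {
  n <- length(fit$par$W)
  k <- upto_layer %||% n
  A <- X
  for (i in seq_len(k)) {
    z <- sweep(A %*% fit$par$W[[i]], 2, fit$par$b[[i]], "+")
    A <- nn_act(z, fit$activations[i])
  }
  A
}
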
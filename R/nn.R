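# Dense feed-forward network trained by mini-batch Adam, with an
# elastic-net weight penalty lambda * ((1 - gamma) * sum(W^2) +
# gamma * sum(|W|)) and early stopping on a held-out validation split.
# Hidden activation is tanh (rectifiers trained poorly beyond one hidden
# layer on these low-dimensional standardised inputs); L = 0 hidden layers
# reduces to (multinomial) linear / logistic regression.  Written in
# vectorised base R; adequate for the 3m-feature problems this package
# targets.

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

nn_init <- function(p_in, hidden, p_out) {
  sizes <- c(p_in, hidden, p_out)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    # variance-preserving Gaussian initialisation
    W[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L], 0,
                           sqrt(1 / sizes[l])), sizes[l], sizes[l + 1L])
    b[[l]] <- rep(0, sizes[l + 1L])
  }
  list(W = W, b = b)
}

nn_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  if (L > 1L) {
    for (l in seq_len(L - 1L)) {
      acts[[l + 1L]] <- tanh(sweep(acts[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+"))
    }
  }
  z_out <- sweep(acts[[L]] %*% net$W[[L]], 2L, net$b[[L]], "+")
  list(acts = acts, z_out = z_out)
}

nn_output <- function(net, X, task) {
  z <- nn_forward(net, X)$z_out
  if (task == "classification") softmax_rows(z) else z
}

# data loss (no penalty); Y one-hot for classification
nn_data_loss <- function(net, X, Y, task) {
  out <- nn_output(net, X, task)
  if (task == "classification") {
    -mean(rowSums(Y * log(pmax(out, 1e-12))))
  } else {
    mean((out - Y)^2)
  }
}

# one Adam step on a mini-batch; returns updated state
nn_batch_step <- function(state, Xb, Yb, task, lambda, gamma, lr) {
  net <- state$net
  L <- length(net$W)
  fw <- nn_forward(net, Xb)
  nb <- nrow(Xb)
  if (task == "classification") {
    delta <- (softmax_rows(fw$z_out) - Yb) / nb
  } else {
    delta <- 2 * (fw$z_out - Yb) / (nb * ncol(Yb))
  }
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(fw$acts[[l]], delta) +
      lambda * (2 * (1 - gamma) * net$W[[l]] + gamma * sign(net$W[[l]]))
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * (1 - fw$acts[[l]]^2)
    }
  }
  # Adam
  st <- state
  st$t <- st$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^st$t; corr2 <- 1 - b2^st$t
  for (l in seq_len(L)) {
    st$mW[[l]] <- b1 * st$mW[[l]] + (1 - b1) * gW[[l]]
    st$vW[[l]] <- b2 * st$vW[[l]] + (1 - b2) * gW[[l]]^2
    st$mb[[l]] <- b1 * st$mb[[l]] + (1 - b1) * gb[[l]]
    st$vb[[l]] <- b2 * st$vb[[l]] + (1 - b2) * gb[[l]]^2
    st$net$W[[l]] <- st$net$W[[l]] -
      lr * (st$mW[[l]] / corr1) / (sqrt(st$vW[[l]] / corr2) + eps)
    st$net$b[[l]] <- st$net$b[[l]] -
      lr * (st$mb[[l]] / corr1) / (sqrt(st$vb[[l]] / corr2) + eps)
  }
  st
}

# Train one network.  X standardised by the caller; Y one-hot (classification)
# or numeric matrix (regression).  Early stopping restores the best weights.
nn_train <- function(X, Y, n_hidden_layers, lambda, gamma,
                     hidden_width = 64L, max_epochs = 500L, patience = 50L,
                     batch_size = 128L, lr = 1e-3, val_frac = 0.1,
                     task = c("classification", "regression")) {
  task <- match.arg(task)
  n <- nrow(X)
  n_val <- max(1L, round(val_frac * n))
  idx <- sample.int(n)
  val <- idx[seq_len(n_val)]
  tr <- idx[-seq_len(n_val)]
  Xtr <- X[tr, , drop = FALSE]; Ytr <- Y[tr, , drop = FALSE]
  Xval <- X[val, , drop = FALSE]; Yval <- Y[val, , drop = FALSE]

  hidden <- rep(hidden_width, n_hidden_layers)
  net <- nn_init(ncol(X), hidden, ncol(Y))
  zero_like <- function(x) lapply(x, function(w) w * 0)
  state <- list(net = net, mW = zero_like(net$W), vW = zero_like(net$W),
                mb = zero_like(net$b), vb = zero_like(net$b), t = 0L)

  best_loss <- Inf; best_net <- state$net; since_best <- 0L
  n_tr <- nrow(Xtr)
  cur_lr <- lr
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1L, n_tr, by = batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + batch_size - 1L, n_tr)]
      state <- nn_batch_step(state, Xtr[bi, , drop = FALSE],
                             Ytr[bi, , drop = FALSE], task, lambda, gamma,
                             cur_lr)
    }
    vloss <- nn_data_loss(state$net, Xval, Yval, task)
    if (is.finite(vloss) && vloss < best_loss - 1e-7) {
      best_loss <- vloss; best_net <- state$net; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      # reduce-on-plateau: halve the step size and resume from the best
      # weights when validation stalls for a third of the patience window
      if (since_best %% max(patience %/% 3L, 10L) == 0L) {
        cur_lr <- cur_lr / 2
        state$net <- best_net
      }
      if (since_best >= patience) break
    }
  }
  list(net = best_net, val_loss = best_loss, epochs = epoch, task = task,
       n_hidden_layers = n_hidden_layers, lambda = lambda, gamma = gamma,
       hidden_width = hidden_width)
}
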
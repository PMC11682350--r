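# Internal dense feed-forward network: leaky-ReLU layers, inverted dropout,
# Adam with per-epoch learning-rate decay, MSE loss with L1 and L2 weight
# penalties. Kept deliberately small and explicit: the recipe search needs
# exact vector-Jacobian products through this net, so the forward/backward
# pair lives here rather than behind an opaque fitting routine.

leaky_relu <- function(z, slope = 0.01) pmax(z, 0) + slope * pmin(z, 0)
leaky_relu_grad <- function(z, slope = 0.01) ifelse(z > 0, 1, slope)

mlp_init <- function(layer_sizes, seed) {
  set.seed(seed)
  L <- length(layer_sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    n_in <- layer_sizes[l]; n_out <- layer_sizes[l + 1]
    W[[l]] <- matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
    b[[l]] <- numeric(n_out)
  }
  list(W = W, b = b, layer_sizes = layer_sizes)
}

# X: n x d matrix. Returns activations (post-nonlinearity) per layer plus
# pre-activations; dropout masks (already scaled 1/(1-p)) applied to the
# stated hidden layers' activations when supplied.
mlp_forward_full <- function(net, X, slope = 0.01, masks = NULL) {
  L <- length(net$W)
  Z <- vector("list", L); A <- vector("list", L)
  inp <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(inp %*% net$W[[l]], 2, net$b[[l]], "+")
    A[[l]] <- leaky_relu(Z[[l]], slope)
    if (!is.null(masks) && !is.null(masks[[l]])) A[[l]] <- A[[l]] * masks[[l]]
    inp <- A[[l]]
  }
  list(Z = Z, A = A)
}

mlp_forward <- function(net, X, slope = 0.01) {
  mlp_forward_full(net, X, slope)$A[[length(net$W)]]
}

# Gradient of  v . f(x)  with respect to the input x (single spectrum).
# Dropout is off: this is the inference-time Jacobian the search uses.
mlp_input_vjp <- function(net, x, v, slope = 0.01) {
  fw <- mlp_forward_full(net, matrix(x, nrow = 1), slope)
  L <- length(net$W)
  d <- matrix(v, nrow = 1) * leaky_relu_grad(fw$Z[[L]], slope)
  for (l in seq(L, 2, length.out = max(0, L - 1))) {
    d_prev <- d %*% t(net$W[[l]])
    d <- d_prev * leaky_relu_grad(fw$Z[[l - 1]], slope)
  }
  as.vector(d %*% t(net$W[[1]]))
}

# One SGD/Adam training run. X: n x d max-normalized spectra, Y: n x k
# targets in [0,1]. cfg is a predictor_config.
mlp_train <- function(net, X, Y, cfg) {
  L <- length(net$W)
  n <- nrow(X)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(bb) bb * 0); vb <- mb
  lr <- cfg$lr
  t_step <- 0
  loss_trace <- numeric(cfg$max_epochs)
  batch <- min(cfg$minibatch, n)
  n_orig <- if (cfg$augment_mix) max(1L, floor(batch * (1 - cfg$augment_frac)))
            else batch
  n_aug <- batch - n_orig

  for (epoch in seq_len(cfg$max_epochs)) {
    perm <- sample.int(n)
    n_batches <- max(1L, floor(n / n_orig))
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      take <- perm[((bi - 1) * n_orig) %% n + seq_len(n_orig)]
      take <- ((take - 1) %% n) + 1
      Xb <- X[take, , drop = FALSE]
      Yb <- Y[take, , drop = FALSE]
      if (n_aug > 0) {
        aug <- augment_batch(X, Y, n_aug, noise_frac = cfg$augment_noise_frac)
        Xb <- rbind(Xb, aug$spectra)
        Yb <- rbind(Yb, aug$targets)
      }
      nb <- nrow(Xb)

      masks <- vector("list", L)
      for (l in seq_len(L)) {
        p <- cfg$dropout[l]
        if (!is.na(p) && p > 0)
          masks[[l]] <- matrix(stats::rbinom(nb * ncol(net$W[[l]]), 1, 1 - p) /
                                 (1 - p), nb, ncol(net$W[[l]]))
      }
      fw <- mlp_forward_full(net, Xb, cfg$leaky_slope, masks)
      out <- fw$A[[L]]
      err <- out - Yb
      epoch_loss <- epoch_loss + mean(err^2)

      d <- (2 / length(err)) * err
      if (!is.null(masks[[L]])) d <- d * masks[[L]]
      d <- d * leaky_relu_grad(fw$Z[[L]], cfg$leaky_slope)
      t_step <- t_step + 1
      for (l in seq(L, 1)) {
        A_prev <- if (l == 1) Xb else fw$A[[l - 1]]
        gW <- crossprod(A_prev, d) + cfg$l1_coeff * sign(net$W[[l]]) +
          2 * cfg$layer_l2 * net$W[[l]]
        gb <- colSums(d)
        if (l > 1) {
          d <- d %*% t(net$W[[l]])
          if (!is.null(masks[[l - 1]])) d <- d * masks[[l - 1]]
          d <- d * leaky_relu_grad(fw$Z[[l - 1]], cfg$leaky_slope)
        }
        mW[[l]] <- cfg$adam_beta1 * mW[[l]] + (1 - cfg$adam_beta1) * gW
        vW[[l]] <- cfg$adam_beta2 * vW[[l]] + (1 - cfg$adam_beta2) * gW^2
        mb[[l]] <- cfg$adam_beta1 * mb[[l]] + (1 - cfg$adam_beta1) * gb
        vb[[l]] <- cfg$adam_beta2 * vb[[l]] + (1 - cfg$adam_beta2) * gb^2
        mhW <- mW[[l]] / (1 - cfg$adam_beta1^t_step)
        vhW <- vW[[l]] / (1 - cfg$adam_beta2^t_step)
        mhb <- mb[[l]] / (1 - cfg$adam_beta1^t_step)
        vhb <- vb[[l]] / (1 - cfg$adam_beta2^t_step)
        net$W[[l]] <- net$W[[l]] - lr * mhW / (sqrt(vhW) + 1e-8)
        net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + 1e-8)
      }
    }
    loss_trace[epoch] <- epoch_loss / n_batches
    lr <- lr * cfg$lr_drop_factor
  }
  list(net = net, loss_trace = loss_trace)
}
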
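# Fixture builders shared across the suite. Everything is generated in code
# at test time; seeds are fixed so runs are reproducible.

# Untrained small predictor with random (seeded) weights: enough structure
# for gradient and forward-pass checks without any training cost.
tiny_predictor <- function(n_desc = 6, seed = 1, hidden = 16) {
  cfg <- predictor_config(preset = "reduced",
                          layer_sizes = c(201L, hidden, n_desc),
                          dropout = rep(NA_real_, 2),
                          max_epochs = 0, seed = seed)
  net <- scentforge:::mlp_init(cfg$layer_sizes, seed)
  structure(list(config = cfg, W = net$W, b = net$b,
                 vocabulary = sprintf("d%02d", seq_len(n_desc)),
                 loss_trace = numeric(0)),
            class = "odor_predictor")
}

# Hand-assembled basis with sparse random component spectra (rows scaled to
# max 1, as fit_components() leaves them).
random_basis <- function(K = 5, seed = 1, n_oils = 10, n_peaks = 25) {
  set.seed(seed)
  H <- matrix(0, K, 201)
  for (k in seq_len(K)) {
    pos <- sample.int(201, n_peaks)
    H[k, pos] <- runif(n_peaks, 0.1, 1)
  }
  H <- H / apply(H, 1, max)
  W <- matrix(runif(n_oils * K), n_oils, K)
  dimnames(W) <- list(paste0("oil_", seq_len(n_oils)),
                      sprintf("component_%02d", seq_len(K)))
  dimnames(H) <- list(colnames(W), mz_labels())
  structure(list(W = W, H = H, K = as.integer(K), fit_loss = NA_real_,
                 loss_trace = numeric(0), n_iter = 0L, converged = TRUE,
                 seed = as.integer(seed)),
            class = "odor_basis")
}

# Central finite differences of the search loss with respect to the raw
# recipe: the independent oracle for the analytic gradient.
fd_recipe_gradient <- function(recipe, basis, predictor, target, h = 1e-5) {
  vapply(seq_along(recipe), function(i) {
    e <- numeric(length(recipe)); e[i] <- h
    lp <- forward_recipe(recipe + e, basis, predictor, target)$loss
    lm <- forward_recipe(recipe - e, basis, predictor, target)$loss
    (lp - lm) / (2 * h)
  }, numeric(1))
}

# Brute-force non-negative least squares by enumerating active sets:
# oracle for project_nnls on small bases.
nnls_bruteforce <- function(A, b) {
  p <- ncol(A)
  best <- list(x = numeric(p), rss = sum(b^2))
  for (mask in seq_len(2^p - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    x <- numeric(p)
    cf <- tryCatch(qr.solve(A[, sel, drop = FALSE], b),
                   error = function(e) NULL)
    if (is.null(cf) || any(cf < 0)) next
    x[sel] <- cf
    rss <- sum((b - A %*% x)^2)
    if (rss < best$rss - 1e-12) best <- list(x = x, rss = rss)
  }
  best
}

# Learnable-by-construction fixture for predictor validation: oils are
# sparse mixtures of latent component spectra and each binary descriptor
# flags the presence of one latent component, so labels are deterministic
# functions of the spectrum.
latent_activity_fixture <- function(n_oils = 24, n_latent = 8, seed = 21) {
  sim <- generate_library(synthetic_config(
    n_oils = n_oils, n_latent = n_latent, n_descriptors = n_latent,
    loading_sparsity = 0.4, noise_level = 0, descriptor_noise = 0,
    seed = seed))
  desc <- descriptor_matrix(1 * (sim$truth$loadings > 0),
                            names = rownames(sim$library),
                            vocabulary = sprintf("latent_%02d",
                                                 seq_len(n_latent)))
  list(library = sim$library, descriptors = desc, truth = sim$truth)
}
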
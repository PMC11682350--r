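#' Configuration of the odor-descriptor predictor
#'
#' A fully connected feed-forward network maps a max-normalized 201-bin
#' mass spectrum to real-valued scores for each odor descriptor. Every
#' layer, including the output, uses a leaky ReLU (slope 0.01); training
#' minimizes mean squared error against the 0/1 labels with an L1 penalty
#' on the weights and a per-layer L2 penalty, using Adam with per-epoch
#' learning-rate decay, heavy dropout on the late hidden layers, and
#' mixture/noise data augmentation.
#'
#' Two presets are provided. `"full"` is the fidelity architecture
#' (201-4754-3565-2377-423-39, dropout 0.9 and 0.75 on the 2377 and 423
#' layers, L1 0.005, L2 1e-4, Adam lr 0.001 decayed by 0.995 per epoch,
#' minibatch 150, 1000 epochs). `"reduced"` (201-256-128-39) is a
#' desk-scale architecture for development and validation on synthetic
#' fixtures: light dropout (0.1 on the 128 layer), L1 1e-4, lr 0.003,
#' 300 epochs. Dropout rates are DROP probabilities.
#'
#' @param preset `"full"` or `"reduced"`; explicit arguments override
#'   preset values.
#' @param layer_sizes Integer vector of layer widths, input first, output
#'   last.
#' @param dropout Numeric vector of drop probabilities, one per weight
#'   layer (the entry for layer `l` drops activations of layer `l`); `NA`
#'   or 0 disables.
#' @param leaky_slope Negative-side slope of every leaky ReLU.
#' @param l1_coeff L1 penalty coefficient on all weights.
#' @param layer_l2 L2 penalty coefficient on all weights.
#' @param lr,lr_drop_factor Initial Adam learning rate and its per-epoch
#'   multiplicative decay.
#' @param adam_beta1,adam_beta2 Adam moment decay factors.
#' @param minibatch Minibatch size (capped at the sample count).
#' @param max_epochs Training epochs.
#' @param augment_mix Use two-oil mixture augmentation (fresh mixtures are
#'   drawn at every training step).
#' @param augment_frac Fraction of each minibatch that is augmented
#'   mixtures rather than originals.
#' @param augment_noise_frac Amplitude of the multiplicative uniform noise
#'   applied to augmented spectra (0.10 = "10 percent uniform noise").
#' @param n_outputs Convenience override of the output-layer width (the
#'   descriptor count), keeping the rest of the preset architecture.
#' @param seed Integer seed controlling initialization, batching, dropout
#'   and augmentation.
#' @return A list of class `predictor_config`.
#' @export
predictor_config <- function(preset = c("reduced", "full"),
                             layer_sizes = NULL, dropout = NULL,
                             leaky_slope = 0.01, l1_coeff = NULL,
                             layer_l2 = 1e-4, lr = NULL,
                             lr_drop_factor = 0.995, adam_beta1 = 0.9,
                             adam_beta2 = 0.999, minibatch = 150,
                             max_epochs = NULL, augment_mix = TRUE,
                             augment_frac = 0.5, augment_noise_frac = 0.10,
                             n_outputs = NULL, seed = 1) {
  preset <- match.arg(preset)
  if (preset == "full") {
    if (is.null(layer_sizes)) layer_sizes <- c(201L, 4754L, 3565L, 2377L, 423L, 39L)
    if (is.null(dropout)) {
      dropout <- rep(NA_real_, length(layer_sizes) - 1L)
      dropout[match(c(2377L, 423L), layer_sizes) - 1L] <- c(0.9, 0.75)
    }
    if (is.null(l1_coeff)) l1_coeff <- 0.005
    if (is.null(lr)) lr <- 0.001
    if (is.null(max_epochs)) max_epochs <- 1000L
  } else {
    if (is.null(layer_sizes)) layer_sizes <- c(201L, 256L, 128L, 39L)
    if (is.null(dropout)) {
      dropout <- rep(NA_real_, length(layer_sizes) - 1L)
      dropout[length(layer_sizes) - 2L] <- 0.1
    }
    if (is.null(l1_coeff)) l1_coeff <- 1e-4
    if (is.null(lr)) lr <- 0.003
    if (is.null(max_epochs)) max_epochs <- 300L
  }
  if (!is.null(n_outputs)) layer_sizes[length(layer_sizes)] <- n_outputs
  if (length(dropout) != length(layer_sizes) - 1L)
    stop("dropout must give one rate per weight layer")
  if (any(stats::na.omit(dropout) < 0) || any(stats::na.omit(dropout) >= 1))
    stop("dropout rates must lie in [0, 1)")
  structure(list(preset = preset, layer_sizes = as.integer(layer_sizes),
                 dropout = dropout, leaky_slope = leaky_slope,
                 l1_coeff = l1_coeff, layer_l2 = layer_l2, lr = lr,
                 lr_drop_factor = lr_drop_factor, adam_beta1 = adam_beta1,
                 adam_beta2 = adam_beta2, minibatch = as.integer(minibatch),
                 max_epochs = as.integer(max_epochs),
                 augment_mix = isTRUE(augment_mix), augment_frac = augment_frac,
                 augment_noise_frac = augment_noise_frac,
                 seed = as.integer(seed)),
            class = "predictor_config")
}

#' Mixture-and-noise data augmentation for spectra and descriptors
#'
#' Draws `n` synthetic samples: for each, two oils `a`, `b` and a ratio
#' `r ~ U(0,1)` are drawn, the spectra are mixed linearly
#' (`r * MS_a + (1 - r) * MS_b`), perturbed by multiplicative uniform noise
#' of amplitude `noise_frac`, clipped at zero and max-normalized; the
#' targets are mixed with the same ratio (`r * OD_a + (1 - r) * OD_b`),
#' giving real-valued targets in `[0, 1]`. Mixing both views with a shared
#' ratio encodes the approximate linear superposition of mass spectra and
#' odor profiles under blending.
#'
#' Uses the current RNG stream. `pairs`/`ratios` may be supplied to make
#' the draw deterministic (mainly for tests).
#'
#' @param spectra `n_oils x 201` matrix of max-normalized spectra.
#' @param targets `n_oils x k` matrix of 0/1 labels (or real targets).
#' @param n Number of augmented samples.
#' @param noise_frac Noise amplitude; 0 disables noise.
#' @param pairs Optional `n x 2` matrix of oil indices.
#' @param ratios Optional numeric vector of mixing ratios in `[0, 1]`.
#' @return List with `spectra` (`n x 201`, max-normalized) and `targets`
#'   (`n x k`).
#' @export
augment_batch <- function(spectra, targets, n, noise_frac = 0.10,
                          pairs = NULL, ratios = NULL) {
  stopifnot(nrow(spectra) >= 1, nrow(spectra) == nrow(targets), n >= 1)
  if (is.null(pairs))
    pairs <- cbind(sample.int(nrow(spectra), n, replace = TRUE),
                   sample.int(nrow(spectra), n, replace = TRUE))
  if (is.null(ratios)) ratios <- stats::runif(n)
  Xs <- ratios * spectra[pairs[, 1], , drop = FALSE] +
    (1 - ratios) * spectra[pairs[, 2], , drop = FALSE]
  if (noise_frac > 0) {
    noise <- matrix(stats::runif(length(Xs), -noise_frac, noise_frac),
                    nrow = n)
    Xs <- pmax(Xs * (1 + noise), 0)
  }
  Xs <- max_normalize(Xs)
  Ys <- ratios * targets[pairs[, 1], , drop = FALSE] +
    (1 - ratios) * targets[pairs[, 2], , drop = FALSE]
  list(spectra = Xs, targets = Ys)
}

#' Train the odor-descriptor predictor
#'
#' @param lib Spectrum library matrix (rows are max-normalized internally).
#' @param descriptors 0/1 descriptor matrix with one row per oil.
#' @param config A [predictor_config()].
#' @return Object of class `odor_predictor`: network weights, the config,
#'   the descriptor vocabulary and the per-epoch training-loss trace.
#' @export
train_predictor <- function(lib, descriptors, config = predictor_config()) {
  stopifnot(inherits(config, "predictor_config"))
  if (nrow(lib) != nrow(descriptors))
    stop("library has ", nrow(lib), " oils but descriptor matrix has ",
         nrow(descriptors))
  if (ncol(lib) != config$layer_sizes[1])
    stop("input width ", ncol(lib), " does not match layer_sizes[1] = ",
         config$layer_sizes[1])
  if (ncol(descriptors) != config$layer_sizes[length(config$layer_sizes)])
    stop("descriptor count ", ncol(descriptors),
         " does not match the output layer width ",
         config$layer_sizes[length(config$layer_sizes)])
  X <- max_normalize(unname(lib))
  Y <- unname(descriptors)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  net <- mlp_init(config$layer_sizes, config$seed)
  fit <- if (config$max_epochs > 0) mlp_train(net, X, Y, config)
         else list(net = net, loss_trace = numeric(0))
  structure(list(config = config, W = fit$net$W, b = fit$net$b,
                 vocabulary = colnames(descriptors),
                 loss_trace = fit$loss_trace),
            class = "odor_predictor")
}

#' @export
print.odor_predictor <- function(x, ...) {
  cat("Odor-descriptor predictor:",
      paste(x$config$layer_sizes, collapse = "-"),
      sprintf("(preset '%s')\n", x$config$preset))
  if (length(x$loss_trace))
    cat("  final training loss:", format(utils::tail(x$loss_trace, 1)), "\n")
  invisible(x)
}

#' Predict descriptor scores from a max-normalized spectrum
#'
#' Deterministic forward pass with dropout disabled. The caller must
#' max-normalize the input ([max_normalize()]): an unnormalized spectrum is
#' an error, not silently rescaled, because the search gradients assume the
#' normalization happened outside the network.
#'
#' @param object An `odor_predictor`.
#' @param spectrum Numeric vector (length 201) or matrix of row spectra,
#'   each with maximum exactly 1.
#' @param ... Unused.
#' @return Named numeric vector (or matrix) of real-valued descriptor
#'   scores; values can leave `[0, 1]` because the output activation is a
#'   leaky ReLU.
#' @export
predict.odor_predictor <- function(object, spectrum, ...) {
  X <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, nrow = 1)
  if (ncol(X) != object$config$layer_sizes[1])
    stop("spectrum length ", ncol(X), " does not match the network input (",
         object$config$layer_sizes[1], ")")
  mx <- apply(X, 1, max)
  if (any(abs(mx - 1) > 1e-8))
    stop("input spectrum is not max-normalized (row maximum ",
         format(mx[which.max(abs(mx - 1))]), "); call max_normalize() first")
  out <- mlp_forward(list(W = object$W, b = object$b), X,
                     object$config$leaky_slope)
  colnames(out) <- object$vocabulary
  if (is.matrix(spectrum)) out else drop(out)
}

#' Balanced accuracy of binary descriptor predictions
#'
#' For each descriptor, balanced accuracy is the mean of sensitivity
#' (`TP / (TP + FN)`) and specificity (`TN / (TN + FP)`), which is robust
#' to the strong class imbalance of descriptor vocabularies. Descriptors
#' with no positive (or no negative) oils report only the defined half and
#' are flagged. Two "All" summaries are reported: `pooled` treats every
#' (oil, descriptor) cell as one observation; `macro` averages the defined
#' per-descriptor balanced accuracies.
#'
#' @param truth 0/1 matrix of true labels.
#' @param pred 0/1 matrix of predicted labels, same shape.
#' @return Object of class `od_eval`: list with `per_descriptor`
#'   (data frame of counts, sensitivity, specificity, balanced accuracy,
#'   and a `one_sided` flag), `pooled`, and `macro`.
#' @export
balanced_accuracy <- function(truth, pred) {
  if (!all(dim(truth) == dim(pred)))
    stop("truth and prediction matrices differ in shape")
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1)))
    stop("balanced accuracy needs binary matrices; binarize() predictions first")
  per <- lapply(seq_len(ncol(truth)), function(j) {
    t_ <- truth[, j]; p_ <- pred[, j]
    tp <- sum(t_ == 1 & p_ == 1); fn <- sum(t_ == 1 & p_ == 0)
    tn <- sum(t_ == 0 & p_ == 0); fp <- sum(t_ == 0 & p_ == 1)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    ba <- mean(c(sens, spec), na.rm = TRUE)
    data.frame(descriptor = colnames(truth)[j] %||% paste0("d", j),
               tp = tp, fn = fn, tn = tn, fp = fp,
               sensitivity = sens, specificity = spec,
               balanced_accuracy = ba,
               one_sided = is.na(sens) || is.na(spec))
  })
  per <- do.call(rbind, per)
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  pooled <- mean(c(if (tp + fn > 0) tp / (tp + fn),
                   if (tn + fp > 0) tn / (tn + fp)))
  structure(list(per_descriptor = per, pooled = pooled,
                 macro = mean(per$balanced_accuracy[!per$one_sided])),
            class = "od_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.od_eval <- function(x, ...) {
  cat("Descriptor evaluation over", nrow(x$per_descriptor), "descriptors\n")
  cat("  pooled balanced accuracy:", round(x$pooled, 3),
      "| macro:", round(x$macro, 3), "\n")
  flagged <- sum(x$per_descriptor$one_sided)
  if (flagged) cat(" ", flagged, "descriptor(s) one-sided (no positives or",
                   "no negatives)\n")
  invisible(x)
}

#' Leave-one-out evaluation of the predictor
#'
#' Trains one predictor per oil with that oil held out, predicts the
#' held-out spectrum, binarizes at `threshold` and scores all held-out
#' predictions jointly with [balanced_accuracy()].
#'
#' @param lib Spectrum library matrix.
#' @param descriptors 0/1 descriptor matrix.
#' @param config A [predictor_config()]; each fold trains with
#'   `seed = config$seed + fold`.
#' @param threshold Binarization threshold for predictions.
#' @param progress Print a dot per fold.
#' @return An `od_eval` (see [balanced_accuracy()]) with the raw held-out
#'   prediction matrix attached as `$predictions`.
#' @export
leave_one_out <- function(lib, descriptors, config = predictor_config(),
                          threshold = 0.5, progress = FALSE) {
  n <- nrow(lib)
  if (n < 2) stop("leave-one-out needs at least 2 oils")
  preds <- matrix(NA_real_, n, ncol(descriptors),
                  dimnames = dimnames(descriptors))
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    fit <- train_predictor(lib[-i, , drop = FALSE],
                           descriptors[-i, , drop = FALSE], cfg_i)
    preds[i, ] <- predict(fit, max_normalize(lib[i, ]))
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  out <- balanced_accuracy(descriptors, binarize(preds, threshold))
  out$predictions <- preds
  out
}
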
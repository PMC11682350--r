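#' Configuration for the synthetic library generator
#'
#' The generator emulates the statistical structure the whole pipeline
#' assumes: spectra are sparse non-negative combinations of a small latent
#' basis (so they superpose linearly under mixing), and each binary odor
#' descriptor is a thresholded linear functional of the latent loadings
#' (so descriptors follow approximate superposition too). Defaults mirror
#' the study conditions the method targets: 94 oils, 39 descriptors, 201
#' m/z bins, 20 downstream components; the latent rank, sparsities and
#' noise levels are the generator's own choices (see the methods vignette).
#'
#' @param n_oils Number of oils in the library.
#' @param n_latent True latent rank of the noiseless spectrum matrix.
#' @param n_components K used downstream by the NMF stage (bookkeeping only).
#' @param n_descriptors Number of binary descriptors.
#' @param spectral_sparsity Fraction of the 201 bins that are non-zero in
#'   each latent basis spectrum.
#' @param loading_sparsity Fraction of latent components active per oil.
#' @param noise_level Amplitude of multiplicative uniform noise applied to
#'   spectra: each bin is scaled by `1 + U(-noise_level, noise_level)`.
#' @param descriptor_noise Probability of flipping each binary label.
#' @param prevalence_range Range of target descriptor prevalences; each
#'   descriptor's threshold is set so its marginal frequency falls in this
#'   band, mimicking the strong imbalance of real descriptor vocabularies.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_oils = 94, n_latent = 10, n_components = 20,
                             n_descriptors = 39, spectral_sparsity = 0.10,
                             loading_sparsity = 0.35, noise_level = 0.05,
                             descriptor_noise = 0.05,
                             prevalence_range = c(0.05, 0.6), seed = 1) {
  cfg <- list(n_oils = as.integer(n_oils), n_latent = as.integer(n_latent),
              n_components = as.integer(n_components),
              n_descriptors = as.integer(n_descriptors),
              spectral_sparsity = spectral_sparsity,
              loading_sparsity = loading_sparsity,
              noise_level = noise_level, descriptor_noise = descriptor_noise,
              prevalence_range = prevalence_range, seed = as.integer(seed))
  stopifnot(cfg$n_oils >= 1, cfg$n_latent >= 1, cfg$n_descriptors >= 1,
            spectral_sparsity >= 0, spectral_sparsity <= 1,
            loading_sparsity >= 0, loading_sparsity <= 1,
            noise_level >= 0, descriptor_noise >= 0, descriptor_noise <= 1)
  if (cfg$n_latent > cfg$n_oils)
    stop("n_latent > n_oils gives an unidentifiable fixture")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic spectrum library with known ground truth
#'
#' Latent basis spectra are sparse non-negative rows (peak positions uniform
#' on the m/z grid, heights Exp(1)); oil loadings are sparse non-negative;
#' spectra are `loadings %*% basis`, perturbed by multiplicative uniform
#' noise and clipped at zero. Each descriptor is 1 when a fixed random
#' linear functional of the oil's latent loadings exceeds a per-descriptor
#' threshold (chosen so prevalences span `prevalence_range`), then flipped
#' with probability `descriptor_noise`. The ground truth (basis, loadings,
#' descriptor weights and thresholds) is returned for recovery tests.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `library` (spectrum matrix), `vocabulary`,
#'   `descriptors` (0/1 matrix) and `truth` (list: `basis`, `loadings`,
#'   `weights`, `thresholds`).
#' @export
generate_library <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)

  n_peaks <- max(2L, round(cfg$spectral_sparsity * N_MZ))
  basis <- matrix(0, cfg$n_latent, N_MZ)
  for (k in seq_len(cfg$n_latent)) {
    pos <- sample.int(N_MZ, n_peaks)
    basis[k, pos] <- stats::rexp(n_peaks)
  }

  n_active <- max(1L, round(cfg$loading_sparsity * cfg$n_latent))
  loadings <- matrix(0, cfg$n_oils, cfg$n_latent)
  for (i in seq_len(cfg$n_oils)) {
    act <- sample.int(cfg$n_latent, n_active)
    loadings[i, act] <- stats::runif(n_active, 0.2, 1)
  }
  # guarantee every latent component is expressed somewhere
  for (k in seq_len(cfg$n_latent))
    if (all(loadings[, k] == 0)) loadings[sample.int(cfg$n_oils, 1), k] <-
        stats::runif(1, 0.2, 1)

  spectra <- loadings %*% basis
  if (cfg$noise_level > 0) {
    noise <- matrix(stats::runif(length(spectra), -cfg$noise_level,
                                 cfg$noise_level), nrow = cfg$n_oils)
    spectra <- pmax(spectra * (1 + noise), 0)
  }
  lib <- spectrum_library(spectra, names = sprintf("oil_%03d", seq_len(cfg$n_oils)))

  weights <- matrix(stats::rnorm(cfg$n_descriptors * cfg$n_latent),
                    cfg$n_descriptors, cfg$n_latent)
  scores <- loadings %*% t(weights)              # n_oils x n_descriptors
  prev <- stats::runif(cfg$n_descriptors, cfg$prevalence_range[1],
                       cfg$prevalence_range[2])
  thresholds <- vapply(seq_len(cfg$n_descriptors), function(d)
    stats::quantile(scores[, d], 1 - prev[d], names = FALSE, type = 7),
    numeric(1))
  desc <- 1 * t(t(scores) > thresholds)
  if (cfg$descriptor_noise > 0) {
    flip <- matrix(stats::runif(length(desc)) < cfg$descriptor_noise,
                   nrow = cfg$n_oils)
    desc[flip] <- 1 - desc[flip]
  }
  vocab <- sprintf("descriptor_%02d", seq_len(cfg$n_descriptors))
  dimnames(desc) <- list(rownames(lib), vocab)
  desc <- suppressWarnings(descriptor_matrix(desc))

  list(library = lib, vocabulary = vocab, descriptors = desc,
       truth = list(basis = basis, loadings = loadings, weights = weights,
                    thresholds = thresholds))
}

#' Query the ground-truth descriptor functional of a latent loading vector
#'
#' Used in tests to confirm that linear mixing of two oils' loadings moves
#' descriptor scores linearly (the superposition the augmentation assumes).
#'
#' @param truth The `truth` element returned by [generate_library()].
#' @param loading Latent loading vector.
#' @return Real-valued descriptor scores (before thresholding).
#' @export
truth_descriptor_scores <- function(truth, loading) {
  as.vector(truth$weights %*% loading)
}

#' Simulate forced-choice sensory counts
#'
#' Draws the number of correct responses in `n_panelists * n_trials`
#' independent trials each answered correctly with probability `p_correct`.
#'
#' @param n_panelists Number of panelists.
#' @param n_trials Trials per panelist.
#' @param p_correct Per-trial probability of a correct answer.
#' @param seed Integer seed.
#' @return List with `correct` and `incorrect` counts.
#' @export
generate_sensory_counts <- function(n_panelists = 26, n_trials = 8,
                                    p_correct = 0.5, seed = 1) {
  stopifnot(p_correct >= 0, p_correct <= 1, n_panelists >= 1, n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- n_panelists * n_trials
  c_ok <- stats::rbinom(1, n, p_correct)
  list(correct = c_ok, incorrect = n - c_ok)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
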
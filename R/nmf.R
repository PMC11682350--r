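#' Generalized Kullback-Leibler divergence between two non-negative matrices
#'
#' `D(V || B) = sum(V * log(V/B) - V + B)` with the convention
#' `0 * log(0) = 0`. This is the loss the odor-component factorization
#' minimizes.
#'
#' @param V,B Non-negative matrices of equal shape (`B` strictly positive
#'   wherever `V > 0`).
#' @return Scalar divergence (non-negative up to floating-point error).
#' @export
generalized_kl <- function(V, B) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / B[pos])) - sum(V) + sum(B)
}

#' Factor a spectrum library into K odor components
#'
#' Non-negative matrix factorization `lib ~ W %*% H` under the generalized
#' KL divergence, fitted by the classical multiplicative updates (which
#' make the loss non-increasing at every iteration). `W` (`n_oils x K`)
#' holds the oil make-up of each component; `H` (`K x 201`) holds the
#' component mass spectra. After convergence each row of `H` is rescaled to
#' maximum 1 with `W` rescaled inversely, which fixes the scale
#' indeterminacy without changing the reconstruction.
#'
#' @param lib Spectrum library matrix (non-negative, `n x 201`).
#' @param K Number of odor components (default 20, matching a 20-channel
#'   olfactory display).
#' @param max_iter Maximum number of multiplicative updates.
#' @param tol Relative loss-change convergence threshold.
#' @param seed Seed for the uniform initialization.
#' @return Object of class `odor_basis`: list with `W`, `H`, `K`,
#'   `fit_loss`, `loss_trace`, `n_iter`, `converged`, `seed`.
#' @export
fit_components <- function(lib, K = 20, max_iter = 500, tol = 1e-8, seed = 1) {
  validate_spectrum_library(lib)
  n <- nrow(lib)
  if (K > min(n, N_MZ))
    stop("K = ", K, " exceeds min(n_oils, ", N_MZ, ") = ", min(n, N_MZ))
  r <- qr(lib)$rank
  if (K > r)
    warning("K = ", K, " exceeds the numerical rank (", r,
            ") of the library; components will be redundant")
  eps <- 1e-12
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(stats::runif(n * K, 1e-6, 1), n, K)
  H <- matrix(stats::runif(K * N_MZ, 1e-6, 1), K, N_MZ)

  V <- unname(lib)
  trace <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H + eps
    H <- H * (crossprod(W, V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / rep(rowSums(H) + eps, each = n)
    loss <- generalized_kl(V, W %*% H + eps)
    trace[it] <- loss
    if (is.finite(prev) && abs(prev - loss) <= tol * max(abs(prev), 1)) {
      converged <- TRUE
      break
    }
    prev <- loss
  }
  # fix scale indeterminacy: H rows to max 1, W compensates
  s <- apply(H, 1, max)
  s[s <= 0] <- 1
  H <- H / s
  W <- W * rep(s, each = n)
  dimnames(W) <- list(rownames(lib), sprintf("component_%02d", seq_len(K)))
  dimnames(H) <- list(colnames(W), mz_labels())

  structure(list(W = W, H = H, K = as.integer(K), fit_loss = trace[it],
                 loss_trace = trace[seq_len(it)], n_iter = it,
                 converged = converged, seed = as.integer(seed)),
            class = "odor_basis")
}

#' @export
print.odor_basis <- function(x, ...) {
  cat("Odor component basis: K =", x$K, "components over", nrow(x$W), "oils\n")
  cat("  generalized KL at convergence:", format(x$fit_loss), "in", x$n_iter,
      "iterations", if (x$converged) "(converged)" else "(max_iter reached)",
      "\n")
  invisible(x)
}

#' Project a spectrum onto an odor-component basis
#'
#' Non-negative least squares: finds the non-negative component
#' coefficients whose mixture spectrum `c' H` is closest to `s` in the
#' Euclidean sense, and reports the root-mean-square residual over the 201
#' bins.
#'
#' @param s Spectrum vector (length 201, non-negative).
#' @param basis An `odor_basis`.
#' @return List with `recipe` (named non-negative coefficients) and `rmse`.
#' @export
project_nnls <- function(s, basis) {
  stopifnot(inherits(basis, "odor_basis"))
  s <- as.numeric(s)
  if (length(s) != ncol(basis$H))
    stop("spectrum length ", length(s), " does not match the basis grid (",
         ncol(basis$H), ")")
  fit <- pracma::lsqnonneg(t(unname(basis$H)), s)
  recipe <- as.numeric(fit$x)
  names(recipe) <- rownames(basis$H)
  resid <- s - as.vector(recipe %*% basis$H)
  list(recipe = recipe, rmse = sqrt(mean(resid^2)))
}

#' Reconstruction RMSE of a library under an odor-component basis
#'
#' Each library spectrum is max-normalized, projected onto the basis by
#' non-negative least squares, and the root-mean-square residual is taken
#' over all oils and all 201 bins. This is the summary used to judge how
#' completely a small component set spans a library.
#'
#' @param lib Spectrum library matrix.
#' @param basis An `odor_basis` on the same m/z grid.
#' @return Scalar RMSE.
#' @export
reconstruction_rmse <- function(lib, basis) {
  validate_spectrum_library(lib)
  msn <- max_normalize(lib)
  res2 <- vapply(seq_len(nrow(msn)), function(i) {
    p <- project_nnls(msn[i, ], basis)
    p$rmse^2
  }, numeric(1))
  sqrt(mean(res2))
}
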
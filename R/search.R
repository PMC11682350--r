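#' Forward pass from a raw recipe to predicted descriptors
#'
#' The chain the search differentiates: raw ratios `OC` are sum-normalized
#' to `OCn`; the mixture spectrum is `MS = OCn' H` (linear superposition of
#' the component spectra); `MS` is max-normalized to `MSn`, recording the
#' argmax bin `m` (ties broken to the lowest index); the predictor maps
#' `MSn` to descriptor scores; when a target is given, the loss is the mean
#' squared error over descriptors.
#'
#' The whole map is scale-invariant in the raw recipe: `forward(c * OC)`
#' equals `forward(OC)` for any `c > 0`.
#'
#' @param recipe Non-negative vector of K raw mixing ratios (not all zero).
#' @param basis An `odor_basis` with K components.
#' @param predictor An `odor_predictor` whose input width matches the grid.
#' @param target Optional descriptor target vector (binary or real).
#' @return List of class `search_state`: `recipe`, `recipe_norm`, `ms`,
#'   `ms_norm`, `max_index`, `predicted`, and (with a target) `loss` and
#'   `sae`.
#' @export
forward_recipe <- function(recipe, basis, predictor, target = NULL) {
  stopifnot(inherits(basis, "odor_basis"), inherits(predictor, "odor_predictor"))
  if (length(recipe) != basis$K)
    stop("recipe has ", length(recipe), " entries but the basis has K = ",
         basis$K)
  ocn <- sum_normalize(recipe)
  ms <- as.vector(ocn %*% basis$H)
  m <- which.max(ms)  # lowest index on ties
  msn <- ms / ms[m]
  msn[m] <- 1  # exact unit maximum for the predictor's contract
  od <- unname(predict(predictor, msn))
  st <- list(recipe = recipe, recipe_norm = ocn, ms = ms, ms_norm = msn,
             max_index = m, predicted = od)
  if (!is.null(target)) {
    if (length(target) != length(od))
      stop("target has ", length(target), " descriptors, predictor outputs ",
           length(od))
    st$loss <- mean((target - od)^2)
    st$sae <- sum(abs(target - od))
  }
  structure(st, class = "search_state")
}

#' Analytic gradient of the search loss with respect to the raw recipe
#'
#' Composes, by the chain rule, the derivative of the mean-squared-error
#' loss through the predictor and both normalizations:
#' the loss term `dL/dOD_p = -(2/n)(ODt_p - OD_p)`; the network
#' input-Jacobian via an exact backward pass; the max-normalization
#' Jacobian, whose row and column at the argmax bin `m` are identically
#' zero, with `1/MS_m` on the remaining diagonal and `-MS_q / MS_m^2` in
#' column `m`; the linear map `H`; and the sum-normalization Jacobian
#' `(I * S - OC 1') / S^2` with `S = sum(OC)`. The argmax `m` recorded in
#' the forward state is held fixed (the map is only piecewise smooth; the
#' frozen-argmax derivative is the one used consistently here).
#'
#' @param state A `search_state` from [forward_recipe()].
#' @param target Descriptor target vector.
#' @param basis,predictor As in [forward_recipe()].
#' @return Numeric vector of length K: `dL/dOC`.
#' @export
recipe_gradient <- function(state, target, basis, predictor) {
  stopifnot(inherits(state, "search_state"))
  od <- state$predicted
  n_od <- length(od)
  g_od <- (2 / n_od) * (od - target)           # = -(2/n)(target - od)
  g_msn <- mlp_input_vjp(list(W = predictor$W, b = predictor$b),
                         state$ms_norm, g_od, predictor$config$leaky_slope)
  ms <- state$ms
  m <- state$max_index
  if (sum(ms == ms[m]) > 1)
    warning("tie at the maximum m/z bin; argmax frozen at the lowest index (",
            m, ")")
  g_ms <- g_msn / ms[m]
  g_ms[m] <- -sum(g_msn[-m] * ms[-m]) / ms[m]^2
  g_ocn <- as.vector(basis$H %*% g_ms)
  S <- sum(state$recipe)
  (g_ocn - sum(g_ocn * state$recipe_norm)) / S
}

#' Search configuration for recipe design
#'
#' @param learning_rate Gradient-descent step size on the raw ratios.
#' @param max_iters Iteration cap.
#' @param loss_tol Declare convergence when the MSE loss drops below this.
#' @param init `"uniform"` (equal ratios over all K components, the
#'   canonical start) or a non-negative numeric vector of length K.
#' @param eps_reset Value a collapsed recipe entry is reset to if the
#'   non-negativity projection ever zeroes the whole recipe.
#' @param record_trace Keep the per-iteration loss trace.
#' @return A list of class `search_config`.
#' @export
search_config <- function(learning_rate = 0.1, max_iters = 5000,
                          loss_tol = 1e-4, init = "uniform",
                          eps_reset = 1e-8, record_trace = TRUE) {
  stopifnot(learning_rate >= 0, max_iters >= 1, loss_tol >= 0)
  structure(list(learning_rate = learning_rate,
                 max_iters = as.integer(max_iters), loss_tol = loss_tol,
                 init = init, eps_reset = eps_reset,
                 record_trace = isTRUE(record_trace)),
            class = "search_config")
}

#' Design a component recipe matching a target descriptor set
#'
#' Plain gradient descent on the raw component ratios: each iteration runs
#' the forward pass, evaluates the analytic gradient, takes a step
#' `OC <- OC - lr * dL/dOC`, and projects back onto the non-negative
#' orthant by clipping at zero. Iteration stops when the loss falls below
#' `loss_tol` or `max_iters` is reached. The landscape is non-convex, so
#' the search can settle in a local minimum; the loss against the target
#' and the sum of absolute errors (SAE) of the final prediction are
#' reported so such runs are visible.
#'
#' @param target Descriptor target vector (binary or real), one entry per
#'   descriptor in the predictor's vocabulary.
#' @param basis An `odor_basis`.
#' @param predictor An `odor_predictor`.
#' @param config A [search_config()].
#' @return Object of class `recipe_search`: `recipe` (raw), `recipe_norm`
#'   (sum-normalized), final `state`, `loss`, `sae`, `iterations`,
#'   `converged`, `loss_trace`.
#' @export
design_recipe <- function(target, basis, predictor, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  K <- basis$K
  oc <- if (identical(config$init, "uniform")) rep(1 / K, K) else {
    if (length(config$init) != K || any(config$init < 0))
      stop("custom init must be a non-negative vector of length K = ", K)
    config$init
  }
  trace <- if (config$record_trace) numeric(config$max_iters) else NULL
  converged <- FALSE
  it <- 0L
  st <- forward_recipe(oc, basis, predictor, target)
  while (it < config$max_iters) {
    it <- it + 1L
    if (config$record_trace) trace[it] <- st$loss
    if (st$loss < config$loss_tol) { converged <- TRUE; break }
    g <- recipe_gradient(st, target, basis, predictor)
    pre <- oc - config$learning_rate * g
    oc <- pmax(pre, 0)
    if (all(oc == 0)) {
      oc[which.max(pre)] <- config$eps_reset
      warning("recipe collapsed to zero after projection; entry ",
              which.max(pre), " reset to ", config$eps_reset)
    }
    st <- forward_recipe(oc, basis, predictor, target)
  }
  structure(list(recipe = oc, recipe_norm = sum_normalize(oc), state = st,
                 loss = st$loss, sae = st$sae, iterations = it,
                 converged = converged,
                 loss_trace = if (config$record_trace) trace[seq_len(it)]),
            class = "recipe_search")
}

#' @export
print.recipe_search <- function(x, ...) {
  cat("Recipe search:", x$iterations, "iterations,",
      if (x$converged) "converged" else "stopped at max_iters", "\n")
  cat("  final loss:", format(x$loss), "| SAE:", format(x$sae), "\n")
  top <- order(x$recipe_norm, decreasing = TRUE)[1:min(3, length(x$recipe_norm))]
  cat("  leading components:",
      paste(sprintf("%d (%.2f)", top, x$recipe_norm[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Self-consistency sweep over the basis components
#'
#' For each of the K components, the target is set to the predictor's own
#' descriptor scores for that component's max-normalized spectrum, and the
#' recipe search is run from the uniform start. A search that works should
#' rediscover descriptor sets it is by construction able to produce; the
#' per-component SAE exposes components the search only reaches up to a
#' local minimum.
#'
#' @param basis An `odor_basis`.
#' @param predictor An `odor_predictor`.
#' @param config A [search_config()].
#' @return List of class `self_consistency`: `results` (one
#'   `recipe_search` per component) and `summary` (data frame with per-
#'   component loss, SAE, convergence flag and the weight the recovered
#'   recipe puts on the targeted component).
#' @export
self_consistency_suite <- function(basis, predictor,
                                   config = search_config()) {
  res <- vector("list", basis$K)
  for (k in seq_len(basis$K)) {
    target <- unname(predict(predictor, max_normalize(basis$H[k, ])))
    res[[k]] <- design_recipe(target, basis, predictor, config)
  }
  summary <- data.frame(
    component = seq_len(basis$K),
    loss = vapply(res, function(r) r$loss, numeric(1)),
    sae = vapply(res, function(r) r$sae, numeric(1)),
    converged = vapply(res, function(r) r$converged, logical(1)),
    self_weight = vapply(seq_len(basis$K),
                         function(k) res[[k]]$recipe_norm[k], numeric(1)))
  structure(list(results = res, summary = summary),
            class = "self_consistency")
}

#' @export
print.self_consistency <- function(x, ...) {
  cat("Self-consistency over", nrow(x$summary), "components\n")
  cat("  SAE below 0.2:", sum(x$summary$sae < 0.2), "of", nrow(x$summary), "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Convert a component recipe into per-oil blending volumes
#'
#' Each odor component is physically a blend of the library oils in the
#' proportions of its `W` column. A recipe over components therefore maps
#' to oil volumes by `volume * W_norm %*% OC_norm`, where `W_norm` has
#' columns scaled to sum 1; the result conserves the requested total
#' volume.
#'
#' @param recipe Non-negative component ratios (length K).
#' @param basis An `odor_basis` carrying `W`.
#' @param volume Total liquid volume to dispense (any unit).
#' @return Named numeric vector of per-oil volumes summing to `volume`.
#' @export
recipe_to_blend <- function(recipe, basis, volume = 1) {
  stopifnot(inherits(basis, "odor_basis"), volume > 0)
  ocn <- sum_normalize(recipe)
  Wn <- sweep(basis$W, 2, colSums(basis$W), "/")
  v <- volume * as.vector(Wn %*% ocn)
  names(v) <- rownames(basis$W)
  v
}
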
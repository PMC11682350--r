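test_that("the forward chain reproduces basis spectra and is scale-invariant", {
  basis <- random_basis(K = 5, seed = 20)
  pred <- tiny_predictor(n_desc = 6, seed = 21)

  # one-hot recipe: mixture spectrum is the max-normalized component row
  st <- forward_recipe(c(0, 0, 1, 0, 0), basis, pred)
  expect_identical(st$ms_norm, unname(max_normalize(basis$H[3, ])))

  # uniform recipe over two components: normalized elementwise mean
  st2 <- forward_recipe(c(1, 1, 0, 0, 0), basis, pred)
  expect_equal(st2$ms, unname((basis$H[1, ] + basis$H[2, ]) / 2),
               tolerance = 1e-15)

  # degree-0 homogeneity: scaling the raw recipe changes nothing
  r <- c(0.2, 0.05, 1.3, 0, 0.4)
  a <- forward_recipe(r, basis, pred)
  b <- forward_recipe(2 * r, basis, pred)          # power of two: exact
  expect_identical(a$predicted, b$predicted)
  cc <- forward_recipe(3.7 * r, basis, pred)
  expect_equal(a$predicted, cc$predicted, tolerance = 1e-12)

  # loss vanishes when the target equals the prediction
  st3 <- forward_recipe(r, basis, pred, target = a$predicted)
  expect_equal(st3$loss, 0)
  expect_equal(st3$sae, 0)

  expect_error(forward_recipe(numeric(5), basis, pred), "all-zero")
  expect_error(forward_recipe(rep(1, 4), basis, pred), "K")
})

test_that("the analytic gradient matches central finite differences", {
  set.seed(40)
  for (trial in 1:15) {
    K <- sample(3:8, 1)
    n_desc <- sample(4:10, 1)
    basis <- random_basis(K = K, seed = 100 + trial)
    pred <- tiny_predictor(n_desc = n_desc, seed = 200 + trial)
    target <- rbinom(n_desc, 1, 0.4)
    recipe <- runif(K, 0.05, 1)
    st <- forward_recipe(recipe, basis, pred, target)
    g <- recipe_gradient(st, target, basis, pred)
    fd <- fd_recipe_gradient(recipe, basis, pred, target)
    expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-8)), 1e-4)
  }
})

test_that("gradient structure reflects the two normalizations", {
  basis <- random_basis(K = 6, seed = 33)
  pred <- tiny_predictor(n_desc = 5, seed = 34)
  target <- c(1, 0, 1, 0, 0)
  recipe <- runif(6, 0.1, 1)
  st <- forward_recipe(recipe, basis, pred, target)
  g <- recipe_gradient(st, target, basis, pred)

  # scale invariance: the directional derivative along the recipe is zero
  expect_lt(abs(sum(g * recipe)), 1e-12 * max(abs(g)))

  # at prediction == target the gradient vanishes identically
  g0 <- recipe_gradient(st, st$predicted, basis, pred)
  expect_equal(g0, numeric(6))

  # the max-normalization Jacobian annihilates the spectrum direction:
  # perturbing MS along itself leaves MSn unchanged
  eps <- 1e-7
  msn_shift <- (st$ms * (1 + eps)) / max(st$ms * (1 + eps))
  expect_equal(msn_shift, st$ms_norm, tolerance = 1e-12)
})

test_that("the search descends to self-generated targets", {
  basis <- random_basis(K = 4, seed = 50)
  pred <- tiny_predictor(n_desc = 6, seed = 51)
  known <- c(0.6, 0.1, 0.25, 0.05)
  target <- forward_recipe(known, basis, pred)$predicted

  res <- design_recipe(target, basis, pred,
                       search_config(learning_rate = 0.1, max_iters = 3000,
                                     loss_tol = 1e-10))
  expect_lt(res$loss, 1e-4)
  expect_lt(res$sae, 0.2)
  expect_true(all(res$recipe >= 0))
  expect_equal(sum(res$recipe_norm), 1, tolerance = 1e-12)

  # best-so-far loss over the tail of the trace is non-increasing
  tail_tr <- tail(res$loss_trace, 50)
  expect_true(all(diff(cummin(tail_tr)) <= 0))

  # zero learning rate leaves the recipe untouched
  frozen <- design_recipe(target, basis, pred,
                          search_config(learning_rate = 0, max_iters = 20,
                                        loss_tol = 0))
  expect_equal(frozen$recipe, rep(0.25, 4))
  expect_equal(diff(range(frozen$loss_trace)), 0)
})

test_that("self-consistency recovers near-one-hot recipes for separable bases", {
  # disjoint-support components: each is identifiable from its spectrum
  set.seed(1)
  H <- matrix(0, 3, 201)
  H[1, 1:40] <- runif(40, 0.2, 1)
  H[2, 81:120] <- runif(40, 0.2, 1)
  H[3, 161:200] <- runif(40, 0.2, 1)
  H <- H / apply(H, 1, max)
  basis <- random_basis(K = 3, seed = 60)
  basis$H <- H
  pred <- tiny_predictor(n_desc = 8, seed = 61)

  # the trajectory that parks in a local minimum can sit on an exact tie of
  # the maximum bin; the tie-break warning is expected there
  sc <- suppressWarnings(
    self_consistency_suite(basis, pred,
                           search_config(learning_rate = 0.2,
                                         max_iters = 3000,
                                         loss_tol = 1e-9)))
  expect_length(sc$results, 3)
  # gradient descent may park a minority of components in a local minimum;
  # the recovered ones must be recovered cleanly and near-one-hot
  ok <- sc$summary$loss < 1e-3
  expect_gte(sum(ok), 2)
  expect_true(all(sc$summary$self_weight[ok] > 0.8))
})

test_that("recipes map to oil volumes that conserve the total", {
  basis <- random_basis(K = 3, seed = 70, n_oils = 4)
  v <- recipe_to_blend(c(0, 1, 0), basis, volume = 10)
  expect_equal(unname(v), unname(10 * basis$W[, 2] / sum(basis$W[, 2])),
               tolerance = 1e-12)
  expect_equal(sum(v), 10, tolerance = 1e-9)

  # two-component equal mix on a hand-sized W
  b2 <- basis
  b2$W <- matrix(c(1, 3, 2, 2, 0, 4), 2, 3)
  rownames(b2$W) <- c("oilA", "oilB")
  v2 <- recipe_to_blend(c(1, 1, 0), b2, volume = 1)
  # 0.5 * (1/4, 3/4) + 0.5 * (1/2, 1/2) = (3/8, 5/8)
  expect_equal(unname(v2), c(3 / 8, 5 / 8), tolerance = 1e-12)
})
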
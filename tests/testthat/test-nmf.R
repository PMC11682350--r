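test_that("multiplicative updates never increase the KL loss", {
  sim <- generate_library(synthetic_config(n_oils = 25, n_latent = 5,
                                           n_descriptors = 6,
                                           noise_level = 0.05, seed = 4))
  for (K in c(3, 5, 10)) {
    fit <- fit_components(sim$library, K = K, max_iter = 300, tol = 0,
                          seed = K)
    d <- diff(fit$loss_trace)
    slack <- 1e-10 * pmax(abs(fit$loss_trace[-fit$n_iter]), 1)
    expect_true(all(d <= slack))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
    expect_equal(unname(apply(fit$H, 1, max)), rep(1, K))  # scale fixed
  }
})

test_that("a noiseless rank-8 library is recovered essentially exactly at K = 8", {
  sim <- generate_library(synthetic_config(n_oils = 60, n_latent = 8,
                                           n_descriptors = 6, noise_level = 0,
                                           descriptor_noise = 0, seed = 9))
  fit <- fit_components(sim$library, K = 8, max_iter = 5000, tol = 1e-13,
                        seed = 1)
  expect_lt(fit$fit_loss, 1e-6 * sum(sim$library))
  expect_lt(reconstruction_rmse(sim$library, fit), 1e-4)
  # nested models: a K = 1 fit cannot beat K = 8 on a rank-8 library
  fit1 <- fit_components(sim$library, K = 1, max_iter = 500, seed = 1)
  expect_gt(reconstruction_rmse(sim$library, fit1),
            reconstruction_rmse(sim$library, fit))
})

test_that("fitting is reproducible bit-for-bit for a fixed seed", {
  sim <- generate_library(synthetic_config(n_oils = 15, n_latent = 3,
                                           n_descriptors = 4, seed = 8))
  a <- fit_components(sim$library, K = 3, max_iter = 50, tol = 0, seed = 42)
  b <- fit_components(sim$library, K = 3, max_iter = 50, tol = 0, seed = 42)
  expect_identical(a$W, b$W)
  expect_identical(a$H, b$H)
})

test_that("NNLS projection recovers exact component mixtures", {
  basis <- random_basis(K = 4, seed = 6)
  p1 <- project_nnls(basis$H[2, ], basis)
  expect_equal(unname(p1$recipe), c(0, 1, 0, 0), tolerance = 1e-10)
  expect_lt(p1$rmse, 1e-10)

  s <- 0.3 * basis$H[1, ] + 0.7 * basis$H[2, ]
  p2 <- project_nnls(s, basis)
  expect_equal(unname(p2$recipe), c(0.3, 0.7, 0, 0), tolerance = 1e-8)
  expect_lt(p2$rmse, 1e-8)
})

test_that("NNLS residual matches an exhaustive active-set oracle", {
  basis <- random_basis(K = 3, seed = 11)
  A <- t(unname(basis$H))
  set.seed(12)
  for (i in 1:10) {
    s <- runif(201)
    p <- project_nnls(s, basis)
    oracle <- nnls_bruteforce(A, s)
    expect_equal(p$rmse, sqrt(oracle$rss / 201), tolerance = 1e-8)
  }
})

test_that("dimension and sign contracts are enforced", {
  sim <- generate_library(synthetic_config(n_oils = 10, n_latent = 3,
                                           n_descriptors = 4, noise_level = 0,
                                           seed = 2))
  expect_error(fit_components(sim$library, K = 11), "exceeds")
  expect_warning(fit_components(sim$library, K = 5, max_iter = 5, seed = 1),
                 "rank")
  basis <- random_basis(K = 3, seed = 1)
  expect_error(project_nnls(numeric(100), basis), "does not match")
})
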
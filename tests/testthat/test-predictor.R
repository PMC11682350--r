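test_that("mixture augmentation interpolates spectra and targets", {
  fx <- latent_activity_fixture(n_oils = 10, n_latent = 4, seed = 13)
  X <- max_normalize(fx$library)
  Y <- fx$descriptors

  # endpoint: ratio 1 returns oil a exactly (noise off)
  aug <- augment_batch(X, Y, 1, noise_frac = 0,
                       pairs = matrix(c(3, 7), 1), ratios = 1)
  expect_equal(unname(aug$spectra[1, ]), unname(X[3, ]))
  expect_equal(unname(aug$targets[1, ]), unname(Y[3, ]))

  # convexity at r = 0.5: shared-absent descriptors stay 0, descriptors
  # present in exactly one oil become 0.5
  aug2 <- augment_batch(X, Y, 1, noise_frac = 0,
                        pairs = matrix(c(1, 2), 1), ratios = 0.5)
  expect_true(all(aug2$targets %in% c(0, 0.5, 1)))
  both0 <- Y[1, ] == 0 & Y[2, ] == 0
  expect_true(all(aug2$targets[1, both0] == 0))
  onein1 <- xor(Y[1, ] == 1, Y[2, ] == 1)
  expect_true(all(aug2$targets[1, onein1] == 0.5))

  # law of large numbers: mean augmented target for a fixed pair
  set.seed(77)
  aug3 <- augment_batch(X, Y, 10000, noise_frac = 0,
                        pairs = matrix(rep(c(1, 2), each = 10000), ncol = 2))
  expect_equal(unname(colMeans(aug3$targets)),
               unname((Y[1, ] + Y[2, ]) / 2), tolerance = 0.02)

  # augmented spectra stay non-negative and max-normalized under noise
  set.seed(78)
  aug4 <- augment_batch(X, Y, 50, noise_frac = 0.1)
  expect_true(all(aug4$spectra >= 0))
  expect_equal(unname(apply(aug4$spectra, 1, max)), rep(1, 50))
  expect_true(all(aug4$targets >= 0 & aug4$targets <= 1))
})

test_that("training reduces the loss and is seed-reproducible", {
  fx <- latent_activity_fixture(n_oils = 20, n_latent = 4, seed = 14)
  cfg <- predictor_config(preset = "reduced", layer_sizes = c(201, 64, 32, 4),
                          max_epochs = 200, seed = 6)
  fit <- train_predictor(fx$library, fx$descriptors, cfg)
  expect_lt(tail(fit$loss_trace, 1), fit$loss_trace[1])

  fit2 <- train_predictor(fx$library, fx$descriptors, cfg)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$loss_trace, fit2$loss_trace)

  # zero-epoch training returns the random-init net with positive loss
  cfg0 <- predictor_config(preset = "reduced",
                           layer_sizes = c(201, 64, 32, 4),
                           max_epochs = 0, seed = 6)
  raw <- train_predictor(fx$library, fx$descriptors, cfg0)
  pred0 <- predict(raw, max_normalize(fx$library))
  expect_gt(mean((pred0 - fx$descriptors)^2), 0)
})

test_that("the forward pass matches a pencil-and-paper computation", {
  # hand-assembled 2-layer net on a 3-bin input, leaky slope 0.01
  cfg <- predictor_config(preset = "reduced", layer_sizes = c(3L, 2L, 2L),
                          dropout = rep(NA_real_, 2), max_epochs = 0, seed = 1)
  net <- list(W = list(matrix(c(1, 0, -1, 2, 1, 0), 3, 2),
                       matrix(c(1, -1, 0.5, 0.5), 2, 2)),
              b = list(c(0.1, -0.2), c(0, 0.3)))
  p <- structure(list(config = cfg, W = net$W, b = net$b,
                      vocabulary = c("A", "B"), loss_trace = numeric(0)),
                 class = "odor_predictor")
  x <- c(0.5, 1, 0.25)
  z1 <- c(0.5 - 0.25 + 0.1, 1 + 1 - 0.2)          # ( 0.35, 1.8 )
  a1 <- z1                                         # both positive
  z2 <- c(a1[1] - a1[2], 0.5 * a1[1] + 0.5 * a1[2] + 0.3)  # (-1.45, 1.375)
  expected <- c(0.01 * z2[1], z2[2])               # leaky output
  expect_equal(unname(predict(p, x)), expected, tolerance = 1e-12)

  # inference is deterministic and names follow the vocabulary
  expect_identical(predict(p, x), predict(p, x))
  expect_named(predict(p, x), c("A", "B"))
  expect_error(predict(p, c(2, 1, 0.5)), "max-normalized")
})

test_that("balanced accuracy matches direct confusion counts", {
  truth <- cbind(a = c(1, 0, 1, 0), b = c(1, 1, 0, 0))
  perfect <- balanced_accuracy(truth, truth)
  expect_equal(perfect$per_descriptor$balanced_accuracy, c(1, 1))
  expect_equal(perfect$pooled, 1)

  allpos <- balanced_accuracy(truth, truth * 0 + 1)
  expect_equal(allpos$per_descriptor$balanced_accuracy, c(0.5, 0.5))

  mixed <- balanced_accuracy(cbind(c(1, 0, 1, 0)), cbind(c(1, 0, 0, 0)))
  expect_equal(mixed$per_descriptor$balanced_accuracy, 0.75)
  expect_equal(mixed$per_descriptor$sensitivity, 0.5)
  expect_equal(mixed$per_descriptor$specificity, 1)

  onesided <- balanced_accuracy(cbind(c(1, 1, 1)), cbind(c(1, 1, 0)))
  expect_true(onesided$per_descriptor$one_sided)

  expect_error(balanced_accuracy(truth, truth[1:2, ]), "shape")
  expect_error(balanced_accuracy(truth, truth * 0.5), "binary")
})

test_that("leave-one-out beats a shuffled-label control on a learnable fixture", {
  fx <- latent_activity_fixture(n_oils = 12, n_latent = 4, seed = 15)
  cfg <- predictor_config(preset = "reduced", layer_sizes = c(201, 64, 32, 4),
                          max_epochs = 150, seed = 30)
  ev <- leave_one_out(fx$library, fx$descriptors, cfg)
  expect_equal(nrow(ev$predictions), nrow(fx$library))
  expect_true(all(!is.na(ev$predictions)))

  set.seed(31)
  shuffled <- fx$descriptors[sample(nrow(fx$descriptors)), ]
  rownames(shuffled) <- rownames(fx$descriptors)
  ev_null <- leave_one_out(fx$library, shuffled, cfg)
  expect_gt(ev$pooled, ev_null$pooled)  # permutation control
})
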
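test_that("ensemble members share structure but differ in activation and init", {
  cfg <- ensemble_config(n_members = 5, hidden_layers = c(16, 16), seed = 1)
  ens <- build_ensemble(cfg, 4, 2)
  acts <- vapply(ens$members, `[[`, "", "activation")
  expect_identical(acts, c("relu", "tanh", "gelu", "silu", "elu"))
  expect_true(all(vapply(ens$members,
                         function(m) identical(m$sizes, c(4, 16, 16, 2)),
                         logical(1))))
  z <- matrix(rnorm(4), 1)
  outs <- vapply(ens$members,
                 function(m) uncertmol:::mlp_forward(m, z)$out[1, 1],
                 numeric(1))
  expect_gt(length(unique(outs)), 1)
  expect_error(ensemble_config(n_members = 1), "n_members")
  expect_error(ensemble_config(q = 0), "q")
})

test_that("the mean prediction is the exact member average and permutation-invariant", {
  A1 <- matrix(c(1, 0), 1, 2); A2 <- matrix(c(3, 0), 1, 2)
  ens <- linear_ensemble(A1, 0, n_members = 2)
  ens$members[[2]]$layers[[1]]$W <- t(A2)
  z <- c(1, 5)
  pr <- predict(ens, z)
  expect_equal(unname(pr$mean[1, 1]), 2) # members predict 1 and 3
  expect_equal(dim(pr$per_member), c(1, 1, 2))
  # per-member outputs match running each member alone
  expect_equal(pr$per_member[1, 1, ],
               vapply(ens$members,
                      function(m) uncertmol:::mlp_forward(m, matrix(z, 1))$out[1, 1],
                      numeric(1)))
  ens2 <- ens; ens2$members <- rev(ens2$members)
  expect_equal(predict(ens2, z)$mean, pr$mean)
  expect_error(predict(ens, c(1, 2, 3)), "dimension")
})

test_that("epistemic uncertainty is the population variance of member predictions", {
  A1 <- matrix(c(1, 0), 1, 2); A2 <- matrix(c(3, 0), 1, 2)
  ens <- linear_ensemble(A1, 0, n_members = 2)
  ens$members[[2]]$layers[[1]]$W <- t(A2)
  u <- epistemic_uncertainty(ens, c(1, 0))
  # members predict {1, 3}: (1 + 9)/2 - 4 = 1
  expect_equal(u$per_property[1, 1], 1)
  expect_equal(u$total, 1)
  # identical members: exactly zero
  same <- linear_ensemble(A1, 0, n_members = 4)
  expect_identical(epistemic_uncertainty(same, c(2, -1))$total, 0)
})

test_that("the one-pass uncertainty matches an independent two-pass variance", {
  set.seed(21)
  for (rep in 1:50) {
    cfg <- ensemble_config(n_members = sample(2:6, 1), hidden_layers = 8L,
                           seed = rep)
    ens <- build_ensemble(cfg, 3, 2)
    z <- rnorm(3)
    pr <- predict(ens, z, natural = FALSE)
    for (p in 1:2) {
      vals <- pr$per_member[1, p, ]
      twopass <- mean((vals - mean(vals))^2)
      expect_equal(pr$uncertainty[1, p], twopass, tolerance = 1e-10)
      expect_gte(pr$uncertainty[1, p], 0)
    }
  }
})

test_that("stochastic gating realizes the configured update probability", {
  h <- fx_loop()
  counts <- h$ensemble$history$update_counts
  n_iter <- h$ensemble$history$n_iterations
  for (c in counts)
    expect_gt(stats::binom.test(c, n_iter, 0.3)$p.value, 1e-4)
  # q = 1 degenerates to every-iteration updates for every member
  hh <- closed_loop_harness(d = 3, n_train = 64, seed = 8)
  ens <- build_ensemble(ensemble_config(q = 1, epochs = 3, seed = 8), 3, 1)
  ens <- train_ensemble(ens, hh$dataset)
  expect_true(all(ens$history$update_counts == ens$history$n_iterations))
})

test_that("uncertainty is low at training clusters and high far away", {
  set.seed(31)
  d <- 4
  deltas <- replicate(3, {
    seed <- sample.int(1e6, 1)
    centers <- matrix(c(rep(2, d), rep(-2, d)), 2, d, byrow = TRUE)
    Z <- rbind(
      matrix(rnorm(150 * d, 0, 0.3), 150, d) +
        matrix(centers[1, ], 150, d, byrow = TRUE),
      matrix(rnorm(150 * d, 0, 0.3), 150, d) +
        matrix(centers[2, ], 150, d, byrow = TRUE)
    )
    A <- matrix(rnorm(d), 1, d)
    P <- analytic_oracle(Z, A, 0)
    prov <- data.frame(index = 1:300, selfies = NA, status = "ok", seed = seed)
    ds <- uncertmol:::new_latent_property_dataset(Z, P, prov, "p1", "")
    ens <- build_ensemble(ensemble_config(epochs = 60, seed = seed), d, 1)
    ens <- train_ensemble(ens, ds)
    near <- centers[sample(1:2, 100, TRUE), ] + matrix(rnorm(100 * d, 0, 0.3), 100, d)
    # probes at >= 5 cluster-sd from both centers, orthogonal-ish direction
    far <- matrix(rnorm(100 * d), 100, d)
    far <- far / sqrt(rowSums(far^2)) * 8
    mean(epistemic_uncertainty(ens, far)$total) -
      mean(epistemic_uncertainty(ens, near)$total)
  })
  expect_true(all(deltas > 0))
})

test_that("larger ensembles stabilize the mean prediction across training seeds", {
  h <- closed_loop_harness(d = 4, n_train = 300, seed = 77)
  z0 <- rep(0.5, 4)
  spread <- sapply(c(2, 10), function(m) {
    preds <- sapply(1:6, function(s) {
      ens <- build_ensemble(ensemble_config(n_members = m, epochs = 40,
                                            seed = s), 4, 1)
      ens <- train_ensemble(ens, h$dataset)
      predict(ens, z0)$mean[1, 1]
    })
    var(preds)
  })
  expect_lt(spread[2], spread[1])
})

test_that("ensemble checkpoints round-trip", {
  h <- fx_loop()
  path <- tempfile(fileext = ".json")
  save_model(h$ensemble, path)
  back <- load_model(path)
  z <- matrix(rnorm(6), 1)
  expect_equal(predict(back, z), predict(h$ensemble, z), tolerance = 1e-12)
  expect_length(back$members, length(h$ensemble$members))
})
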
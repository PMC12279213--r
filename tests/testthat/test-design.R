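test_that("target grids are evenly spaced and validated", {
  expect_equal(target_grid(0, 4, 5), c(0, 1, 2, 3, 4))
  expect_equal(length(target_grid(-10, 0, 2000)), 2000)
  expect_error(target_grid(2, 1, 5), "low must be")
  expect_error(target_grid(1, 2, 1))
  r <- qm_target_ranges("single")
  expect_equal(r$homo, c(-10, 0))
  expect_equal(r$lumo, c(-4, 2))
  expect_equal(r$dipole, c(0, 4))
  rm <- qm_target_ranges("multi")
  expect_equal(rm$homo, c(-8, -3))
  expect_equal(rm$lumo, c(-3, 2))
})

test_that("zero steps returns the seeded initialization", {
  h <- fx_loop()
  req <- design_request(c(p1 = 0.3), k = 1, steps = 0, seed = 4)
  res <- optimize_latent(req, h$ensemble)
  z0 <- uncertmol:::with_seed(4, matrix(rnorm(6), 1, 6))
  expect_equal(unname(res$latent), as.numeric(z0))
})

test_that("with a perfect linear surrogate and no uncertainty term the optimizer matches least squares", {
  set.seed(14)
  A <- matrix(rnorm(5), 1, 5); A <- A / sqrt(sum(A^2))
  ens <- linear_ensemble(A, 0, n_members = 3)
  for (target in c(-0.8, 0.2, 1.1)) {
    req <- design_request(c(p1 = target), k = 1, steps = 400,
                          learning_rate = 0.05, uncertainty_weight = 0,
                          seed = 21)
    res <- optimize_latent(req, ens)
    # least squares certifies the target is achievable exactly
    expect_lt(abs(sum(A * res$latent) - target), 1e-3)
    expect_lt(res$surrogate_error_total, 1e-3)
  }
})

test_that("best-iterate objective is non-increasing in the step budget", {
  h <- fx_loop()
  objs <- sapply(c(5, 25, 100, 250), function(s) {
    req <- design_request(c(p1 = 0.5), k = 1, steps = s, seed = 11)
    min(optimize_latent(req, h$ensemble)$objective_trace)
  })
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("k tries reduce to one try and retain the minimum-error candidate", {
  h <- fx_loop()
  req1 <- design_request(c(p1 = 0.4), k = 1, steps = 60, seed = 31)
  single <- optimize_latent(req1, h$ensemble)
  viak <- design_molecule(req1, h$ensemble)
  expect_equal(viak$latent, single$latent)

  reqk <- design_request(c(p1 = 0.4), k = 5, steps = 60, seed = 31)
  best <- design_molecule(reqk, h$ensemble, oracle = h$harness$oracle)
  errs <- vapply(best$candidates, function(r) sum(r$oracle_error), numeric(1))
  expect_equal(sum(best$oracle_error), min(errs))
  expect_identical(best$selection, "oracle_error")
  # without an oracle, surrogate error decides
  best2 <- design_molecule(reqk, h$ensemble)
  errs2 <- vapply(best2$candidates, function(r) r$surrogate_error_total,
                  numeric(1))
  expect_equal(best2$surrogate_error_total, min(errs2))
})

test_that("a large uncertainty weight keeps designs near the training latents", {
  h <- fx_loop()
  # a target beyond the training box pulls the unconstrained optimizer out
  tg <- h$harness$b + 1.3 * h$harness$S
  nn_dist <- function(lambda, seed) {
    req <- design_request(c(p1 = tg), k = 1, steps = 150,
                          uncertainty_weight = lambda, seed = seed)
    z <- optimize_latent(req, h$ensemble)$latent
    sqrt(min(colSums((t(h$harness$dataset$latents) - z)^2)))
  }
  d0 <- sapply(1:3, function(s) nn_dist(0, s))
  d5 <- sapply(1:3, function(s) nn_dist(5, s))
  expect_lt(mean(d5), mean(d0))
})

test_that("the design CSV records targets, errors and identities", {
  vae <- fx_vae()
  Z <- sample_prior_latents(60, 8, seed = 41)
  ds <- reacquire(Z, vae, "descriptors", check_geometry = FALSE, seed = 41)
  ens <- build_ensemble(ensemble_config(epochs = 30, seed = 42), 8, 3)
  ens <- train_ensemble(ens, ds)
  req <- design_request(c(mw = 60), k = 2, steps = 50, seed = 43)
  res <- design_molecule(req, ens, vae,
                         oracle = function(s)
                           descriptor_oracle(s, check_geometry = FALSE))
  expect_false(is.na(res$selfies))
  path <- tempfile(fileext = ".csv")
  tab <- write_design_csv(list(res), path)
  back <- read_design_csv(path)
  expect_equal(back$target_mw, 60)
  expect_equal(back$surrogate_error_mw, unname(res$surrogate_error["mw"]))
  expect_identical(back$canonical_id, canonical_id(res$selfies))
})

test_that("the mass penalty is monotone in size and inert at weight zero", {
  vae <- fx_vae()
  methane_z <- matrix(0, 1, 8)
  expect_lt(selfies_mass("[C]"), selfies_mass(strrep("[C]", 10)))
  p_small <- mass_penalty(methane_z, vae) # whatever it decodes to
  expect_true(is.finite(p_small))

  h <- fx_loop()
  req0 <- design_request(c(p1 = 0.2), k = 1, steps = 40, seed = 51,
                         extra_penalties = list(none = function(z, d)
                           list(value = 0, grad = NULL)))
  reqn <- design_request(c(p1 = 0.2), k = 1, steps = 40, seed = 51)
  r0 <- optimize_latent(req0, h$ensemble)
  rn <- optimize_latent(reqn, h$ensemble)
  expect_equal(r0$latent, rn$latent)
})

test_that("batched grid design matches the protocol and improves with tries", {
  h <- fx_loop()
  g1 <- design_grid(h$harness$targets_in$p1[1:5], "p1", h$ensemble,
                    oracle = h$harness$oracle, k = 1, lambda = 1,
                    steps = 120, seed = 61)
  g5 <- design_grid(h$harness$targets_in$p1[1:5], "p1", h$ensemble,
                    oracle = h$harness$oracle, k = 5, lambda = 1,
                    steps = 120, seed = 61)
  expect_lte(mean(g5$oracle_error), mean(g1$oracle_error))
  expect_equal(nrow(g1), 5L)
  expect_true(all(is.finite(g1$uncertainty)))
})
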
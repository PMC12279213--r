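test_that("prior latent samples are reproducible standard normals", {
  z1 <- sample_prior_latents(1, 4, seed = 42)
  expect_identical(z1, sample_prior_latents(1, 4, seed = 42))
  Z <- sample_prior_latents(1e5, 2, seed = 1)
  expect_true(all(abs(colMeans(Z)) < 3 / sqrt(1e5)))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 0.02))
})

test_that("identity-decoder reacquisition stores exactly (z, A z + b)", {
  A <- matrix(rnorm(8), 2, 4); b <- c(1, -1)
  Z <- sample_prior_latents(50, 4, seed = 2)
  ds <- reacquire(Z, "identity", make_analytic_oracle(A, b), seed = 2)
  expect_equal(nrow(ds$latents), 50L)
  expect_equal(unname(ds$properties),
               unname(analytic_oracle(Z, A, b)), tolerance = 1e-14)
  expect_equal(attr(ds, "n_unstable"), 0L)
  # stored pairs are recomputable from their latents (consistency)
  for (i in c(1, 25, 50)) {
    again <- make_analytic_oracle(A, b)(ds$latents[i, ])
    expect_identical(as.numeric(again$properties), unname(ds$properties[i, ]))
  }
})

test_that("unstable oracle outcomes are excluded and counted", {
  # deterministic ~10% failure rate keyed on the latent itself
  flaky <- function(z) {
    u <- uncertmol:::with_seed(
      as.integer(abs(sum(z) * 1e6)) %% 1000000L, stats::runif(1))
    if (u < 0.1) oracle_result("unstable", reason = "mock")
    else oracle_result("ok", property_vector(c(p = sum(z)), units = ""))
  }
  N <- 400
  Z <- sample_prior_latents(N, 3, seed = 5)
  ds <- reacquire(Z, "identity", flaky, seed = 5)
  n_fail <- attr(ds, "n_unstable")
  expect_equal(nrow(ds$latents), N - n_fail)
  # dataset size is binomial(N, 0.9): two-sided test at alpha = 0.01
  expect_gt(stats::binom.test(N - n_fail, N, 0.9)$p.value, 0.01)
  expect_gt(n_fail, 0)
})

test_that("reacquisition through the VAE decoder labels what latents decode to", {
  vae <- fx_vae()
  Z <- sample_prior_latents(30, 8, seed = 6)
  ds <- reacquire(Z, vae, "descriptors", check_geometry = FALSE, seed = 6)
  expect_lte(nrow(ds$latents), 30L)
  # provenance records the decoded string, and relabelling reproduces the
  # stored property
  i <- 1L
  s <- ds$provenance$selfies[i]
  expect_identical(s, greedy_selfies(vae, ds$latents[i, , drop = FALSE]))
  r <- descriptor_oracle(s, check_geometry = FALSE)
  expect_equal(as.numeric(r$properties), unname(ds$properties[i, ]))
})

test_that("legacy encoding pairs every training molecule with its posterior mean", {
  vae <- fx_vae()
  ds <- fx_dataset()
  leg <- legacy_encode_dataset(ds, vae)
  expect_equal(nrow(leg$latents), length(ds$records))
  expect_true(all(leg$provenance$status == "legacy"))
  ids <- tokenize(ds$records[[1]]$selfies, vae$vocab)
  post <- encode(vae, ids, ds$records[[1]]$graph)
  expect_equal(unname(leg$latents[1, ]), as.numeric(post$mean))
  expect_equal(unname(leg$properties[1, ]),
               unname(as.matrix(ds$properties)[1, ]))
})

test_that("datasets round-trip through the plain-text directory format", {
  A <- matrix(rnorm(4), 1, 4)
  Z <- sample_prior_latents(25, 4, seed = 9)
  ds <- reacquire(Z, "identity", make_analytic_oracle(A, 0.5), seed = 9)
  dir <- tempfile("ds")
  save_dataset(ds, dir, oracle_name = "analytic")
  back <- load_dataset(dir)
  expect_equal(back$latents, ds$latents, tolerance = 1e-12)
  expect_equal(back$properties, ds$properties, tolerance = 1e-12)
  expect_equal(back$stats$mean, ds$stats$mean, tolerance = 1e-12)
  expect_identical(back$property_names, ds$property_names)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(man$oracle, "analytic")
})
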
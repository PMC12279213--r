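test_that("encoding is deterministic and tolerates absent graphs", {
  vae <- fx_vae()
  ds <- fx_dataset()
  r <- ds$records[[1]]
  ids <- tokenize(r$selfies, vae$vocab)
  p1 <- encode(vae, ids, r$graph)
  p2 <- encode(vae, ids, r$graph)
  expect_identical(p1, p2)
  expect_true(all(is.finite(p1$mean)))
  # graph branch tolerates a missing 3D view
  p3 <- encode(vae, ids, NULL)
  expect_true(all(is.finite(p3$mean)))
  expect_false(identical(p1$mean, p3$mean))
})

test_that("posterior means are finite across the training corpus", {
  vae <- fx_vae()
  ds <- fx_dataset()
  ids <- t(vapply(ds$records, function(r) tokenize(r$selfies, vae$vocab),
                  integer(vae$vocab$max_length)))
  post <- encode(vae, ids, lapply(ds$records, `[[`, "graph"))
  expect_true(all(is.finite(post$mean)))
  expect_true(all(is.finite(post$log_variance)))
})

test_that("reparameterized sampling has the right limits and moments", {
  dist <- structure(list(mean = matrix(c(1, -2), 1, 2),
                         log_variance = matrix(c(-60, -60), 1, 2)),
                    class = "latent_distribution")
  z <- sample_latent(dist, seed = 1)
  expect_equal(as.numeric(z), c(1, -2), tolerance = 1e-10)

  dist2 <- structure(list(mean = matrix(0.5, 1, 1),
                          log_variance = matrix(log(4), 1, 1)),
                     class = "latent_distribution")
  expect_identical(sample_latent(dist2, seed = 3), sample_latent(dist2, seed = 3))
  big <- structure(list(mean = matrix(0.5, 1e5, 1),
                        log_variance = matrix(log(4), 1e5, 1)),
                   class = "latent_distribution")
  draws <- sample_latent(big, seed = 4)
  # Monte-Carlo 3-sigma band for the mean of 1e5 draws with sd 2
  expect_lt(abs(mean(draws) - 0.5), 3 * 2 / sqrt(1e5))
  expect_lt(abs(sd(draws) - 2), 0.05)
})

test_that("closed-form KL matches hand values and a Monte-Carlo estimate", {
  expect_equal(kl_standard_normal(0, 0), 0)
  expect_equal(kl_standard_normal(1, 0), 0.5)
  expect_equal(kl_standard_normal(c(1, 1), c(0, 0)), 1)

  set.seed(12)
  mu <- runif(4, -2, 2); lv <- runif(4, -1, 1)
  kl <- kl_standard_normal(mu, lv)
  n <- 2e5
  x <- matrix(rnorm(n * 4), n, 4)
  x <- sweep(sweep(x, 2, exp(lv / 2), "*"), 2, mu, "+")
  logq <- sapply(1:4, function(j) dnorm(x[, j], mu[j], exp(lv[j] / 2), log = TRUE))
  logp <- dnorm(x, log = TRUE)
  mc <- mean(rowSums(logq - logp))
  expect_equal(kl, mc, tolerance = 0.02)
})

test_that("the loss zero case behaves: perfect reconstruction at the prior", {
  vae <- fx_vae()
  ds <- fx_dataset()
  n <- 4
  recs <- ds$records[1:n]
  ids <- t(vapply(recs, function(r) tokenize(r$selfies, vae$vocab),
                  integer(vae$vocab$max_length)))
  graphs <- lapply(recs, `[[`, "graph")
  P <- matrix(0, n, 3)
  L <- vae$vocab$max_length; V <- length(vae$vocab$tokens)
  gp <- uncertmol:::pack_graphs(graphs, vae$max_atoms)
  X <- uncertmol:::tokens_onehot(ids, V)
  # construct an output that reproduces the targets exactly
  tgt_atom <- matrix(0, n, vae$max_atoms * 4)
  tgt_coord <- matrix(0, n, vae$max_atoms * 3)
  for (a in seq_len(vae$max_atoms)) {
    rows <- (seq_len(n) - 1L) * vae$max_atoms + a
    tgt_atom[, (a - 1) * 4 + 1:4] <- gp$feat[rows, 1:4]
    tgt_coord[, (a - 1) * 3 + 1:3] <- gp$feat[rows, 5:7]
  }
  out <- structure(list(
    selfies_logits = X * 1e4, atom_scores = tgt_atom, coords = tgt_coord,
    property_pred = P, L = L, V = V, max_atoms = vae$max_atoms
  ), class = "vae_output")
  post <- structure(list(mean = matrix(0, n, 8),
                         log_variance = matrix(0, n, 8)),
                    class = "latent_distribution")
  l <- vae_loss(out, post, ids, graphs, P)
  expect_equal(l$prop_l1, 0)
  expect_equal(l$graph_l2, 0)
  expect_equal(l$kl, 0)
  expect_lt(l$selfies_ce, 1e-6)
  expect_lt(l$total, 1e-6)
})

test_that("the loss KL component equals the closed form", {
  vae <- fx_vae()
  ds <- fx_dataset()
  recs <- ds$records[1:3]
  ids <- t(vapply(recs, function(r) tokenize(r$selfies, vae$vocab),
                  integer(vae$vocab$max_length)))
  graphs <- lapply(recs, `[[`, "graph")
  post <- encode(vae, ids, graphs)
  out <- decode(vae, post$mean)
  P <- uncertmol:::apply_standardize(as.matrix(ds$properties[1:3, ]),
                                     vae$prop_stats)
  l <- vae_loss(out, post, ids, graphs, P)
  expect_equal(l$kl,
               mean(kl_standard_normal(post$mean, post$log_variance)),
               tolerance = 1e-12)
})

test_that("training is seeded-deterministic and reduces the loss", {
  ds <- fx_dataset()
  cfg <- vae_config(latent_dim = 8, epochs = 5, max_length = 12, seed = 6)
  m1 <- train_vae(ds, cfg)
  m2 <- train_vae(ds, cfg)
  expect_identical(m1$history, m2$history)
  expect_equal(nrow(m1$history), 5L)
  expect_lt(m1$history$total[5], m1$history$total[1])
})

test_that("training improves reconstruction and property prediction over the untrained model", {
  ds <- fx_dataset()
  vae <- fx_vae()
  cfg0 <- vae$config; cfg0$epochs <- 0L
  # untrained reference: same architecture, zero epochs
  un <- train_vae(ds, vae_config(latent_dim = 8, epochs = 1, lr = 0,
                                 max_length = 12, seed = 2))
  ids <- t(vapply(ds$records, function(r) tokenize(r$selfies, vae$vocab),
                  integer(vae$vocab$max_length)))
  graphs <- lapply(ds$records, `[[`, "graph")
  acc <- function(m) {
    post <- encode(m, ids, graphs)
    out <- decode(m, post$mean)
    V <- length(m$vocab$tokens)
    pred <- matrix(0L, nrow(ids), ncol(ids))
    for (l in seq_len(ncol(ids))) {
      cols <- (l - 1) * V + seq_len(V)
      pred[, l] <- max.col(out$selfies_logits[, cols, drop = FALSE],
                           ties.method = "first")
    }
    mean(pred == ids)
  }
  expect_gt(acc(vae), acc(un))
  pm <- function(m) {
    post <- encode(m, ids, graphs)
    mean(abs(vae_predict_properties(m, post$mean) - as.matrix(ds$properties)))
  }
  expect_lt(pm(vae), pm(un))
})

test_that("every prior sample decodes deterministically to a valid molecule", {
  vae <- fx_vae()
  Z <- sample_prior_latents(200, 8, seed = 9)
  s1 <- greedy_selfies(vae, Z)
  s2 <- greedy_selfies(vae, Z)
  expect_identical(s1, s2)
  for (s in s1) {
    topo <- decode_selfies(s)
    expect_gte(topo$n_atoms, 1)
  }
})

test_that("after training, property-similar molecules sit closer in latent space", {
  vae <- fx_vae()
  ds <- fx_dataset()
  ids <- t(vapply(ds$records, function(r) tokenize(r$selfies, vae$vocab),
                  integer(vae$vocab$max_length)))
  post <- encode(vae, ids, lapply(ds$records, `[[`, "graph"))
  Z <- post$mean
  P <- uncertmol:::apply_standardize(as.matrix(ds$properties), vae$prop_stats)
  n <- nrow(Z)
  dz <- as.matrix(dist(Z)); dp <- as.matrix(dist(P))
  ut <- upper.tri(dz)
  # pairs in the most property-similar decile vs all pairs
  sim <- dp[ut] <= quantile(dp[ut], 0.1)
  expect_lt(mean(dz[ut][sim]), mean(dz[ut]))
})

test_that("ablating the property head weakens property organization of the latent space", {
  ds <- fx_dataset()
  latprop_cor <- function(weight_prop, seed) {
    m <- train_vae(ds, vae_config(latent_dim = 8, epochs = 25, lr = 3e-3,
                                  max_length = 12, seed = seed,
                                  weights = c(prop = weight_prop)))
    ids <- t(vapply(ds$records, function(r) tokenize(r$selfies, m$vocab),
                    integer(m$vocab$max_length)))
    Z <- encode(m, ids, lapply(ds$records, `[[`, "graph"))$mean
    P <- uncertmol:::apply_standardize(as.matrix(ds$properties), m$prop_stats)
    dz <- as.matrix(dist(Z)); dp <- as.matrix(dist(P)); ut <- upper.tri(dz)
    cor(dz[ut], dp[ut])
  }
  seeds <- c(11, 12, 13)
  full <- vapply(seeds, function(s) latprop_cor(1, s), numeric(1))
  ablated <- vapply(seeds, function(s) latprop_cor(0, s), numeric(1))
  expect_gt(mean(full), mean(ablated))
})

test_that("the default fixture suite builds quickly", {
  t0 <- Sys.time()
  spec <- fixture_spec(n_molecules = 200, seed = 17)
  corpus <- generate_selfies_corpus(spec, embed = TRUE)
  ds <- build_labelled_dataset(corpus, "descriptors")
  h <- closed_loop_harness(d = 16, n_train = 2000, seed = 17)
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_gt(length(ds$records), 100)
  expect_equal(nrow(h$dataset$latents), 2000L)
  expect_lt(elapsed, 60)
})

test_that("model checkpoints round-trip through JSON", {
  vae <- fx_vae()
  path <- tempfile(fileext = ".json")
  save_model(vae, path)
  back <- load_model(path)
  Z <- sample_prior_latents(5, 8, seed = 10)
  expect_identical(greedy_selfies(back, Z), greedy_selfies(vae, Z))
  expect_equal(back$prop_stats, vae$prop_stats)
})
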
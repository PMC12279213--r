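# The hand-written forward/backward passes are the package's numerical
# core; finite differences are the independent oracle for them.

test_that("activation derivatives match finite differences", {
  x <- matrix(seq(-2.95, 3.05, length.out = 31), 1)  # avoid the relu kink at 0
  h <- 1e-6
  for (act in uncertmol:::ACTIVATIONS) {
    num <- (uncertmol:::act_forward(x + h, act) -
            uncertmol:::act_forward(x - h, act)) / (2 * h)
    ana <- uncertmol:::act_grad(x, act)
    expect_equal(ana, num, tolerance = 1e-5, label = act)
  }
})

test_that("MLP backward matches finite differences for every activation", {
  set.seed(4)
  X <- matrix(rnorm(3 * 5), 3, 5)
  Y <- matrix(rnorm(3 * 2), 3, 2)
  h <- 1e-6
  for (act in uncertmol:::ACTIVATIONS) {
    net <- uncertmol:::mlp_new(c(5, 7, 2), act, seed = 8)
    lossfn <- function(net) {
      out <- uncertmol:::mlp_forward(net, X)$out
      sum((out - Y)^2)
    }
    fw <- uncertmol:::mlp_forward(net, X)
    bw <- uncertmol:::mlp_backward(net, fw$cache, 2 * (fw$out - Y))
    for (l in 1:2) {
      for (idx in c(1, 3)) {
        n2 <- net; n2$layers[[l]]$W[idx] <- n2$layers[[l]]$W[idx] + h
        n3 <- net; n3$layers[[l]]$W[idx] <- n3$layers[[l]]$W[idx] - h
        num <- (lossfn(n2) - lossfn(n3)) / (2 * h)
        expect_equal(bw$grads[[l]]$W[idx], num, tolerance = 1e-4, label = act)
      }
    }
    # gradient with respect to the input (needed by the latent optimizer)
    i <- 2
    X2 <- X; X2[1, i] <- X2[1, i] + h
    X3 <- X; X3[1, i] <- X3[1, i] - h
    num <- (sum((uncertmol:::mlp_forward(net, X2)$out - Y)^2) -
            sum((uncertmol:::mlp_forward(net, X3)$out - Y)^2)) / (2 * h)
    expect_equal(bw$dX[1, i], num, tolerance = 1e-4, label = act)
  }
})

test_that("AdamW reduces a simple regression loss", {
  set.seed(5)
  X <- matrix(rnorm(100 * 3), 100, 3)
  Y <- X %*% c(1, -2, 0.5)
  net <- uncertmol:::mlp_new(c(3, 8, 1), "tanh", seed = 6)
  st <- uncertmol:::adamw_init(net$layers)
  loss0 <- sum((uncertmol:::mlp_forward(net, X)$out - Y)^2) / 100
  for (t in 1:200) {
    fw <- uncertmol:::mlp_forward(net, X)
    bw <- uncertmol:::mlp_backward(net, fw$cache, 2 * (fw$out - Y) / 100)
    upd <- uncertmol:::adamw_step(net$layers, bw$grads, st, 0.01, t)
    net$layers <- upd$layers; st <- upd$state
  }
  loss1 <- sum((uncertmol:::mlp_forward(net, X)$out - Y)^2) / 100
  expect_lt(loss1, loss0 / 10)
})

test_that("cosine schedule interpolates from lr0 to lr_min", {
  expect_equal(uncertmol:::cosine_lr(1, 100, 0.1, 0.001), 0.1)
  expect_equal(uncertmol:::cosine_lr(100, 100, 0.1, 0.001), 0.001)
  mid <- uncertmol:::cosine_lr(50, 100, 0.1, 0)
  expect_true(mid < 0.1 && mid > 0.01)
  # monotone non-increasing
  lrs <- sapply(1:100, uncertmol:::cosine_lr, t_max = 100, lr0 = 0.1)
  expect_true(all(diff(lrs) <= 1e-12))
})

test_that("standardization round-trips and has unit statistics", {
  set.seed(7)
  P <- matrix(rnorm(50 * 3, mean = c(10, -5, 100), sd = c(2, 1, 30)), 50, 3,
              byrow = TRUE)
  st <- uncertmol:::standardize_stats(P)
  Ps <- uncertmol:::apply_standardize(P, st)
  expect_equal(colMeans(Ps), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(Ps, 2, sd), rep(1, 3), tolerance = 1e-12)
  expect_equal(uncertmol:::undo_standardize(Ps, st), P, tolerance = 1e-12)
})
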
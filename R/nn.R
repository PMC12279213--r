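# Minimal dense-network toolkit: explicit forward/backward passes over
# base-R matrices, an AdamW optimizer and a cosine-annealing schedule.
# Sized for the desk-scale models this package trains (a few thousand to a
# few hundred thousand parameters); everything is seeded and deterministic.

act_forward <- function(x, name) {
  switch(name,
    identity = x,
    relu = pmax(x, 0),
    tanh = tanh(x),
    gelu = x * stats::pnorm(x),
    silu = x / (1 + exp(-x)),
    elu  = ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    stop("unknown activation: ", name)
  )
}

# derivative of the activation as a function of pre-activation x
act_grad <- function(x, name) {
  switch(name,
    identity = array(1, dim = dim(x)),
    relu = (x > 0) * 1,
    tanh = 1 - tanh(x)^2,
    gelu = stats::pnorm(x) + x * stats::dnorm(x),
    silu = { s <- 1 / (1 + exp(-x)); s * (1 + x * (1 - s)) },
    elu  = ifelse(x > 0, 1, exp(pmin(x, 0))),
    stop("unknown activation: ", name)
  )
}

ACTIVATIONS <- c("relu", "tanh", "gelu", "silu", "elu")

# Dense layer parameter init (Glorot-uniform), seeded.
layer_init <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = rep(0, n_out))
}

# A plain MLP: sizes = c(d_in, hidden..., d_out); hidden layers share one
# activation, output layer is linear.
mlp_new <- function(sizes, activation, seed = 1L) {
  stopifnot(length(sizes) >= 2)
  layers <- with_seed(seed, {
    lapply(seq_len(length(sizes) - 1L),
           function(i) layer_init(sizes[i], sizes[i + 1L]))
  })
  structure(list(layers = layers, sizes = sizes, activation = activation),
            class = "uncertmol_mlp")
}

# forward pass; X is n x d_in. Returns list(out, cache) where cache holds
# per-layer inputs and pre-activations for the backward pass.
mlp_forward <- function(net, X) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  L <- length(net$layers)
  ins <- vector("list", L); pre <- vector("list", L)
  h <- X
  for (l in seq_len(L)) {
    ins[[l]] <- h
    z <- h %*% net$layers[[l]]$W +
      matrix(net$layers[[l]]$b, nrow(h), length(net$layers[[l]]$b), byrow = TRUE)
    pre[[l]] <- z
    h <- if (l < L) act_forward(z, net$activation) else z
  }
  list(out = h, cache = list(ins = ins, pre = pre))
}

# backward pass: dY is the gradient at the output (n x d_out).
# Returns list(grads = per-layer list(W, b), dX = gradient at the input).
mlp_backward <- function(net, cache, dY) {
  L <- length(net$layers)
  grads <- vector("list", L)
  delta <- dY
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * act_grad(cache$pre[[l]], net$activation)
    grads[[l]] <- list(W = crossprod(cache$ins[[l]], delta),
                       b = colSums(delta))
    delta <- delta %*% t(net$layers[[l]]$W)
  }
  list(grads = grads, dX = delta)
}

# ---- AdamW -------------------------------------------------------------

adamw_init <- function(layers) {
  lapply(layers, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0
  ))
}

# One decoupled-weight-decay Adam step over a list of layers.
adamw_step <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       weight_decay = 1e-2) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (l in seq_along(layers)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W^2
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b^2
    layers[[l]]$W <- layers[[l]]$W - lr *
      (st$mW / c1 / (sqrt(st$vW / c2) + eps) + weight_decay * layers[[l]]$W)
    layers[[l]]$b <- layers[[l]]$b - lr * (st$mb / c1 / (sqrt(st$vb / c2) + eps))
    state[[l]] <- st
  }
  list(layers = layers, state = state)
}

# Cosine-annealed learning rate at step t of t_max (1-based).
cosine_lr <- function(t, t_max, lr0, lr_min = 0) {
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * (t - 1) / max(t_max - 1, 1)))
}

# standardization statistics of a property matrix (columns = properties)
standardize_stats <- function(P) {
  mu <- colMeans(P)
  sd <- apply(P, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

apply_standardize <- function(P, stats) {
  sweep(sweep(P, 2, stats$mean, "-"), 2, stats$sd, "/")
}

undo_standardize <- function(P, stats) {
  sweep(sweep(P, 2, stats$sd, "*"), 2, stats$mean, "+")
}
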
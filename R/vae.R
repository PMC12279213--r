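#' Configuration for the multi-view molecular VAE
#'
#' The VAE encodes two linked views of a molecule — its token sequence and
#' its 3D heavy-atom graph — into one latent vector, and is trained to
#' reconstruct both views and to predict the molecule's properties from
#' the latent. The property head is what organizes the latent space so
#' that nearby latents have similar properties, which is the premise of
#' optimizing designs in this space.
#'
#' @param latent_dim Latent dimension d (default 64).
#' @param hidden Decoder/encoder fusion hidden width (default 128).
#' @param token_feat,graph_feat Widths of the two encoder branches.
#' @param prop_hidden Hidden width of the latent-to-property head.
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Initial AdamW learning rate, cosine-annealed to `lr_min`.
#' @param lr_min Final learning rate of the cosine schedule.
#' @param weights Named loss weights `prop`, `graph`, `ce`, `kl`
#'   (default all 1: the training objective is their unweighted sum).
#' @param max_atoms Heavy-atom padding size for graphs (default: largest
#'   graph in the training set).
#' @param max_length Token positions per molecule (default 32).
#' @param seed Integer seed controlling initialization, shuffling and
#'   latent sampling.
#' @return A `vae_config` list.
#' @export
vae_config <- function(latent_dim = 64L, hidden = 128L, token_feat = 64L,
                       graph_feat = 32L, prop_hidden = 32L,
                       epochs = 50L, batch_size = 32L,
                       lr = 1e-3, lr_min = 1e-5,
                       weights = c(prop = 1, graph = 1, ce = 1, kl = 1),
                       max_atoms = NULL, max_length = 32L, seed = 1L) {
  w <- c(prop = 1, graph = 1, ce = 1, kl = 1)
  w[names(weights)] <- weights
  structure(list(
    latent_dim = as.integer(latent_dim), hidden = as.integer(hidden),
    token_feat = as.integer(token_feat), graph_feat = as.integer(graph_feat),
    prop_hidden = as.integer(prop_hidden), epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), lr = lr, lr_min = lr_min,
    weights = w, max_atoms = max_atoms, max_length = as.integer(max_length),
    seed = as.integer(seed)
  ), class = "vae_config")
}

GRAPH_ELEMENTS <- c("C", "N", "O", "F")

# one-hot token matrix: B x (L*V) from a B x L id matrix
tokens_onehot <- function(ids, V) {
  B <- nrow(ids); L <- ncol(ids)
  X <- matrix(0, B, L * V)
  pos <- rep(seq_len(L), each = B)
  X[cbind(rep(seq_len(B), L), (pos - 1L) * V + as.vector(ids))] <- 1
  X
}

# pack a list of graphs (or NULLs) into padded arrays.
# Coordinates are centered per molecule (the reconstruction is
# non-equivariant, in the input frame).
pack_graphs <- function(graphs, max_atoms) {
  B <- length(graphs); E <- length(GRAPH_ELEMENTS)
  feat <- matrix(0, B * max_atoms, E + 3)
  mask <- matrix(0, B, max_atoms)
  has <- numeric(B)
  for (b in seq_len(B)) {
    g <- graphs[[b]]
    if (is.null(g)) next
    n <- min(g$n_atoms, max_atoms)
    has[b] <- 1
    mask[b, seq_len(n)] <- 1
    rows <- (b - 1L) * max_atoms + seq_len(n)
    el <- match(g$atom_types[seq_len(n)], GRAPH_ELEMENTS)
    coords <- g$coords[seq_len(n), , drop = FALSE]
    coords <- sweep(coords, 2, colMeans(coords), "-")
    feat[cbind(rows, el)] <- 1
    feat[rows, E + 1:3] <- coords
  }
  list(feat = feat, mask = mask, has = has, max_atoms = max_atoms)
}

dense <- function(X, ly) X %*% ly$W + matrix(ly$b, nrow(X), length(ly$b), byrow = TRUE)

vae_param_names <- c("enc_tok", "enc_graph", "fuse1", "fuse2",
                     "dec_core", "head_seq", "head_atom", "head_coord",
                     "prop1", "prop2")

init_vae_params <- function(L, V, E, max_atoms, k, cfg) {
  with_seed(cfg$seed, list(
    enc_tok   = layer_init(L * V, cfg$token_feat),
    enc_graph = layer_init(E + 3, cfg$graph_feat),
    fuse1     = layer_init(cfg$token_feat + cfg$graph_feat + 1, cfg$hidden),
    fuse2     = layer_init(cfg$hidden, 2L * cfg$latent_dim),
    dec_core  = layer_init(cfg$latent_dim, cfg$hidden),
    head_seq  = layer_init(cfg$hidden, L * V),
    head_atom = layer_init(cfg$hidden, max_atoms * E),
    head_coord = layer_init(cfg$hidden, max_atoms * 3L),
    prop1     = layer_init(cfg$latent_dim, cfg$prop_hidden),
    prop2     = layer_init(cfg$prop_hidden, k)
  ))
}

# encoder forward: returns mu, logvar and caches
vae_encode_forward <- function(par, X_tok, gpack) {
  tok_pre <- dense(X_tok, par$enc_tok)
  tok_feat <- tanh(tok_pre)
  atom_pre <- dense(gpack$feat, par$enc_graph)
  atom_h <- tanh(atom_pre)
  B <- nrow(X_tok); A <- gpack$max_atoms
  cnt <- pmax(rowSums(gpack$mask), 1)
  w <- as.vector(t(gpack$mask / cnt))          # (B*A), row-major by molecule
  grp <- rep(seq_len(B), each = A)
  pool <- rowsum(atom_h * w, grp)
  flag <- matrix(1 - gpack$has, B, 1)
  fuse_in <- cbind(tok_feat, pool, flag)
  f1_pre <- dense(fuse_in, par$fuse1)
  f1 <- tanh(f1_pre)
  out <- dense(f1, par$fuse2)
  d <- ncol(out) %/% 2L
  mu <- out[, seq_len(d), drop = FALSE]
  logvar <- pmin(pmax(out[, d + seq_len(d), drop = FALSE], -10), 10)
  list(mu = mu, logvar = logvar,
       cache = list(X_tok = X_tok, tok_pre = tok_pre, atom_pre = atom_pre,
                    atom_h = atom_h, w = w, grp = grp, A = A,
                    fuse_in = fuse_in, f1_pre = f1_pre, f1 = f1))
}

vae_decode_forward <- function(par, Z) {
  core_pre <- dense(Z, par$dec_core)
  h <- tanh(core_pre)
  list(seq = dense(h, par$head_seq),
       atom = dense(h, par$head_atom),
       coord = dense(h, par$head_coord),
       cache = list(Z = Z, core_pre = core_pre, h = h))
}

vae_prop_forward <- function(par, Z) {
  p1_pre <- dense(Z, par$prop1)
  h <- tanh(p1_pre)
  list(pred = dense(h, par$prop2),
       cache = list(Z = Z, p1_pre = p1_pre, h = h))
}

# row-wise softmax over V classes applied to each of L blocks
blockwise_softmax <- function(logits, L, V) {
  B <- nrow(logits)
  out <- logits
  for (l in seq_len(L)) {
    cols <- (l - 1L) * V + seq_len(V)
    x <- logits[, cols, drop = FALSE]
    x <- x - apply(x, 1, max)
    ex <- exp(x)
    out[, cols] <- ex / rowSums(ex)
  }
  out
}

#' Encode molecules to their latent posterior
#'
#' The graph branch tolerates absent graphs (zero features plus an
#' absence flag), so molecules whose conformer embedding failed can still
#' be encoded from their token view.
#'
#' @param model A trained `sgp_vae` model.
#' @param tokens Integer token sequence (length `max_length`) or a matrix
#'   with one sequence per row.
#' @param graph A `molecule_graph`, a list of them (or NULLs), or NULL.
#' @return A `latent_distribution`: list with `mean` and `log_variance`
#'   (matrices, one row per molecule).
#' @export
encode <- function(model, tokens, graph = NULL) {
  ids <- if (is.matrix(tokens)) tokens else matrix(tokens, nrow = 1)
  stopifnot(ncol(ids) == model$vocab$max_length)
  graphs <- if (is.null(graph)) vector("list", nrow(ids))
            else if (inherits(graph, "molecule_graph")) list(graph)
            else graph
  stopifnot(length(graphs) == nrow(ids))
  X <- tokens_onehot(ids, length(model$vocab$tokens))
  gp <- pack_graphs(graphs, model$max_atoms)
  enc <- vae_encode_forward(model$params, X, gp)
  structure(list(mean = enc$mu, log_variance = enc$logvar),
            class = "latent_distribution")
}

#' Sample a latent vector by reparameterization
#'
#' `z = mean + exp(log_variance / 2) * eps`, `eps ~ N(0, 1)`, seeded.
#'
#' @param dist A `latent_distribution`.
#' @param seed Integer seed.
#' @return Matrix of latents (one row per distribution row).
#' @export
sample_latent <- function(dist, seed = 1L) {
  mu <- dist$mean; lv <- dist$log_variance
  eps <- with_seed(seed, matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)))
  mu + exp(lv / 2) * eps
}

#' Decode latent vectors into reconstruction scores
#'
#' @param model A trained `sgp_vae`.
#' @param z Latent vector (length d) or matrix (n x d).
#' @return A `vae_output`: list with `selfies_logits` (n x L*V),
#'   `atom_scores`, `coords`, `property_pred` (standardized space), and
#'   the dimensions needed to interpret them.
#' @export
decode <- function(model, z) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  stopifnot(ncol(Z) == model$config$latent_dim)
  dec <- vae_decode_forward(model$params, Z)
  prop <- vae_prop_forward(model$params, Z)
  structure(list(
    selfies_logits = dec$seq, atom_scores = dec$atom, coords = dec$coord,
    property_pred = prop$pred,
    L = model$vocab$max_length, V = length(model$vocab$tokens),
    max_atoms = model$max_atoms
  ), class = "vae_output")
}

#' Greedy-decode latents to molecular strings
#'
#' Per-position argmax over the symbol logits, truncated at the first
#' `[STOP]`/`[PAD]`; by the derivation robustness guarantee the result is
#' always a valid molecule.
#'
#' @param model A trained `sgp_vae`.
#' @param z Latent vector or matrix of latents.
#' @param sample Logical: sample from the per-position distributions
#'   instead of taking the argmax (default FALSE, deterministic).
#' @param seed Seed for sampling decode.
#' @return Character vector of molecular strings.
#' @export
greedy_selfies <- function(model, z, sample = FALSE, seed = 1L) {
  out <- decode(model, z)
  V <- out$V; L <- out$L
  n <- nrow(out$selfies_logits)
  ids <- matrix(0L, n, L)
  if (sample) {
    probs <- blockwise_softmax(out$selfies_logits, L, V)
    ids <- with_seed(seed, {
      m <- matrix(0L, n, L)
      for (l in seq_len(L)) {
        cols <- (l - 1L) * V + seq_len(V)
        for (b in seq_len(n)) m[b, l] <- sample.int(V, 1, prob = probs[b, cols])
      }
      m
    })
  } else {
    for (l in seq_len(L)) {
      cols <- (l - 1L) * V + seq_len(V)
      ids[, l] <- max.col(out$selfies_logits[, cols, drop = FALSE],
                          ties.method = "first")
    }
  }
  vapply(seq_len(n), function(b) detokenize(ids[b, ], model$vocab), character(1))
}

#' Closed-form KL divergence to the standard normal
#'
#' `KL(N(mu, diag(sigma^2)) || N(0, I)) =
#'  0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param mean,log_variance Numeric vectors (or matrices, row per
#'   distribution) of the diagonal Gaussian's parameters.
#' @return KL in nats (vector with one value per row).
#' @export
#' @examples
#' kl_standard_normal(0, 0)   # 0
#' kl_standard_normal(1, 0)   # 0.5
kl_standard_normal <- function(mean, log_variance) {
  mu <- if (is.matrix(mean)) mean else matrix(mean, nrow = 1)
  lv <- if (is.matrix(log_variance)) log_variance else matrix(log_variance, nrow = 1)
  stopifnot(all(dim(mu) == dim(lv)))
  drop(0.5 * rowSums(mu^2 + exp(lv) - 1 - lv))
}

#' Loss components of the multi-view VAE
#'
#' `total = |p - p_hat| + ||x_graph - x_graph_hat||^2_2 +
#'  CE(x_string, x_string_hat) + KL(q(z) || N(0, 1))`, each term averaged
#' over the batch; the graph term is masked to real atoms and skipped for
#' molecules without a graph; properties are compared in standardized
#' space. The KL term uses the diagonal-Gaussian closed form
#' `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param output A `vae_output` from [decode()].
#' @param posterior A `latent_distribution` from [encode()].
#' @param target_tokens Token id matrix (n x L).
#' @param target_graphs List of `molecule_graph`s or NULLs.
#' @param target_properties Standardized property matrix (n x k).
#' @param weights Named loss weights (default all 1).
#' @return Named list `prop_l1`, `graph_l2`, `selfies_ce`, `kl`, `total`.
#' @export
vae_loss <- function(output, posterior, target_tokens, target_graphs,
                     target_properties,
                     weights = c(prop = 1, graph = 1, ce = 1, kl = 1)) {
  ids <- if (is.matrix(target_tokens)) target_tokens else matrix(target_tokens, nrow = 1)
  P <- as.matrix(target_properties)
  B <- nrow(ids); L <- output$L; V <- output$V
  gp <- pack_graphs(
    if (is.null(target_graphs)) vector("list", B) else target_graphs,
    output$max_atoms
  )
  comps <- vae_loss_core(output$selfies_logits, output$atom_scores,
                         output$coords, output$property_pred,
                         posterior$mean, posterior$log_variance,
                         tokens_onehot(ids, V), gp, P, L, V, weights)
  for (nm in names(comps$loss))
    if (!is.finite(comps$loss[[nm]]))
      stop("non-finite loss component: ", nm)
  comps$loss
}

# shared by vae_loss and the training loop; also returns output-side
# gradients for backprop
vae_loss_core <- function(seq_logits, atom_scores, coords, prop_pred,
                          mu, logvar, X_tok, gp, P, L, V, weights) {
  B <- nrow(X_tok)
  E <- length(GRAPH_ELEMENTS)
  A <- gp$max_atoms
  w <- weights

  dprop <- sign(prop_pred - P) / B
  prop_l1 <- sum(abs(prop_pred - P)) / B

  sm <- blockwise_softmax(seq_logits, L, V)
  # CE summed over positions, averaged over batch
  ce <- -sum(X_tok * log(pmax(sm, 1e-12))) / B
  dseq <- (sm - X_tok) / B

  # graph targets from gp: atom one-hot and centered coords with mask
  tgt_atom <- matrix(0, B, A * E)
  tgt_coord <- matrix(0, B, A * 3)
  amask <- matrix(0, B, A * E)
  cmask <- matrix(0, B, A * 3)
  if (any(gp$has > 0)) {
    fe <- gp$feat  # (B*A) x (E+3)
    for (a in seq_len(A)) {
      rows <- (seq_len(B) - 1L) * A + a
      tgt_atom[, (a - 1L) * E + seq_len(E)] <- fe[rows, seq_len(E)]
      tgt_coord[, (a - 1L) * 3L + 1:3] <- fe[rows, E + 1:3]
      amask[, (a - 1L) * E + seq_len(E)] <- gp$mask[, a]
      cmask[, (a - 1L) * 3L + 1:3] <- gp$mask[, a]
    }
  }
  graph_l2 <- (sum(((atom_scores - tgt_atom)^2) * amask) +
               sum(((coords - tgt_coord)^2) * cmask)) / B
  datom <- 2 * (atom_scores - tgt_atom) * amask / B
  dcoord <- 2 * (coords - tgt_coord) * cmask / B

  kl <- 0.5 * sum(mu^2 + exp(logvar) - 1 - logvar) / B
  dmu_kl <- w[["kl"]] * mu / B
  dlv_kl <- w[["kl"]] * 0.5 * (exp(logvar) - 1) / B

  total <- w[["prop"]] * prop_l1 + w[["graph"]] * graph_l2 +
    w[["ce"]] * ce + w[["kl"]] * kl
  list(
    loss = list(prop_l1 = prop_l1, graph_l2 = graph_l2, selfies_ce = ce,
                kl = kl, total = total),
    grad = list(dprop = w[["prop"]] * dprop, dseq = w[["ce"]] * dseq,
                datom = w[["graph"]] * datom, dcoord = w[["graph"]] * dcoord,
                dmu_kl = dmu_kl, dlv_kl = dlv_kl)
  )
}

# full backward pass for one batch -> list of per-parameter-group grads
vae_backward <- function(par, enc, dec, prop, grad, eps, X_tok, gp) {
  g <- list()
  # property head
  dh <- grad$dprop %*% t(par$prop2$W)
  g$prop2 <- list(W = crossprod(prop$cache$h, grad$dprop), b = colSums(grad$dprop))
  dp1 <- dh * (1 - tanh(prop$cache$p1_pre)^2)
  g$prop1 <- list(W = crossprod(prop$cache$Z, dp1), b = colSums(dp1))
  dZ_prop <- dp1 %*% t(par$prop1$W)

  # decoder heads
  dhc <- grad$dseq %*% t(par$head_seq$W) +
         grad$datom %*% t(par$head_atom$W) +
         grad$dcoord %*% t(par$head_coord$W)
  g$head_seq <- list(W = crossprod(dec$cache$h, grad$dseq), b = colSums(grad$dseq))
  g$head_atom <- list(W = crossprod(dec$cache$h, grad$datom), b = colSums(grad$datom))
  g$head_coord <- list(W = crossprod(dec$cache$h, grad$dcoord), b = colSums(grad$dcoord))
  dcore <- dhc * (1 - tanh(dec$cache$core_pre)^2)
  g$dec_core <- list(W = crossprod(dec$cache$Z, dcore), b = colSums(dcore))
  dZ_dec <- dcore %*% t(par$dec_core$W)

  dZ <- dZ_prop + dZ_dec
  # reparameterization: z = mu + exp(lv/2) * eps
  dmu <- dZ + grad$dmu_kl
  dlv <- dZ * eps * exp(enc$logvar / 2) * 0.5 + grad$dlv_kl
  dout <- cbind(dmu, dlv)

  cache <- enc$cache
  g$fuse2 <- list(W = crossprod(cache$f1, dout), b = colSums(dout))
  df1 <- (dout %*% t(par$fuse2$W)) * (1 - tanh(cache$f1_pre)^2)
  g$fuse1 <- list(W = crossprod(cache$fuse_in, df1), b = colSums(df1))
  dfuse_in <- df1 %*% t(par$fuse1$W)

  t_w <- ncol(par$enc_tok$W)
  g_w <- ncol(par$enc_graph$W)
  dtok_feat <- dfuse_in[, seq_len(t_w), drop = FALSE]
  dpool <- dfuse_in[, t_w + seq_len(g_w), drop = FALSE]

  dtok_pre <- dtok_feat * (1 - tanh(cache$tok_pre)^2)
  g$enc_tok <- list(W = crossprod(X_tok, dtok_pre), b = colSums(dtok_pre))

  datom_h <- dpool[cache$grp, , drop = FALSE] * cache$w
  datom_pre <- datom_h * (1 - tanh(cache$atom_pre)^2)
  g$enc_graph <- list(W = crossprod(gp$feat, datom_pre), b = colSums(datom_pre))
  g
}

#' Train the multi-view molecular VAE
#'
#' AdamW with a cosine-annealed learning rate; seeded end to end. The
#' history records the batch-averaged loss components per epoch. Training
#' aborts with a diagnostic if any component becomes non-finite.
#'
#' @param dataset A labelled dataset from [build_labelled_dataset()] (or a
#'   list with `records` and a numeric `properties` matrix).
#' @param config A [vae_config()].
#' @param vocab Optional vocabulary; built from the records by default.
#' @return An `sgp_vae` model: parameters, vocabulary, property
#'   standardization statistics, config, and `history` (data.frame of
#'   per-epoch loss components).
#' @export
train_vae <- function(dataset, config = vae_config(), vocab = NULL) {
  records <- dataset$records
  if (length(records) == 0) stop("empty dataset")
  P_nat <- as.matrix(dataset$properties)
  stopifnot(nrow(P_nat) == length(records))
  if (is.null(vocab))
    vocab <- build_vocabulary(vapply(records, `[[`, "", "selfies"),
                              max_length = config$max_length)
  graphs <- lapply(records, `[[`, "graph")
  max_atoms <- config$max_atoms
  if (is.null(max_atoms)) {
    sizes <- vapply(graphs, function(g) if (is.null(g)) 0L else g$n_atoms, 0L)
    max_atoms <- max(c(sizes, 4L))
  }
  pstats <- if (!is.null(dataset$stats)) dataset$stats else standardize_stats(P_nat)
  P <- apply_standardize(P_nat, pstats)

  ids <- t(vapply(records, function(r) tokenize(r$selfies, vocab),
                  integer(vocab$max_length)))
  L <- vocab$max_length; V <- length(vocab$tokens)
  E <- length(GRAPH_ELEMENTS)
  k <- ncol(P)
  cfg <- config
  par <- init_vae_params(L, V, E, max_atoms, k, cfg)
  opt <- adamw_init(par)

  n <- length(records)
  n_batch <- ceiling(n / cfg$batch_size)
  t_max <- cfg$epochs * n_batch
  hist <- matrix(NA_real_, cfg$epochs, 5,
                 dimnames = list(NULL, c("prop_l1", "graph_l2", "selfies_ce",
                                         "kl", "total")))
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 1000, ep), sample.int(n))
    acc <- numeric(5)
    for (bi in seq_len(n_batch)) {
      idx <- ord[seq.int((bi - 1L) * cfg$batch_size + 1L,
                         min(bi * cfg$batch_size, n))]
      X_tok <- tokens_onehot(ids[idx, , drop = FALSE], V)
      gp <- pack_graphs(graphs[idx], max_atoms)
      enc <- vae_encode_forward(par, X_tok, gp)
      eps <- with_seed(derive_seed(cfg$seed, 100003, step),
                       matrix(stats::rnorm(length(enc$mu)),
                              nrow(enc$mu), ncol(enc$mu)))
      Z <- enc$mu + exp(enc$logvar / 2) * eps
      dec <- vae_decode_forward(par, Z)
      prop <- vae_prop_forward(par, Z)
      lc <- vae_loss_core(dec$seq, dec$atom, dec$coord, prop$pred,
                          enc$mu, enc$logvar, X_tok, gp,
                          P[idx, , drop = FALSE], L, V, cfg$weights)
      if (!all(vapply(lc$loss, is.finite, logical(1)))) {
        bad <- names(lc$loss)[!vapply(lc$loss, is.finite, logical(1))]
        stop("training diverged at epoch ", ep, " (non-finite: ",
             paste(bad, collapse = ", "), ")")
      }
      grads <- vae_backward(par, enc, dec, prop, lc$grad, eps, X_tok, gp)
      step <- step + 1L
      lr <- cosine_lr(step, t_max, cfg$lr, cfg$lr_min)
      upd <- adamw_step(par[vae_param_names], grads[vae_param_names], opt,
                        lr, step)
      par <- upd$layers; opt <- upd$state
      acc <- acc + unlist(lc$loss)
    }
    hist[ep, ] <- acc / n_batch
  }
  structure(list(
    params = par, vocab = vocab, config = cfg, max_atoms = max_atoms,
    property_names = colnames(P_nat), property_units = dataset$units,
    prop_stats = pstats,
    history = as.data.frame(hist)
  ), class = "sgp_vae")
}

#' @export
print.sgp_vae <- function(x, ...) {
  cat("<sgp_vae> d =", x$config$latent_dim, "|", length(x$vocab$tokens),
      "tokens x", x$vocab$max_length, "positions |", x$max_atoms,
      "atom slots |", length(x$property_names), "properties\n")
  if (nrow(x$history) > 0)
    cat("  trained", nrow(x$history), "epochs; final total loss",
        round(x$history$total[nrow(x$history)], 4), "\n")
  invisible(x)
}

#' Predict properties from latents (natural units)
#'
#' The VAE's own latent-to-property head, de-standardized to natural
#' units.
#'
#' @param model An `sgp_vae`.
#' @param z Latent vector or matrix.
#' @return Matrix (n x k) of property predictions.
#' @export
vae_predict_properties <- function(model, z) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  pred <- vae_prop_forward(model$params, Z)$pred
  colnames(pred) <- model$property_names
  undo_standardize(pred, model$prop_stats)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file JSON archives (R type-preserving
#' serialization) holding parameters, vocabulary, standardization
#' statistics and config.
#'
#' @param model A model object (`sgp_vae` or `surrogate_ensemble`).
#' @param path File path.
#' @return `save_model` returns the path invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  writeLines(jsonlite::serializeJSON(model, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
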
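#' Deep-ensemble property surrogate
#'
#' The surrogate is an ensemble of MLPs with identical layer structure but
#' different activation functions, trained latent -> standardized
#' properties. Its mean prediction is the design-time property estimate
#' and the population variance of member predictions is the epistemic
#' uncertainty: high where training latents are sparse, low where the
#' surrogate can be trusted.
#'
#' @param n_members Number of ensemble members (default 5).
#' @param hidden_layers Hidden widths shared by all members.
#' @param activations Activation names cycled across members.
#' @param q Per-iteration update probability of each member (stochastic
#'   gating; default 0.3, so 300 nominal epochs realize about 90
#'   update-epochs per member).
#' @param epochs Training epochs (default 300).
#' @param batch_size Mini-batch size (default 32).
#' @param lr Initial AdamW learning rate, cosine-annealed.
#' @param seed Integer seed.
#' @return An `ensemble_config`.
#' @export
ensemble_config <- function(n_members = 5L, hidden_layers = c(64L, 64L),
                            activations = ACTIVATIONS,
                            q = 0.3, epochs = 300L, batch_size = 32L,
                            lr = 1e-3, seed = 1L) {
  stopifnot(n_members >= 2, q > 0, q <= 1, all(hidden_layers >= 1))
  structure(list(
    n_members = as.integer(n_members),
    hidden_layers = as.integer(hidden_layers),
    activations = activations, q = q,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, seed = as.integer(seed)
  ), class = "ensemble_config")
}

#' Build an (untrained) ensemble surrogate
#'
#' Member `j` uses `activations[(j - 1) %% length(activations) + 1]` and
#' its own seeded initialization.
#'
#' @param config An [ensemble_config()].
#' @param latent_dim Input (latent) dimension.
#' @param property_dim Output (property) dimension.
#' @return A `surrogate_ensemble`.
#' @export
build_ensemble <- function(config, latent_dim, property_dim) {
  stopifnot(inherits(config, "ensemble_config"))
  sizes <- c(latent_dim, config$hidden_layers, property_dim)
  members <- lapply(seq_len(config$n_members), function(j) {
    act <- config$activations[(j - 1L) %% length(config$activations) + 1L]
    mlp_new(sizes, act, seed = derive_seed(config$seed, 101, j))
  })
  structure(list(
    members = members, config = config,
    latent_dim = latent_dim, property_dim = property_dim,
    stats = NULL, property_names = NULL, property_units = NULL,
    history = NULL
  ), class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  acts <- vapply(x$members, `[[`, "", "activation")
  cat("<surrogate_ensemble> ", length(x$members), " members (",
      paste(acts, collapse = ", "), "), ", x$latent_dim, " -> ",
      x$property_dim, if (is.null(x$stats)) " [untrained]" else " [trained]",
      "\n", sep = "")
  invisible(x)
}

# Bernoulli gating draws: epochs x n matrix of 0/1 update decisions, one
# column per member. Used by the trainer (per iteration) and by the
# schedule simulation.
gating_draws <- function(n_iter, n_members, q, seed) {
  with_seed(seed, matrix(stats::rbinom(n_iter * n_members, 1L, q),
                         n_iter, n_members))
}

#' Simulate the stochastically gated update schedule
#'
#' Draws the per-epoch Bernoulli(q) gating decisions for `n` independent
#' members over `epochs` epochs and returns each member's realized number
#' of update-epochs. With q = 0.3 and 300 epochs the expectation is 90.
#'
#' @param epochs Number of epochs.
#' @param q Update probability per epoch.
#' @param n Number of simulated members.
#' @param seed Integer seed.
#' @return Integer vector of length `n`: realized update-epochs.
#' @export
simulate_gating <- function(epochs = 300L, q = 0.3, n = 10000L, seed = 1L) {
  colSums(gating_draws(epochs, n, q, seed))
}

#' Train the ensemble surrogate with stochastic gating
#'
#' At each mini-batch iteration every member independently performs an
#' AdamW step with probability `q` (seeded Bernoulli draws). Training is
#' on L1 loss in standardized property space; the dataset's own
#' standardization statistics are stored with the model so design targets
#' share the same scaling.
#'
#' @param model A [build_ensemble()] result.
#' @param dataset A `latent_property_dataset`.
#' @param config Optional override of the config stored in `model`.
#' @return The trained `surrogate_ensemble`; `history` holds per-epoch
#'   mean L1 loss and per-member realized update counts
#'   (`update_counts`, `n_iterations`).
#' @export
train_ensemble <- function(model, dataset, config = NULL) {
  stopifnot(inherits(model, "surrogate_ensemble"),
            inherits(dataset, "latent_property_dataset"))
  cfg <- if (is.null(config)) model$config else config
  Z <- dataset$latents
  stopifnot(ncol(Z) == model$latent_dim)
  P <- apply_standardize(dataset$properties, dataset$stats)
  n <- nrow(Z)
  nm <- length(model$members)
  n_batch <- ceiling(n / cfg$batch_size)
  t_max <- cfg$epochs * n_batch
  gate <- gating_draws(t_max, nm, cfg$q, derive_seed(cfg$seed, 7, 13))
  opt <- lapply(model$members, function(m) adamw_init(m$layers))
  opt_t <- integer(nm)
  loss_ep <- numeric(cfg$epochs)
  it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, 7919, ep), sample.int(n))
    acc <- 0; n_acc <- 0L
    for (bi in seq_len(n_batch)) {
      it <- it + 1L
      idx <- ord[seq.int((bi - 1L) * cfg$batch_size + 1L,
                         min(bi * cfg$batch_size, n))]
      Zb <- Z[idx, , drop = FALSE]
      Pb <- P[idx, , drop = FALSE]
      lr <- cosine_lr(it, t_max, cfg$lr)
      for (j in seq_len(nm)) {
        if (gate[it, j] == 0L) next
        fw <- mlp_forward(model$members[[j]], Zb)
        err <- fw$out - Pb
        loss <- sum(abs(err)) / nrow(Zb)
        if (!is.finite(loss))
          stop("non-finite loss in ensemble member ", j, " at epoch ", ep)
        bw <- mlp_backward(model$members[[j]], fw$cache, sign(err) / nrow(Zb))
        opt_t[j] <- opt_t[j] + 1L
        upd <- adamw_step(model$members[[j]]$layers, bw$grads, opt[[j]],
                          lr, opt_t[j])
        model$members[[j]]$layers <- upd$layers
        opt[[j]] <- upd$state
        acc <- acc + loss; n_acc <- n_acc + 1L
      }
    }
    loss_ep[ep] <- if (n_acc > 0) acc / n_acc else NA_real_
  }
  model$stats <- dataset$stats
  model$property_names <- dataset$property_names
  model$property_units <- dataset$property_units
  model$history <- list(
    loss = loss_ep,
    update_counts = colSums(gate),
    n_iterations = t_max,
    q = cfg$q, epochs = cfg$epochs
  )
  model$config <- cfg
  model
}

# forward through all members at once; Z is n x d.
# Returns list(per_member = array n x k x m, mean = n x k)
ensemble_forward <- function(model, Z) {
  Z <- if (is.matrix(Z)) Z else matrix(Z, nrow = 1)
  m <- length(model$members)
  outs <- lapply(model$members, function(net) mlp_forward(net, Z)$out)
  arr <- array(unlist(outs), dim = c(nrow(Z), model$property_dim, m))
  list(per_member = arr, mean = apply(arr, c(1, 2), mean))
}

#' Predict properties with the ensemble surrogate
#'
#' @param object A `surrogate_ensemble`.
#' @param z Latent vector or matrix.
#' @param natural Logical: de-standardize predictions to natural units
#'   (default TRUE when standardization statistics are available).
#' @param ... Unused.
#' @return A `surrogate_prediction`: list with `mean` (n x k),
#'   `per_member` (n x k x m), `uncertainty` (n x k, standardized space)
#'   and `uncertainty_total` (length n).
#' @export
predict.surrogate_ensemble <- function(object, z, natural = !is.null(object$stats), ...) {
  Z <- if (is.matrix(z)) z else matrix(z, nrow = 1)
  if (ncol(Z) != object$latent_dim)
    stop("latent dimension ", ncol(Z), " does not match model (",
         object$latent_dim, ")")
  fw <- ensemble_forward(object, Z)
  m <- length(object$members)
  # one-pass population variance of member predictions (clipped at 0
  # against floating-point negatives)
  sq <- apply(fw$per_member^2, c(1, 2), mean)
  U <- pmax(sq - fw$mean^2, 0)
  mean_out <- fw$mean
  per <- fw$per_member
  if (natural && !is.null(object$stats)) {
    mean_out <- undo_standardize(mean_out, object$stats)
    for (j in seq_len(m))
      per[, , j] <- undo_standardize(
        matrix(per[, , j], ncol = object$property_dim), object$stats)
  }
  colnames(mean_out) <- object$property_names
  structure(list(
    mean = mean_out, per_member = per,
    uncertainty = U, uncertainty_total = rowSums(U),
    standardized = !natural || is.null(object$stats)
  ), class = "surrogate_prediction")
}

#' Epistemic uncertainty of the ensemble at a latent point
#'
#' Per property, the population variance of member predictions
#' `U = mean_j(phi_j(z)^2) - phi_avg(z)^2`, computed in standardized
#' property space; the aggregate is the sum over properties.
#'
#' @param model A `surrogate_ensemble`.
#' @param z Latent vector or matrix.
#' @return List with `per_property` (n x k matrix) and `total` (length n).
#' @export
epistemic_uncertainty <- function(model, z) {
  pr <- predict(model, z, natural = FALSE)
  list(per_property = pr$uncertainty, total = pr$uncertainty_total)
}
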
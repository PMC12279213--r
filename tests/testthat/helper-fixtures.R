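# Shared fixtures, built lazily once per test run. All construction is
# seeded so every test sees identical objects.

.fx <- new.env()

fx_corpus <- function() {
  if (is.null(.fx$corpus)) {
    spec <- fixture_spec(n_molecules = 80, max_tokens = 12, seed = 7)
    .fx$corpus <- generate_selfies_corpus(spec, embed = TRUE)
  }
  .fx$corpus
}

fx_dataset <- function() {
  if (is.null(.fx$dataset))
    .fx$dataset <- build_labelled_dataset(fx_corpus(), "descriptors")
  .fx$dataset
}

fx_vae <- function() {
  if (is.null(.fx$vae))
    .fx$vae <- train_vae(fx_dataset(),
                         vae_config(latent_dim = 8, epochs = 30, lr = 3e-3,
                                    max_length = 12, seed = 2))
  .fx$vae
}

# small trained closed-loop ensemble + its harness
fx_loop <- function() {
  if (is.null(.fx$loop)) {
    h <- closed_loop_harness(d = 6, n_train = 600, seed = 3)
    ens <- build_ensemble(ensemble_config(epochs = 80, seed = 4), 6, 1)
    ens <- train_ensemble(ens, h$dataset)
    .fx$loop <- list(harness = h, ensemble = ens)
  }
  .fx$loop
}

# an ensemble whose members are all the same exact linear map A z + b:
# phi_avg is exact and U is identically zero
linear_ensemble <- function(A, b, n_members = 3L) {
  A <- as.matrix(A)
  member <- structure(
    list(layers = list(list(W = t(A), b = b)),
         sizes = c(ncol(A), nrow(A)), activation = "relu"),
    class = "uncertmol_mlp")
  structure(list(
    members = rep(list(member), n_members),
    config = ensemble_config(n_members = n_members),
    latent_dim = ncol(A), property_dim = nrow(A),
    stats = list(mean = stats::setNames(rep(0, nrow(A)),
                                        paste0("p", seq_len(nrow(A)))),
                 sd = stats::setNames(rep(1, nrow(A)),
                                      paste0("p", seq_len(nrow(A))))),
    property_names = paste0("p", seq_len(nrow(A))),
    property_units = rep("", nrow(A)), history = NULL
  ), class = "surrogate_ensemble")
}
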
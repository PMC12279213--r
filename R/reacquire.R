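#' Latent-property training sets for the surrogate
#'
#' The surrogate is trained on pairs `(z, p)` where `z` is a latent and
#' `p` the property vector the forward process assigns to the molecule
#' that `z` decodes to. *Reacquisition* builds this set by sampling
#' latents from the prior, decoding them, and labelling the decoded
#' molecules with the oracle — so the pairs represent the latent space the
#' optimizer will actually search, rather than only the latents of
#' encoded dataset molecules.
#'
#' @name reacquisition
NULL

#' Sample latent vectors from the standard-normal prior
#'
#' @param N Number of latents.
#' @param d Latent dimension.
#' @param seed Integer seed.
#' @return N x d matrix of i.i.d. N(0, 1) draws.
#' @export
sample_prior_latents <- function(N, d, seed = 1L) {
  stopifnot(N >= 1, d >= 1)
  with_seed(seed, matrix(stats::rnorm(N * d), N, d))
}

new_latent_property_dataset <- function(latents, properties, provenance,
                                        names, units, stats = NULL) {
  colnames(latents) <- paste0("z", seq_len(ncol(latents)))
  colnames(properties) <- names
  if (is.null(stats)) stats <- standardize_stats(properties)
  structure(list(
    latents = latents, properties = properties, provenance = provenance,
    property_names = names, property_units = units, stats = stats
  ), class = "latent_property_dataset")
}

#' @export
print.latent_property_dataset <- function(x, ...) {
  cat("<latent_property_dataset> ", nrow(x$latents), " pairs, d = ",
      ncol(x$latents), ", properties: ",
      paste(x$property_names, collapse = ", "), "\n", sep = "")
  n_un <- attr(x, "n_unstable")
  if (!is.null(n_un)) cat("  (", n_un, " unstable latents excluded)\n", sep = "")
  invisible(x)
}

#' Reacquire latent-property pairs by decode / embed / label
#'
#' For each latent: decode to a molecule, (optionally) embed a conformer,
#' and compute properties with the forward oracle. Latents whose oracle
#' call is `unstable` are excluded and counted. The stored property of
#' every retained pair is recomputable by re-running the same
#' decode-embed-label chain on its latent.
#'
#' @param latents N x d matrix (e.g. from [sample_prior_latents()]).
#' @param decoder An `sgp_vae` model, or `"identity"` for closed-loop
#'   harnesses where the oracle consumes latents directly.
#' @param oracle A function following the oracle contract
#'   (`x -> oracle_result`), or `"descriptors"` for the batched
#'   descriptor forward process.
#' @param embedder `"distance_geometry"` to embed conformers (via
#'   [embed_topology()]) for oracles that consume graphs, `"none"` when
#'   the oracle works from the string/latent.
#' @param check_geometry Passed to the descriptor oracle.
#' @param seed Seed recorded in provenance.
#' @return A `latent_property_dataset`; attribute `n_unstable` counts
#'   excluded latents.
#' @export
reacquire <- function(latents, decoder, oracle,
                      embedder = c("none", "distance_geometry"),
                      check_geometry = TRUE, seed = 1L) {
  embedder <- match.arg(embedder)
  stopifnot(is.matrix(latents))
  N <- nrow(latents)

  if (identical(decoder, "identity")) {
    stopifnot(is.function(oracle))
    res <- lapply(seq_len(N), function(i) oracle(latents[i, ]))
    ok <- vapply(res, function(r) r$status == "ok", logical(1))
    if (!any(ok)) stop("all latents unstable under the oracle")
    P <- do.call(rbind, lapply(res[ok], function(r) as.numeric(r$properties)))
    nm <- names(res[which(ok)[1]][[1]]$properties)
    un <- attr(res[which(ok)[1]][[1]]$properties, "units")
    prov <- data.frame(index = which(ok), selfies = NA_character_,
                       status = "ok", seed = seed)
    ds <- new_latent_property_dataset(latents[ok, , drop = FALSE], P, prov, nm, un)
    attr(ds, "n_unstable") <- sum(!ok)
    return(ds)
  }

  stopifnot(inherits(decoder, "sgp_vae"),
            ncol(latents) == decoder$config$latent_dim)
  selfies <- greedy_selfies(decoder, latents)
  if (identical(oracle, "descriptors")) {
    r <- descriptor_oracle_batch(selfies, check_geometry = check_geometry)
    ok <- r$status == "ok"
    if (!any(ok)) stop("all decoded molecules unstable under the oracle")
    P <- r$values[ok, , drop = FALSE]
    nm <- colnames(P); un <- unname(DESCRIPTOR_UNITS[nm])
  } else {
    stopifnot(is.function(oracle))
    res <- vector("list", N)
    for (i in seq_len(N)) {
      x <- if (embedder == "distance_geometry") {
        emb <- embed_conformer(selfies[i], seed = seed)
        if (emb$status != "ok") NULL else emb$graph
      } else selfies[i]
      res[[i]] <- if (is.null(x))
        oracle_result("unstable", reason = "embedding_failed") else oracle(x)
    }
    ok <- vapply(res, function(r) r$status == "ok", logical(1))
    if (!any(ok)) stop("all decoded molecules unstable under the oracle")
    P <- do.call(rbind, lapply(res[ok], function(r) as.numeric(r$properties)))
    first <- res[[which(ok)[1]]]$properties
    nm <- names(first); un <- attr(first, "units")
  }
  prov <- data.frame(index = which(ok), selfies = selfies[ok],
                     status = "ok", seed = seed)
  ds <- new_latent_property_dataset(latents[ok, , drop = FALSE], P, prov, nm, un)
  attr(ds, "n_unstable") <- sum(!ok)
  ds
}

#' Legacy surrogate training pairs from encoded dataset molecules
#'
#' The conventional construction the reacquisition method replaces: pair
#' each training molecule's posterior-mean latent with its ground-truth
#' property. Kept as the ablation baseline; pairs are flagged `legacy` in
#' provenance.
#'
#' @param dataset A labelled dataset (`records` + `properties`).
#' @param model A trained `sgp_vae` encoder.
#' @return A `latent_property_dataset` of size `nrow(properties)`.
#' @export
legacy_encode_dataset <- function(dataset, model) {
  records <- dataset$records
  ids <- t(vapply(records, function(r) tokenize(r$selfies, model$vocab),
                  integer(model$vocab$max_length)))
  graphs <- lapply(records, `[[`, "graph")
  post <- encode(model, ids, graphs)
  P <- as.matrix(dataset$properties)
  prov <- data.frame(index = seq_len(nrow(P)),
                     selfies = vapply(records, `[[`, "", "selfies"),
                     status = "legacy", seed = NA_integer_)
  new_latent_property_dataset(post$mean, P, prov,
                              colnames(P), dataset$units)
}

#' Save / load a latent-property dataset as a plain-text directory
#'
#' Writes `latents.csv`, `properties.csv`, `provenance.jsonl` and a
#' `manifest.json` recording property names/units, standardization
#' statistics and oracle identity.
#'
#' @param dataset A `latent_property_dataset`.
#' @param dir Directory path (created if needed).
#' @param oracle_name Free-text oracle identifier for the manifest.
#' @return Invisibly, `dir`.
#' @export
save_dataset <- function(dataset, dir, oracle_name = "unspecified") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(dataset$latents, file.path(dir, "latents.csv"),
                   row.names = FALSE)
  utils::write.csv(dataset$properties, file.path(dir, "properties.csv"),
                   row.names = FALSE)
  con <- file(file.path(dir, "provenance.jsonl"), "w")
  for (i in seq_len(nrow(dataset$provenance)))
    writeLines(jsonlite::toJSON(dataset$provenance[i, ], auto_unbox = TRUE,
                                na = "null"), con)
  close(con)
  manifest <- list(
    n_pairs = nrow(dataset$latents), latent_dim = ncol(dataset$latents),
    property_names = dataset$property_names,
    property_units = dataset$property_units,
    standardization = dataset$stats, oracle = oracle_name,
    n_unstable = attr(dataset, "n_unstable")
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(dir) {
  Z <- as.matrix(utils::read.csv(file.path(dir, "latents.csv")))
  P <- as.matrix(utils::read.csv(file.path(dir, "properties.csv")))
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  prov_lines <- readLines(file.path(dir, "provenance.jsonl"))
  prov <- do.call(rbind, lapply(prov_lines, function(l)
    as.data.frame(jsonlite::fromJSON(l))))
  ds <- new_latent_property_dataset(
    Z, P, prov, man$property_names, man$property_units,
    stats = list(mean = stats::setNames(as.numeric(man$standardization$mean),
                                        man$property_names),
                 sd = stats::setNames(as.numeric(man$standardization$sd),
                                      man$property_names))
  )
  attr(ds, "n_unstable") <- man$n_unstable
  ds
}
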
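#' Desk-scale synthetic inputs
#'
#' Everything in the pipeline is testable without downloads: random valid
#' molecular strings stand in for a quantum-chemistry training corpus,
#' the descriptor oracle stands in for a physics forward process, and the
#' analytic closed-loop harness lets the reacquisition / surrogate /
#' design machinery be verified exactly.
#'
#' @param n_molecules Corpus size (default 200).
#' @param max_tokens Maximum symbols per molecule (default 16; lengths
#'   are uniform on 3..max_tokens).
#' @param alphabet Symbol alphabet (default [selfies_alphabet()]).
#' @param seed Integer seed.
#' @param oracle_name Label recorded in manifests (default
#'   `"descriptors"`).
#' @return A `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 200L, max_tokens = 16L,
                         alphabet = selfies_alphabet(), seed = 7L,
                         oracle_name = "descriptors") {
  stopifnot(n_molecules >= 1, length(alphabet) > 0,
            all(alphabet %in% selfies_alphabet()))
  structure(list(
    n_molecules = as.integer(n_molecules), max_tokens = as.integer(max_tokens),
    alphabet = alphabet, seed = as.integer(seed), oracle_name = oracle_name
  ), class = "fixture_spec")
}

# one random symbol sequence; atom symbols are favored 3:1 over
# structural symbols so that typical draws are molecule-like rather than
# degenerate
random_selfies <- function(max_tokens, alphabet) {
  len <- sample(3:max_tokens, 1L)
  atomic <- vapply(alphabet, function(s) !is.null(parse_atom_symbol(s)),
                   logical(1))
  w <- ifelse(atomic, 3, 1)
  paste(sample(alphabet, len, replace = TRUE, prob = w), collapse = "")
}

#' Generate a deduplicated corpus of random valid molecules
#'
#' Draws random symbol sequences over the alphabet — each decodes to a
#' valid molecule by the derivation guarantee — and deduplicates them by
#' canonical structure id, retrying up to `retry_rounds` oversampled
#' rounds. Returns fewer than requested (with a warning) only if the
#' alphabet cannot supply enough distinct structures.
#'
#' @param spec A [fixture_spec()].
#' @param embed Logical: embed 3D conformers for each record (one batched
#'   call; molecules that fail embedding keep `graph = NULL`).
#' @param retry_rounds Oversampling rounds for deduplication (default 6).
#' @return List of `molecule_record`s.
#' @export
generate_selfies_corpus <- function(spec, embed = FALSE, retry_rounds = 6L) {
  stopifnot(inherits(spec, "fixture_spec"))
  chosen <- character(0); chosen_ids <- character(0)
  with_seed(spec$seed, {
    for (round in seq_len(retry_rounds)) {
      need <- spec$n_molecules - length(chosen)
      if (need <= 0) break
      cand <- vapply(seq_len(2L * need),
                     function(i) random_selfies(spec$max_tokens, spec$alphabet),
                     character(1))
      smiles <- vapply(cand, selfies_to_smiles, character(1), USE.NAMES = FALSE)
      ids <- ob_canonical(smiles)
      keep <- !is.na(ids) & !duplicated(ids) & !(ids %in% chosen_ids)
      take <- utils::head(which(keep), need)
      chosen <- c(chosen, cand[take])
      chosen_ids <- c(chosen_ids, ids[take])
    }
  })
  if (length(chosen) < spec$n_molecules)
    warning("only ", length(chosen), " distinct structures reachable (",
            spec$n_molecules, " requested)")
  graphs <- if (embed) embed3d_batch(chosen, seed = spec$seed) else NULL
  lapply(seq_along(chosen), function(i) {
    g <- NULL
    if (!is.null(graphs) && !is.null(graphs[[i]]))
      g <- structure(list(atom_types = graphs[[i]]$element,
                          coords = graphs[[i]]$coords,
                          n_atoms = length(graphs[[i]]$element),
                          seed = spec$seed),
                     class = "molecule_graph")
    structure(list(selfies = chosen[i],
                   smiles = selfies_to_smiles(chosen[i]),
                   canonical_id = chosen_ids[i],
                   tokens = NULL, graph = g),
              class = "molecule_record")
  })
}

#' Label a corpus with a forward oracle
#'
#' Unstable molecules are dropped and counted; standardization statistics
#' of the retained natural-unit labels are stored with the dataset.
#'
#' @param corpus List of `molecule_record`s.
#' @param oracle `"descriptors"` for the batched descriptor oracle, or a
#'   function `record -> oracle_result`.
#' @param check_geometry Passed to the descriptor oracle (default FALSE:
#'   corpus labelling needs no conformer round-trip).
#' @return A `labelled_dataset`: list with `records`, `properties`
#'   (matrix), `names`, `units`, `stats`, `n_unstable`.
#' @export
build_labelled_dataset <- function(corpus, oracle = "descriptors",
                                   check_geometry = FALSE) {
  stopifnot(length(corpus) > 0)
  if (identical(oracle, "descriptors")) {
    selfies <- vapply(corpus, `[[`, "", "selfies")
    r <- descriptor_oracle_batch(selfies, check_geometry = check_geometry)
    ok <- r$status == "ok"
    P <- r$values[ok, , drop = FALSE]
    nm <- colnames(P); un <- unname(DESCRIPTOR_UNITS[nm])
  } else {
    stopifnot(is.function(oracle))
    res <- lapply(corpus, oracle)
    ok <- vapply(res, function(x) x$status == "ok", logical(1))
    if (!any(ok)) stop("all molecules unstable under the oracle")
    P <- do.call(rbind, lapply(res[ok], function(x) as.numeric(x$properties)))
    first <- res[[which(ok)[1]]]$properties
    nm <- names(first); un <- attr(first, "units")
    colnames(P) <- nm
  }
  if (!any(ok)) stop("all molecules unstable under the oracle")
  structure(list(
    records = corpus[ok], properties = P, names = nm, units = un,
    stats = standardize_stats(P), n_unstable = sum(!ok)
  ), class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat("<labelled_dataset> ", length(x$records), " molecules, properties: ",
      paste(x$names, collapse = ", "),
      " (", x$n_unstable, " unstable dropped)\n", sep = "")
  invisible(x)
}

#' Analytic closed-loop harness
#'
#' Builds the exact test bed for the surrogate/design machinery: training
#' latents confined to a bounded box, a linear oracle `p = A z + b`, and
#' target values partitioned into achievable-in-region and
#' outside-the-region. No molecular decoding is involved — the "molecule"
#' is its latent — so parameter recovery and uncertainty extrapolation
#' can be verified against least squares.
#'
#' @param d Latent dimension (default 16).
#' @param n_train Number of training latents (default 2000).
#' @param region Half-width r of the training box `[-r, r]^d`
#'   (default 1).
#' @param A Oracle coefficient matrix (k x d); default: one random
#'   unit-norm row (scalar property).
#' @param b Oracle offset (default 0 per property).
#' @param n_targets Targets per partition (default 20).
#' @param in_frac In-range targets span `b +/- in_frac * S` where
#'   `S = max |A z| over the box` (default 0.6).
#' @param out_range Out-of-range targets span `b + (out_range[1]..out_range[2]) * S`
#'   (default c(1.05, 1.4)).
#' @param seed Integer seed.
#' @return List with `dataset` (a `latent_property_dataset`), `A`, `b`,
#'   `region`, `oracle` (contract function on latents), `targets_in`,
#'   `targets_out`, `S` (per-property box amplitude).
#' @export
closed_loop_harness <- function(d = 16L, n_train = 2000L, region = 1,
                                A = NULL, b = NULL, n_targets = 20L,
                                in_frac = 0.6, out_range = c(1.05, 1.4),
                                seed = 1L) {
  if (is.null(A)) {
    A <- with_seed(derive_seed(seed, 1, 17), matrix(stats::rnorm(d), 1, d))
    A <- A / sqrt(sum(A^2))
  }
  A <- as.matrix(A)
  k <- nrow(A)
  if (is.null(b)) b <- rep(0, k)
  Z <- with_seed(seed, matrix(stats::runif(n_train * d, -region, region),
                              n_train, d))
  P <- analytic_oracle(Z, A, b)
  nm <- paste0("p", seq_len(k))
  prov <- data.frame(index = seq_len(n_train), selfies = NA_character_,
                     status = "ok", seed = seed)
  ds <- new_latent_property_dataset(Z, P, prov, nm, rep("", k))
  S <- as.numeric(abs(A) %*% rep(region, d)) # max |A z| over the box
  targets_in <- lapply(seq_len(k), function(j)
    target_grid(b[j] - in_frac * S[j], b[j] + in_frac * S[j], n_targets))
  targets_out <- lapply(seq_len(k), function(j)
    target_grid(b[j] + out_range[1] * S[j], b[j] + out_range[2] * S[j],
                n_targets))
  names(targets_in) <- names(targets_out) <- nm
  list(dataset = ds, A = A, b = b, region = region,
       oracle = make_analytic_oracle(A, b),
       targets_in = targets_in, targets_out = targets_out, S = S)
}
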
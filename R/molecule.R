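#' Molecule records: linked string / token / 3D-graph views
#'
#' A `molecule_record` carries the three linked views the encoder consumes:
#' the molecular string, its fixed-length token sequence, and (optionally)
#' a 3D heavy-atom graph from conformer embedding. The `canonical_id` is
#' the OpenBabel canonical SMILES and is the identity used by the novelty
#' and uniqueness metrics.
#'
#' @param selfies Molecular string.
#' @param vocab A [build_vocabulary()] result (or NULL to skip tokens).
#' @param embed Logical; embed a 3D conformer (default FALSE).
#' @param seed Integer seed recorded with the embedding.
#' @return A `molecule_record`: list with `selfies`, `smiles`,
#'   `canonical_id`, `tokens` (or NULL), `graph` (a `molecule_graph` or
#'   NULL when embedding failed or was not requested).
#' @export
#' @examples
#' \donttest{
#' r <- molecule_record("[C][C][O]")
#' r$canonical_id
#' }
molecule_record <- function(selfies, vocab = NULL, embed = FALSE, seed = 1L) {
  smiles <- selfies_to_smiles(selfies)
  cid <- ob_canonical(smiles)
  if (is.na(cid)) stop("canonicalization failed for: ", smiles)
  tokens <- if (!is.null(vocab)) tokenize(selfies, vocab) else NULL
  graph <- NULL
  if (embed) {
    emb <- embed_conformer(selfies, seed = seed)
    if (emb$status == "ok") graph <- emb$graph
  }
  structure(
    list(selfies = selfies, smiles = smiles, canonical_id = cid,
         tokens = tokens, graph = graph),
    class = "molecule_record"
  )
}

#' @export
print.molecule_record <- function(x, ...) {
  cat("<molecule_record> ", x$selfies, " (", x$canonical_id, ")",
      if (!is.null(x$graph)) " +3D" else "", "\n", sep = "")
  invisible(x)
}

#' Canonical structure identity of a molecular string
#'
#' Two strings encoding the same structure map to the same id (OpenBabel
#' canonical SMILES), which is what the novelty/uniqueness metrics compare.
#'
#' @param selfies Molecular string, vectorized.
#' @return Character vector of canonical ids.
#' @export
canonical_id <- function(selfies) {
  smiles <- vapply(selfies, selfies_to_smiles, character(1), USE.NAMES = FALSE)
  ids <- ob_canonical(smiles)
  if (anyNA(ids))
    stop("canonicalization failed for: ",
         paste(smiles[is.na(ids)], collapse = ", "))
  ids
}

#' Embed a 3D conformer for a molecular string
#'
#' Seeded distance-geometry embedding with gradient relaxation (see
#' [embed_topology()]): deterministic given the seed. Failure is a
#' first-class outcome — callers count it as instability rather than an
#' error — so the result carries a status.
#'
#' @param selfies Molecular string.
#' @param seed Integer seed for the embedding's random start.
#' @return List with `status` (`"ok"` or `"failed"`), `graph` (a
#'   `molecule_graph` with `atom_types`, `coords` in Angstrom, `n_atoms`;
#'   heavy atoms only) and `reason` when failed.
#' @export
embed_conformer <- function(selfies, seed = 1L) {
  topo <- tryCatch(decode_selfies(selfies), error = function(e) NULL)
  if (is.null(topo))
    return(list(status = "failed", graph = NULL, reason = "uninterpretable"))
  X <- embed_topology(topo, seed = seed)
  if (is.null(X))
    return(list(status = "failed", graph = NULL, reason = "embedding_failed"))
  graph <- structure(
    list(atom_types = topo$element, coords = X,
         n_atoms = topo$n_atoms, seed = as.integer(seed)),
    class = "molecule_graph"
  )
  list(status = "ok", graph = graph, reason = NULL)
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("<molecule_graph> ", x$n_atoms, " heavy atoms (",
      paste(x$atom_types, collapse = ""), ")\n", sep = "")
  invisible(x)
}

#' Perturb one view of a molecule record
#'
#' Small perturbations of the kind used in the representation-robustness
#' study: Gaussian coordinate noise on one randomly chosen atom, a random
#' atom-type swap, or a random symbol swap in the molecular string. A
#' perturbation that yields an uninterpretable structure is a `"failed"`
#' outcome (counted as unstable downstream), not an error.
#'
#' @param record A `molecule_record` (with `graph` for the two graph modes).
#' @param mode One of `"coord_noise"`, `"atom_type_swap"`, `"selfies_swap"`.
#' @param sigma Noise scale in Angstrom for `coord_noise` (default 0.1).
#' @param seed Integer seed; the choice of atom/symbol is reproducible.
#' @return List with `status`, and on success the perturbed view:
#'   `graph` (graph modes) or `selfies` (string mode).
#' @export
perturb <- function(record, mode = c("coord_noise", "atom_type_swap", "selfies_swap"),
                    sigma = 0.1, seed = 1L) {
  mode <- match.arg(mode)
  if (mode %in% c("coord_noise", "atom_type_swap")) {
    if (is.null(record$graph))
      stop("record has no 3D graph; embed a conformer first")
    g <- record$graph
    if (mode == "coord_noise") {
      g$coords <- with_seed(seed, {
        k <- sample.int(g$n_atoms, 1L)
        g$coords[k, ] <- g$coords[k, ] + stats::rnorm(3, 0, sigma)
        g$coords
      })
      return(list(status = "ok", graph = g))
    }
    alphabet <- names(ELEMENT_VALENCE)
    g$atom_types <- with_seed(seed, {
      k <- sample.int(g$n_atoms, 1L)
      g$atom_types[k] <- sample(setdiff(alphabet, g$atom_types[k]), 1L)
      g$atom_types
    })
    return(list(status = "ok", graph = g))
  }
  # selfies_swap: replace one randomly chosen symbol with a different
  # alphabet symbol; the result is decodable by the robustness guarantee
  syms <- split_symbols(record$selfies)
  syms <- with_seed(seed, {
    k <- sample.int(length(syms), 1L)
    syms[k] <- sample(setdiff(selfies_alphabet(), syms[k]), 1L)
    syms
  })
  list(status = "ok", selfies = paste(syms, collapse = ""))
}

#' Read molecules from a plain-text file
#'
#' Accepts `.selfies`/`.smi` one-molecule-per-line files (SMILES are
#' converted into the constrained string representation) and CSV files
#' with a `molecule` column plus numeric property columns.
#'
#' @param path File path.
#' @return For line files, a character vector of molecular strings with a
#'   `rejected` attribute (data.frame of unparseable lines and reasons);
#'   for CSV, a list with `molecules` and `properties` (data.frame).
#' @export
read_molecules <- function(path) {
  ext <- tolower(tools::file_ext(path))
  to_selfies <- function(x) {
    if (grepl("^\\[", x)) return(x)
    topology_to_selfies(smiles_to_topology(x))
  }
  if (ext == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"molecule" %in% names(tab)) stop("CSV must have a 'molecule' column")
    mols <- vapply(tab$molecule, function(x) {
      tryCatch(to_selfies(x), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    keep <- !is.na(mols)
    props <- tab[keep, setdiff(names(tab), "molecule"), drop = FALSE]
    return(list(molecules = mols[keep], properties = props,
                n_rejected = sum(!keep)))
  }
  lines <- readLines(path)
  lines <- trimws(sub("\\s.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- character(0); rej <- character(0); why <- character(0)
  for (x in lines) {
    s <- tryCatch(to_selfies(x), error = function(e) conditionMessage(e))
    if (grepl("^\\[", s)) out <- c(out, s)
    else { rej <- c(rej, x); why <- c(why, s) }
  }
  attr(out, "rejected") <- data.frame(molecule = rej, reason = why)
  out
}

#' Write embedded conformers to an SDF file
#'
#' @param records List of `molecule_record`s with graphs.
#' @param path Output SDF path.
#' @return Invisibly, the number of conformers written.
#' @export
write_conformers_sdf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- 0L
  for (r in records) {
    if (is.null(r$graph)) next
    g <- r$graph
    writeLines(c(
      r$canonical_id, "  uncertmol", "",
      sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", g$n_atoms, 0L),
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              g$coords[, 1], g$coords[, 2], g$coords[, 3], g$atom_types),
      "M  END", "$$$$"
    ), con)
    n <- n + 1L
  }
  invisible(n)
}

# derive a child seed from (seed, multiplier, offset) without integer
# overflow; result is always a valid 32-bit seed
derive_seed <- function(seed, mult, add) {
  as.integer((as.numeric(seed) * mult + add) %% 2147483647)
}

# run code under a temporary RNG state; global .Random.seed is restored
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}
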
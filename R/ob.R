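# Thin, batched wrappers around ChemmineOB (OpenBabel). All cheminformatics
# plumbing — canonical identity, descriptors, 3D embedding, bond
# re-perception from geometry — funnels through here so the rest of the
# package never touches OB directly.

ob_convert <- function(from, to, text, gen3d = FALSE) {
  if (gen3d)
    ChemmineOB::convertFormat(from, to, source = text,
                              options = data.frame(names = "gen3d", args = ""))
  else
    ChemmineOB::convertFormat(from, to, source = text)
}

# Canonical SMILES for a vector of SMILES; NA where OB fails to parse.
# One OB call for the whole batch; identity tracked via molecule titles.
ob_canonical <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  ids <- paste0("m", seq_along(smiles))
  inp <- paste0(smiles, " ", ids, "\n", collapse = "")
  out <- tryCatch(ob_convert("SMI", "CAN", inp), error = function(e) "")
  res <- rep(NA_character_, length(smiles))
  if (nzchar(out)) {
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\t", fixed = TRUE)
    for (p in parts) {
      if (length(p) >= 2) {
        k <- match(p[2], ids)
        if (!is.na(k)) res[k] <- p[1]
      }
    }
  }
  res
}

# MW / logP / TPSA for a vector of SMILES via OB descriptors.
# Returns a matrix (length(smiles) x 3) with NA rows on failure.
ob_descriptors <- function(smiles) {
  res <- matrix(NA_real_, nrow = length(smiles), ncol = 3,
                dimnames = list(NULL, c("mw", "logp", "tpsa")))
  if (length(smiles) == 0) return(res)
  ids <- paste0("m", seq_along(smiles))
  inp <- paste0(smiles, " ", ids, "\n", collapse = "")
  tab <- tryCatch(
    ChemmineOB::forEachMol("SMI", inp, ChemmineOB::prop_OB, reduce = rbind),
    error = function(e) NULL
  )
  if (!is.null(tab) && nrow(tab) > 0) {
    k <- match(tab$title, ids)
    keep <- !is.na(k)
    res[k[keep], "mw"] <- tab$MW[keep]
    res[k[keep], "logp"] <- tab$logP[keep]
    res[k[keep], "tpsa"] <- tab$TPSA[keep]
  }
  res
}

# Parse the atom/bond block of a single V2000 SDF entry.
# Returns list(element, coords, bonds, charged) or NULL on failure.
parse_sdf_block <- function(block_lines) {
  if (length(block_lines) < 4) return(NULL)
  counts <- block_lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || na < 1) return(NULL)
  if (length(block_lines) < 4 + na + nb) return(NULL)
  atoms <- block_lines[5:(4 + na)]
  x <- as.numeric(substr(atoms, 1, 10))
  y <- as.numeric(substr(atoms, 11, 20))
  z <- as.numeric(substr(atoms, 21, 30))
  el <- trimws(substr(atoms, 32, 34))
  bonds <- if (nb > 0) {
    bl <- block_lines[(5 + na):(4 + na + nb)]
    data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else data.frame(i = integer(0), j = integer(0), order = integer(0))
  charged <- any(grepl("^M  CHG", block_lines))
  list(element = el, coords = cbind(x = x, y = y, z = z),
       bonds = bonds, charged = charged)
}

# SMILES -> molecule_topology through OB's SDF writer (heavy atoms only).
# Errors when the structure falls outside the constrained representation:
# unsupported elements, formal charges, exceeded valence, aromatic bond
# records, or multiple fragments.
smiles_to_topology <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  if (grepl(".", smiles, fixed = TRUE))
    stop("multi-fragment structure is not interpretable: ", smiles)
  sdf <- tryCatch(ob_convert("SMI", "SDF", paste0(smiles, "\n")),
                  error = function(e) "")
  if (!nzchar(sdf)) stop("structure could not be parsed: ", smiles)
  blk <- parse_sdf_block(strsplit(sdf, "\n", fixed = TRUE)[[1]])
  if (is.null(blk)) stop("structure could not be parsed: ", smiles)
  if (blk$charged) stop("charged species are not interpretable: ", smiles)
  keep <- blk$element != "H"
  if (!any(keep)) stop("no heavy atoms in: ", smiles)
  idx <- cumsum(keep)
  bonds <- blk$bonds[keep[blk$bonds$i] & keep[blk$bonds$j], , drop = FALSE]
  bonds$i <- idx[bonds$i]; bonds$j <- idx[bonds$j]
  if (any(bonds$order > 3))
    stop("aromatic/unknown bond orders are not interpretable: ", smiles)
  topo <- structure(
    list(element = blk$element[keep], bonds = bonds, n_atoms = sum(keep)),
    class = "molecule_topology"
  )
  # valence/element checks happen here; errors propagate to the caller
  invisible(topology_to_selfies(topo))
  topo
}

# Re-perceive connectivity from raw geometry: each (element, coords) entry
# becomes a molecule_topology with atoms in the input order (bonds and
# orders as OB infers them from interatomic distances and angles), or NULL
# on failure. This mirrors handing bare coordinates to a physics engine,
# which sees geometry, not the intended bond graph.
ob_perceive_topology_batch <- function(geoms) {
  res <- vector("list", length(geoms))
  if (length(geoms) == 0) return(res)
  live <- which(!vapply(geoms, is.null, logical(1)))
  if (length(live) == 0) return(res)
  chunks <- vapply(live, function(k) {
    g <- geoms[[k]]
    paste0(
      nrow(g$coords), "\n", "m", k, "\n",
      paste(sprintf("%s %.6f %.6f %.6f", g$element,
                    g$coords[, 1], g$coords[, 2], g$coords[, 3]),
            collapse = "\n"), "\n"
    )
  }, character(1))
  out <- tryCatch(ob_convert("XYZ", "SDF", paste(chunks, collapse = "")),
                  error = function(e) "")
  if (!nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  ends <- which(lines == "$$$$")
  ids <- paste0("m", seq_along(geoms))
  start <- 1L
  for (e in ends) {
    block <- lines[start:(e - 1L)]
    start <- e + 1L
    if (length(block) < 4) next
    k <- match(trimws(block[1]), ids)
    if (is.na(k)) next
    blk <- parse_sdf_block(block)
    if (is.null(blk) || blk$charged) next
    if (any(blk$bonds$order > 3)) next
    res[[k]] <- structure(
      list(element = blk$element, bonds = blk$bonds,
           n_atoms = length(blk$element)),
      class = "molecule_topology"
    )
  }
  res
}

# canonical id of a perceived topology, through the constrained
# representation's interpretability gate; NA when uninterpretable
perceived_canonical <- function(topos) {
  smi <- vapply(topos, function(tp) {
    if (is.null(tp)) return(NA_character_)
    tryCatch({ invisible(topology_to_selfies(tp)); topology_to_smiles(tp) },
             error = function(e) NA_character_)
  }, character(1))
  res <- rep(NA_character_, length(topos))
  live <- which(!is.na(smi))
  if (length(live) > 0) res[live] <- ob_canonical(smi[live])
  res
}
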
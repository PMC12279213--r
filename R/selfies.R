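#' @title Robust molecular string representation
#'
#' @description
#' `uncertmol` uses a constrained, SELFIES-style molecular string
#' representation over the QM9 element set (C, N, O, F). The defining
#' guarantee, which the whole design pipeline relies on, is *robustness*:
#' every sequence of alphabet symbols derives to a valence-correct,
#' single-fragment molecule. Symbols that cannot be applied in the current
#' derivation state (a ring with no partner, a branch on a saturated atom,
#' a bond exceeding remaining valence) are skipped or clipped rather than
#' raising an error, exactly so that a generative decoder can emit any
#' symbol sequence and still obtain a valid molecule.
#'
#' The alphabet consists of atom symbols with an optional bond-order prefix
#' (`[C]`, `[=C]`, `[#C]`, `[N]`, `[=N]`, `[#N]`, `[O]`, `[=O]`, `[F]`),
#' a branch opener `[Branch1]` and ring closures `[Ring1]`, `[=Ring1]`.
#' `[Branch1]` and `[Ring1]` consume the *next* symbol as an overloaded
#' numeric index (the symbol's position in the canonical alphabet): the
#' branch length in symbols, or how many atoms back the ring partner lies.
#'
#' @name selfies-representation
NULL

# canonical alphabet order; a symbol's 0-based position here is its value
# when it is read as an overloaded index after [Branch1]/[Ring1]
SELFIES_SYMBOLS <- c(
  "[C]", "[=C]", "[#C]", "[N]", "[=N]", "[#N]", "[O]", "[=O]", "[F]",
  "[Branch1]", "[Ring1]", "[=Ring1]"
)

ELEMENT_VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L)

ELEMENT_MASS <- c(C = 12.011, N = 14.007, O = 15.999, F = 18.998, H = 1.008)

#' Canonical symbol alphabet of the molecular string representation
#'
#' @return Character vector of all symbols, in canonical (index) order.
#' @export
#' @examples
#' selfies_alphabet()
selfies_alphabet <- function() SELFIES_SYMBOLS

# split a string like "[C][=O]" into its bracketed symbols
split_symbols <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1L)
  if (!nzchar(selfies)) return(character(0))
  m <- gregexpr("\\[[^][]*\\]", selfies)[[1]]
  syms <- regmatches(selfies, gregexpr("\\[[^][]*\\]", selfies))[[1]]
  if (sum(attr(m, "match.length")) != nchar(selfies))
    stop("malformed molecular string (characters outside [...] symbols): ", selfies)
  syms
}

symbol_index <- function(symbol) {
  i <- match(symbol, SELFIES_SYMBOLS)
  if (is.na(i)) 0L else i - 1L
}

# parse an atom symbol like "[=N]" -> list(element, order); NULL if not atomic
parse_atom_symbol <- function(symbol) {
  body <- sub("^\\[", "", sub("\\]$", "", symbol))
  order <- 1L
  if (startsWith(body, "=")) { order <- 2L; body <- substring(body, 2) }
  else if (startsWith(body, "#")) { order <- 3L; body <- substring(body, 2) }
  if (body %in% names(ELEMENT_VALENCE)) list(element = body, order = order) else NULL
}

# Derivation state: grown by reference inside one decode call.
new_graph_state <- function() {
  st <- new.env(parent = emptyenv())
  st$element <- character(0)
  st$free <- integer(0)
  st$bond_i <- integer(0)
  st$bond_j <- integer(0)
  st$bond_order <- integer(0)
  st
}

add_atom <- function(st, element) {
  st$element <- c(st$element, element)
  st$free <- c(st$free, ELEMENT_VALENCE[[element]])
  length(st$element)
}

add_bond <- function(st, i, j, order) {
  st$bond_i <- c(st$bond_i, i)
  st$bond_j <- c(st$bond_j, j)
  st$bond_order <- c(st$bond_order, order)
  st$free[i] <- st$free[i] - order
  st$free[j] <- st$free[j] - order
}

has_bond <- function(st, i, j) {
  any((st$bond_i == i & st$bond_j == j) | (st$bond_i == j & st$bond_j == i))
}

# Core derivation. `attach` is the atom the fragment grows from (0 = none).
# Unusable symbols are skipped; chain growth stops when the current atom is
# saturated. Returns nothing; mutates st.
derive_symbols <- function(symbols, st, attach) {
  cur <- attach
  i <- 1L
  n <- length(symbols)
  while (i <= n) {
    sym <- symbols[[i]]
    atom <- parse_atom_symbol(sym)
    if (!is.null(atom)) {
      if (cur == 0L) {
        cur <- add_atom(st, atom$element)
      } else {
        if (st$free[cur] == 0L) break # saturated: chain derivation ends
        ord <- min(atom$order, st$free[cur], ELEMENT_VALENCE[[atom$element]])
        j <- add_atom(st, atom$element)
        add_bond(st, cur, j, ord)
        cur <- j
      }
      i <- i + 1L
    } else if (sym == "[Branch1]") {
      if (i == n) break
      len <- symbol_index(symbols[[i + 1L]]) + 1L
      branch <- symbols[seq.int(i + 2L, length.out = min(len, n - i - 1L))]
      # a branch needs one valence for itself and one for chain continuation
      if (cur != 0L && st$free[cur] >= 2L && length(branch) > 0L)
        derive_symbols(branch, st, cur)
      i <- i + 2L + len
    } else if (sym %in% c("[Ring1]", "[=Ring1]")) {
      if (i == n) break
      q <- symbol_index(symbols[[i + 1L]])
      if (cur != 0L) {
        tgt <- cur - (q + 1L)
        want <- if (sym == "[=Ring1]") 2L else 1L
        if (tgt >= 1L && tgt != cur && !has_bond(st, cur, tgt)) {
          ord <- min(want, st$free[cur], st$free[tgt])
          if (ord >= 1L) add_bond(st, cur, tgt, ord)
        }
      }
      i <- i + 2L
    } else {
      i <- i + 1L # unknown symbol: robustly ignored
    }
  }
}

#' Derive the molecular graph encoded by a molecular string
#'
#' Every symbol sequence derives to a valid molecule: inapplicable symbols
#' are skipped and bond orders are clipped to the valence still available.
#' A sequence that derives no atom at all (e.g. only ring symbols)
#' completes to methane, the minimal molecule, so the robustness guarantee
#' holds unconditionally.
#'
#' @param selfies A molecular string such as `"[C][=O]"`, or a character
#'   vector of its symbols.
#' @return A `molecule_topology`: list with `element` (character vector),
#'   `bonds` (data.frame `i`, `j`, `order`) and `n_atoms`. Hydrogens are
#'   implicit.
#' @export
#' @examples
#' decode_selfies("[C][=O]")     # formaldehyde skeleton
#' decode_selfies("[Ring1][C]")  # nothing derivable -> methane
decode_selfies <- function(selfies) {
  symbols <- if (length(selfies) == 1L) split_symbols(selfies) else as.character(selfies)
  st <- new_graph_state()
  derive_symbols(symbols, st, 0L)
  if (length(st$element) == 0L) add_atom(st, "C")
  structure(
    list(
      element = st$element,
      bonds = data.frame(i = st$bond_i, j = st$bond_j, order = st$bond_order),
      n_atoms = length(st$element)
    ),
    class = "molecule_topology"
  )
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat("<molecule_topology> ", x$n_atoms, " heavy atoms (",
      paste(x$element, collapse = ""), "), ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# adjacency list: per atom, data.frame(nbr, order)
topology_adjacency <- function(topo) {
  adj <- vector("list", topo$n_atoms)
  for (k in seq_len(nrow(topo$bonds))) {
    i <- topo$bonds$i[k]; j <- topo$bonds$j[k]; o <- topo$bonds$order[k]
    adj[[i]] <- rbind(adj[[i]], c(j, o))
    adj[[j]] <- rbind(adj[[j]], c(i, o))
  }
  adj
}

bond_symbol <- function(order) c("", "=", "#")[order]

#' Write a molecular graph as a SMILES string
#'
#' Depth-first writer with ring-closure digits; hydrogens left implicit.
#' Because graphs coming out of [decode_selfies()] are valence-correct by
#' construction, the emitted SMILES is always chemically valid.
#'
#' @param topo A `molecule_topology` (see [decode_selfies()]).
#' @return A single SMILES string.
#' @export
topology_to_smiles <- function(topo) {
  stopifnot(inherits(topo, "molecule_topology"))
  n <- topo$n_atoms
  adj <- topology_adjacency(topo)
  visited <- rep(FALSE, n)
  ring_digit <- new.env(parent = emptyenv()) # "i_j" -> digit
  digit_counter <- 0L

  ring_key <- function(i, j) paste(sort(c(i, j)), collapse = "_")

  # first pass: find back edges via DFS
  back_edges <- list()
  dfs_order <- integer(0)
  walk <- function(u, parent) {
    visited[u] <<- TRUE
    dfs_order <<- c(dfs_order, u)
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]
        if (v == parent) next
        if (visited[v]) {
          k <- ring_key(u, v)
          if (is.null(ring_digit[[k]])) {
            digit_counter <<- digit_counter + 1L
            ring_digit[[k]] <- digit_counter
          }
        } else {
          walk(v, u)
        }
      }
    }
  }
  walk(1L, 0L)
  if (!all(visited)) stop("disconnected molecular graph cannot be written as one SMILES")

  emitted_ring <- new.env(parent = emptyenv())
  visited2 <- rep(FALSE, n)
  emit <- function(u, parent) {
    visited2[u] <<- TRUE
    s <- topo$element[u]
    kids <- integer(0); kid_ord <- integer(0)
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]; o <- adj[[u]][r, 2]
        if (v == parent) next
        k <- ring_key(u, v)
        if (!is.null(ring_digit[[k]])) {
          d <- ring_digit[[k]]
          dd <- if (d > 9) paste0("%", d) else as.character(d)
          s <- paste0(s, bond_symbol(o), dd)
          emitted_ring[[k]] <- TRUE
        } else if (!visited2[v]) {
          kids <- c(kids, v); kid_ord <- c(kid_ord, o)
        }
      }
    }
    if (length(kids) > 0) {
      for (idx in seq_along(kids)) {
        sub <- paste0(bond_symbol(kid_ord[idx]), emit(kids[idx], u))
        s <- if (idx < length(kids)) paste0(s, "(", sub, ")") else paste0(s, sub)
      }
    }
    s
  }
  emit(1L, 0L)
}

#' Convert a molecular string directly to SMILES
#'
#' @param selfies A molecular string.
#' @return A SMILES string; always valid, by the derivation guarantee.
#' @export
#' @examples
#' selfies_to_smiles("[C][C][O]") # "CCO"
selfies_to_smiles <- function(selfies) topology_to_smiles(decode_selfies(selfies))

# ---- encoding: molecular graph -> symbol string ------------------------

# Emit the symbol sequence for the DFS subtree rooted at u (u's own atom
# symbol first). `pos` maps atom -> DFS preorder position. Ring-closure
# symbols are emitted immediately after arriving at the later endpoint so
# that the decoder's "atoms derived so far" count matches the preorder.
encode_subtree <- function(u, parent, in_order, topo, adj, pos, tree, rings) {
  prefix <- c("", "=", "#")[in_order]
  out <- paste0("[", prefix, topo$element[u], "]")
  for (rr in rings[[u]]) {
    v <- rr[1]; o <- rr[2]
    q <- pos[u] - pos[v] - 1L
    if (q >= length(SELFIES_SYMBOLS))
      stop("ring span too wide to encode (offset ", q, ")")
    if (o > 2L) stop("triple-bond ring closures are not encodable")
    ring_sym <- if (o == 2L) "[=Ring1]" else "[Ring1]"
    out <- c(out, ring_sym, SELFIES_SYMBOLS[q + 1L])
  }
  kids <- tree[[u]]
  if (!is.null(kids) && nrow(kids) > 0) {
    for (r in seq_len(nrow(kids))) {
      sub <- encode_subtree(kids[r, 1], u, kids[r, 2], topo, adj, pos, tree, rings)
      if (r < nrow(kids)) {
        if (length(sub) > length(SELFIES_SYMBOLS))
          stop("branch too long to encode (", length(sub), " symbols)")
        out <- c(out, "[Branch1]", SELFIES_SYMBOLS[length(sub)], sub)
      } else {
        out <- c(out, sub)
      }
    }
  }
  out
}

#' Encode a molecular graph as a molecular string
#'
#' Inverse of [decode_selfies()] on interpretable graphs: the returned
#' string derives back to the same topology. Errors if the graph uses
#' elements outside C/N/O/F, violates valence, is disconnected, or needs
#' a branch/ring index beyond the alphabet's range.
#'
#' @param topo A `molecule_topology`.
#' @return A molecular string.
#' @export
topology_to_selfies <- function(topo) {
  stopifnot(inherits(topo, "molecule_topology"))
  bad <- setdiff(unique(topo$element), names(ELEMENT_VALENCE))
  if (length(bad) > 0)
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  # valence check
  used <- rep(0L, topo$n_atoms)
  for (k in seq_len(nrow(topo$bonds))) {
    used[topo$bonds$i[k]] <- used[topo$bonds$i[k]] + topo$bonds$order[k]
    used[topo$bonds$j[k]] <- used[topo$bonds$j[k]] + topo$bonds$order[k]
  }
  over <- which(used > ELEMENT_VALENCE[topo$element])
  if (length(over) > 0)
    stop("valence exceeded at atom(s): ", paste(over, collapse = ", "))

  adj <- topology_adjacency(topo)
  n <- topo$n_atoms
  pos <- integer(n); visited <- rep(FALSE, n); counter <- 0L
  tree <- vector("list", n)   # per atom: matrix (child, order) in visit order
  rings <- rep(list(list()), n) # per atom: back edges (partner, order)
  seen_edge <- new.env(parent = emptyenv())
  key <- function(i, j) paste(sort(c(i, j)), collapse = "_")
  walk <- function(u, parent) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    pos[u] <<- counter
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]; o <- adj[[u]][r, 2]
        k <- key(u, v)
        if (!is.null(seen_edge[[k]])) next
        if (visited[v]) {
          seen_edge[[k]] <- TRUE
          rings[[u]] <<- c(rings[[u]], list(c(v, o)))
        } else {
          seen_edge[[k]] <- TRUE
          tree[[u]] <<- rbind(tree[[u]], c(v, o))
          walk(v, u)
        }
      }
    }
  }
  walk(1L, 0L)
  if (!all(visited)) stop("disconnected molecular graph cannot be encoded")
  paste(encode_subtree(1L, 0L, 1L, topo, adj, pos, tree, rings), collapse = "")
}

#' Molecular mass of a molecular string (implicit hydrogens included)
#'
#' @param selfies A molecular string.
#' @return Molecular mass in Dalton.
#' @export
selfies_mass <- function(selfies) {
  topo <- decode_selfies(selfies)
  used <- rep(0L, topo$n_atoms)
  for (k in seq_len(nrow(topo$bonds))) {
    used[topo$bonds$i[k]] <- used[topo$bonds$i[k]] + topo$bonds$order[k]
    used[topo$bonds$j[k]] <- used[topo$bonds$j[k]] + topo$bonds$order[k]
  }
  n_h <- sum(ELEMENT_VALENCE[topo$element] - used)
  sum(ELEMENT_MASS[topo$element]) + n_h * ELEMENT_MASS[["H"]]
}
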
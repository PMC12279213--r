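# Seeded 3D conformer embedding: distance-geometry targets (ideal bond
# lengths by element pair and bond order, 1-3 distances from idealized
# hybridization angles, soft nonbonded repulsion) relaxed by gradient
# descent from a seeded random start. Deterministic by construction —
# the property the reacquisition pipeline needs from its conformer
# generator — with an explicit convergence criterion, so strained
# structures fail embedding rather than yielding nonsense geometry.

COVALENT_RADIUS <- c(C = 0.77, N = 0.75, O = 0.73, F = 0.71)
BOND_ORDER_SCALE <- c(1.0, 0.87, 0.78)

ideal_bond_length <- function(el_i, el_j, order) {
  (COVALENT_RADIUS[[el_i]] + COVALENT_RADIUS[[el_j]]) *
    BOND_ORDER_SCALE[order]
}

# idealized bond angle at a center atom from its bonding pattern
center_angle <- function(n_neighbors, max_order, sum_order) {
  if (max_order >= 3 || (n_neighbors == 2 && sum_order >= 4)) pi        # sp
  else if (max_order == 2 || n_neighbors == 3) 2 * pi / 3               # sp2
  else acos(-1 / 3)                                                     # sp3
}

# Build distance constraints for a topology.
# Returns list(pairs = matrix(i, j), target, weight, rep_pairs, rep_min)
embedding_constraints <- function(topo) {
  n <- topo$n_atoms
  bonds <- topo$bonds
  adj <- topology_adjacency(topo)
  pi_ <- numeric(0); pj <- numeric(0); tgt <- numeric(0); w <- numeric(0)
  if (nrow(bonds) > 0) {
    for (k in seq_len(nrow(bonds))) {
      pi_ <- c(pi_, bonds$i[k]); pj <- c(pj, bonds$j[k])
      tgt <- c(tgt, ideal_bond_length(topo$element[bonds$i[k]],
                                      topo$element[bonds$j[k]],
                                      bonds$order[k]))
      w <- c(w, 4)
    }
  }
  # 1-3 distances from the angle at the middle atom
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (is.null(nb) || nrow(nb) < 2) next
    theta <- center_angle(nrow(nb), max(nb[, 2]), sum(nb[, 2]))
    for (a in seq_len(nrow(nb) - 1)) {
      for (b in seq.int(a + 1, nrow(nb))) {
        i <- nb[a, 1]; k <- nb[b, 1]
        r_ij <- ideal_bond_length(topo$element[i], topo$element[j], nb[a, 2])
        r_jk <- ideal_bond_length(topo$element[j], topo$element[k], nb[b, 2])
        d13 <- sqrt(r_ij^2 + r_jk^2 - 2 * r_ij * r_jk * cos(theta))
        pi_ <- c(pi_, i); pj <- c(pj, k); tgt <- c(tgt, d13); w <- c(w, 1)
      }
    }
  }
  # repulsion between atoms 3+ bonds apart (graph BFS distances)
  gd <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    gd[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0 && depth < 3) {
      depth <- depth + 1
      nxt <- integer(0)
      for (u in frontier) {
        nb <- adj[[u]]
        if (is.null(nb)) next
        for (v in nb[, 1]) if (gd[s, v] > depth) { gd[s, v] <- depth; nxt <- c(nxt, v) }
      }
      frontier <- unique(nxt)
    }
  }
  rep_i <- integer(0); rep_j <- integer(0)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
      if (gd[i, j] > 2) { rep_i <- c(rep_i, i); rep_j <- c(rep_j, j) }
  }
  list(ci = pi_, cj = pj, target = tgt, weight = w,
       rep_i = rep_i, rep_j = rep_j, rep_min = 2.4)
}

#' Deterministic conformer embedding for a molecular topology
#'
#' Distance-geometry targets (ideal bond lengths, 1-3 distances from
#' idealized angles, nonbonded repulsion) relaxed by seeded gradient
#' descent. Fails — returns NULL — when the relaxed geometry leaves any
#' bond more than `tol` Angstrom from its ideal length, which is how
#' strained topologies (fused small rings, cumulated systems under
#' ring constraints) surface as embedding failures.
#'
#' @param topo A `molecule_topology`.
#' @param seed Integer seed for the random start.
#' @param n_steps Relaxation steps (default 400).
#' @param tol Maximum tolerated bond-length deviation in Angstrom
#'   (default 0.25).
#' @return A coordinate matrix (n_atoms x 3) or NULL on failure.
#' @export
embed_topology <- function(topo, seed = 1L, n_steps = 400L, tol = 0.25) {
  n <- topo$n_atoms
  if (n == 1) return(matrix(0, 1, 3))
  cs <- embedding_constraints(topo)
  X <- with_seed(derive_seed(seed, 7877, n), matrix(stats::rnorm(n * 3, 0, 1.5), n, 3))
  nc <- length(cs$ci)
  for (s in seq_len(n_steps)) {
    step <- 0.12 * (1 - (s - 1) / n_steps) + 0.01
    G <- matrix(0, n, 3)
    D <- X[cs$ci, , drop = FALSE] - X[cs$cj, , drop = FALSE]
    r <- sqrt(rowSums(D^2)) + 1e-9
    f <- cs$weight * (r - cs$target) / r     # d/dxi of w*(r - r0)^2 / 2
    FD <- D * f
    # accumulate gradients (loop form: n is tiny)
    for (k in seq_len(nc)) {
      G[cs$ci[k], ] <- G[cs$ci[k], ] + FD[k, ]
      G[cs$cj[k], ] <- G[cs$cj[k], ] - FD[k, ]
    }
    if (length(cs$rep_i) > 0) {
      Dr <- X[cs$rep_i, , drop = FALSE] - X[cs$rep_j, , drop = FALSE]
      rr <- sqrt(rowSums(Dr^2)) + 1e-9
      close <- rr < cs$rep_min
      if (any(close)) {
        fr <- ifelse(close, 2 * (rr - cs$rep_min) / rr, 0)
        FR <- Dr * fr
        for (k in which(close)) {
          G[cs$rep_i[k], ] <- G[cs$rep_i[k], ] + FR[k, ]
          G[cs$rep_j[k], ] <- G[cs$rep_j[k], ] - FR[k, ]
        }
      }
    }
    X <- X - step * G
  }
  # convergence criterion: every bond near its ideal length
  b <- topo$bonds
  if (nrow(b) > 0) {
    D <- X[b$i, , drop = FALSE] - X[b$j, , drop = FALSE]
    r <- sqrt(rowSums(D^2))
    ideal <- vapply(seq_len(nrow(b)), function(k)
      ideal_bond_length(topo$element[b$i[k]], topo$element[b$j[k]],
                        b$order[k]), numeric(1))
    if (any(abs(r - ideal) > tol) || !all(is.finite(X))) return(NULL)
  }
  X - matrix(colMeans(X), n, 3, byrow = TRUE)
}

# A geometry is accepted as a conformer of a topology only if every bond
# sits within `tol` Angstrom of its ideal length — the same convergence
# criterion the embedder enforces. Distorted geometries (e.g. after
# coordinate noise) fail here, mirroring a physics stage rejecting an
# off-equilibrium structure.
conformer_consistent <- function(topo, coords, tol = 0.25) {
  b <- topo$bonds
  if (nrow(b) == 0) return(TRUE)
  D <- coords[b$i, , drop = FALSE] - coords[b$j, , drop = FALSE]
  r <- sqrt(rowSums(D^2))
  ideal <- vapply(seq_len(nrow(b)), function(k)
    ideal_bond_length(topo$element[b$i[k]], topo$element[b$j[k]],
                      b$order[k]), numeric(1))
  all(is.finite(r)) && all(abs(r - ideal) <= tol)
}

# Batch embedding of molecular strings through the package's embedder;
# per input either list(element, coords) or NULL on failure.
embed3d_batch <- function(selfies, seed = 1L) {
  lapply(seq_along(selfies), function(i) {
    topo <- tryCatch(decode_selfies(selfies[i]), error = function(e) NULL)
    if (is.null(topo)) return(NULL)
    X <- embed_topology(topo, seed = seed)
    if (is.null(X)) return(NULL)
    list(element = topo$element, coords = X)
  })
}
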
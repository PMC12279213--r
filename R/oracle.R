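#' Property vectors and oracle results
#'
#' A `property_vector` is a named numeric vector of molecular properties
#' with per-property unit labels, carried unmodified through the whole
#' pipeline. An `oracle_result` is the outcome of a forward-process call:
#' either `ok` with properties, or `unstable` with a reason.
#'
#' @param values Numeric vector.
#' @param names Property names (defaults to `names(values)`).
#' @param units Unit labels, same length.
#' @return A `property_vector`.
#' @export
property_vector <- function(values, names = base::names(values), units = NULL) {
  stopifnot(!is.null(names), length(names) == length(values))
  if (is.null(units)) units <- rep("", length(values))
  stopifnot(length(units) == length(values))
  structure(stats::setNames(as.numeric(values), names),
            units = units, class = "property_vector")
}

#' @export
print.property_vector <- function(x, ...) {
  u <- attr(x, "units")
  cat("<property_vector>\n")
  for (i in seq_along(x))
    cat(sprintf("  %-8s %10.4f %s\n", names(x)[i], x[i], u[i]))
  invisible(x)
}

oracle_result <- function(status, properties = NULL, reason = NULL) {
  stopifnot(status %in% c("ok", "unstable"))
  if (status == "ok") stopifnot(!is.null(properties))
  structure(list(status = status, properties = properties, reason = reason),
            class = "oracle_result")
}

DESCRIPTOR_UNITS <- c(mw = "Da", logp = "", tpsa = "A^2")

# Batched descriptor forward process over molecular strings.
# A molecule is stable when (1) its structure is interpretable, (2) a 3D
# conformer embeds, (3) re-perceiving connectivity from the embedded
# geometry alone reproduces the intended topology — the desk-scale
# analogue of the geometry surviving a quantum-chemistry pipeline — and
# (4) all descriptors are finite. `check_geometry = FALSE` skips (2)-(3).
descriptor_oracle_batch <- function(selfies, check_geometry = TRUE) {
  smiles <- vapply(selfies, function(s) {
    tryCatch(selfies_to_smiles(s), error = function(e) NA_character_)
  }, character(1), USE.NAMES = FALSE)
  n <- length(selfies)
  status <- ifelse(is.na(smiles), "unstable", "ok")
  reason <- ifelse(is.na(smiles), "uninterpretable", NA_character_)
  if (check_geometry) {
    live <- which(status == "ok")
    if (length(live) > 0) {
      geoms <- embed3d_batch(selfies[live])
      failed <- vapply(geoms, is.null, logical(1))
      status[live[failed]] <- "unstable"
      reason[live[failed]] <- "embedding_failed"
      ok2 <- live[!failed]
      if (length(ok2) > 0) {
        intended <- ob_canonical(smiles[ok2])
        seen <- perceived_canonical(ob_perceive_topology_batch(geoms[!failed]))
        mismatch <- is.na(seen) | is.na(intended) | seen != intended
        status[ok2[mismatch]] <- "unstable"
        reason[ok2[mismatch]] <- "geometry_mismatch"
      }
    }
  }
  vals <- matrix(NA_real_, n, 3, dimnames = list(NULL, names(DESCRIPTOR_UNITS)))
  live <- which(status == "ok")
  if (length(live) > 0) {
    d <- ob_descriptors(smiles[live])
    vals[live, ] <- d
    bad <- live[!apply(is.finite(d), 1, all)]
    status[bad] <- "unstable"
    reason[bad] <- "descriptor_failed"
  }
  list(status = status, values = vals, reason = reason, smiles = smiles)
}

#' Descriptor-based forward process (desk-scale oracle)
#'
#' Computes three molecular descriptors — molecular weight (Da), an
#' octanol/water partition estimate (logP) and topological polar surface
#' area (A^2) — mirroring the dimensionality of a three-property
#' quantum-chemistry target (HOMO/LUMO/dipole) without its cost. The
#' molecule is flagged `unstable` when interpretation, conformer
#' embedding, or the geometry round-trip fails (see Details).
#'
#' @details Stability requires that re-perceiving connectivity from the
#' embedded 3D coordinates alone reproduces the intended topology. This is
#' the package's stand-in for the convergence requirement of a physics
#' oracle: a geometry that does not support its own topology is rejected.
#'
#' @param x A molecular string, `molecule_record`, or `molecule_graph`
#'   (for graphs, connectivity is re-perceived from coordinates).
#' @param check_geometry Logical; include the embedding/round-trip check
#'   (default TRUE).
#' @return An `oracle_result`.
#' @export
#' @examples
#' \donttest{
#' descriptor_oracle("[C][C][O]")
#' }
descriptor_oracle <- function(x, check_geometry = TRUE) {
  if (inherits(x, "molecule_graph")) {
    # a conformer is first re-perceived from its coordinates; the given
    # geometry must be a near-equilibrium conformer of what was
    # perceived, and the perceived molecule then passes the same
    # stability chain as any molecular string
    tp <- ob_perceive_topology_batch(list(list(element = x$atom_types,
                                               coords = x$coords)))[[1]]
    if (is.null(tp))
      return(oracle_result("unstable", reason = "reperception_failed"))
    s <- tryCatch(topology_to_selfies(tp), error = function(e) NA_character_)
    if (is.na(s))
      return(oracle_result("unstable", reason = "uninterpretable"))
    if (check_geometry && !conformer_consistent(tp, x$coords))
      return(oracle_result("unstable", reason = "distorted_geometry"))
    return(descriptor_oracle(s, check_geometry = check_geometry))
  }
  selfies <- if (inherits(x, "molecule_record")) x$selfies else x
  r <- descriptor_oracle_batch(selfies, check_geometry = check_geometry)
  if (r$status[1] != "ok")
    return(oracle_result("unstable", reason = r$reason[1]))
  oracle_result("ok", property_vector(r$values[1, ],
                                      units = unname(DESCRIPTOR_UNITS)))
}

#' Analytic test oracle on latent vectors
#'
#' `p = A z + b`, optionally through a fixed smooth nonlinearity. Used in
#' closed-loop harnesses where the "molecule" is its latent, enabling
#' exact verification of the reacquisition/surrogate/design machinery.
#'
#' @param z Latent vector (length d) or matrix (n x d).
#' @param A Coefficient matrix (k x d).
#' @param b Offset vector (length k).
#' @param nonlinearity Optional elementwise function applied to `A z + b`.
#' @return A `property_vector` (or an n x k matrix for matrix input).
#' @export
#' @examples
#' analytic_oracle(c(1, 2), diag(2), c(0, 0))
analytic_oracle <- function(z, A, b, nonlinearity = NULL) {
  A <- as.matrix(A)
  if (is.matrix(z)) {
    if (ncol(z) != ncol(A)) stop("latent dimension ", ncol(z),
                                 " does not match A (", ncol(A), " columns)")
    out <- z %*% t(A) + matrix(b, nrow(z), length(b), byrow = TRUE)
    if (!is.null(nonlinearity)) out <- nonlinearity(out)
    colnames(out) <- paste0("p", seq_len(ncol(out)))
    return(out)
  }
  if (length(z) != ncol(A)) stop("latent dimension ", length(z),
                                 " does not match A (", ncol(A), " columns)")
  p <- drop(A %*% z) + b
  if (!is.null(nonlinearity)) p <- nonlinearity(p)
  property_vector(p, names = paste0("p", seq_along(p)),
                  units = rep("", length(p)))
}

#' Bundle an analytic oracle into the forward-process contract
#'
#' @inheritParams analytic_oracle
#' @return A function `f(z) -> oracle_result` satisfying the oracle
#'   contract with latents in place of molecules.
#' @export
make_analytic_oracle <- function(A, b, nonlinearity = NULL) {
  force(A); force(b); force(nonlinearity)
  function(z) oracle_result("ok", analytic_oracle(z, A, b, nonlinearity))
}

#' External-command forward process
#'
#' Wraps a user command into the oracle contract: the command receives the
#' path of an SDF file with one conformer and must print a JSON object of
#' named numeric properties on stdout. Any failure (non-zero exit, bad
#' JSON, non-finite values) yields an `unstable` result with the captured
#' reason — the contract an external quantum-chemistry adapter satisfies.
#'
#' @param command Command string; the SDF path is appended as the last
#'   argument.
#' @param units Optional named unit labels for the returned properties.
#' @return A function `f(record_or_graph) -> oracle_result`.
#' @export
external_oracle <- function(command, units = NULL) {
  force(command); force(units)
  function(x) {
    g <- if (inherits(x, "molecule_graph")) x else x$graph
    if (is.null(g)) return(oracle_result("unstable", reason = "no_conformer"))
    path <- tempfile(fileext = ".sdf")
    on.exit(unlink(path))
    rec <- list(canonical_id = "mol", graph = g)
    write_conformers_sdf(list(rec), path)
    out <- tryCatch(
      suppressWarnings(system(paste(command, shQuote(path)),
                              intern = TRUE, ignore.stderr = TRUE)),
      error = function(e) NULL
    )
    if (is.null(out) || !is.null(attr(out, "status")))
      return(oracle_result("unstable", reason = "command_failed"))
    vals <- tryCatch(jsonlite::fromJSON(paste(out, collapse = "")),
                     error = function(e) NULL)
    if (is.null(vals) || !all(is.finite(unlist(vals))))
      return(oracle_result("unstable", reason = "bad_output"))
    v <- unlist(vals)
    u <- if (is.null(units)) rep("", length(v)) else unname(units[names(v)])
    oracle_result("ok", property_vector(v, units = u))
  }
}
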
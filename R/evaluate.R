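#' Evaluation metrics for generated designs
#'
#' The headline metric is the forward-process (oracle) error: the mean
#' absolute difference between the properties the oracle computes for the
#' generated molecules and the target properties, in natural units.
#' Novelty, uniqueness and the surrogate-oracle misalignment complete the
#' report.
#'
#' @name evaluation
NULL

# collect per-design rows into a data.frame for persistence/recomputation
designs_to_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    row <- data.frame(selfies = r$selfies, stringsAsFactors = FALSE)
    for (nm in names(r$targets)) {
      row[[paste0("target_", nm)]] <- as.numeric(r$targets[[nm]])
      row[[paste0("surrogate_error_", nm)]] <- unname(r$surrogate_error[nm])
      row[[paste0("oracle_error_", nm)]] <-
        if (is.null(r$oracle_error)) NA_real_
        else unname(r$oracle_error[match(nm, names(r$targets))])
    }
    row$uncertainty <- r$uncertainty_total
    row$oracle_status <- if (is.null(r$oracle_status)) NA_character_
                         else r$oracle_status
    row
  }))
}

#' Write / read the per-design results table
#'
#' @param results List of `design_result`s.
#' @param path CSV path.
#' @return Invisibly the table (write) / the table (read).
#' @export
write_design_csv <- function(results, path) {
  tab <- designs_to_table(results)
  tab$canonical_id <- vapply(tab$selfies, function(s) {
    if (is.na(s)) NA_character_ else canonical_id(s)
  }, character(1), USE.NAMES = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Oracle (forward-process) error of a set of designs
#'
#' Mean absolute error, per property, between oracle-computed properties
#' of the designs and their targets; unstable designs are excluded from
#' the MAE and counted.
#'
#' @param results List of `design_result`s whose oracle fields are filled
#'   (see [design_molecule()] with an oracle, or fill them with `oracle`
#'   here).
#' @param oracle Optional oracle used to fill missing oracle results.
#' @param decoder Decoder for oracle evaluation of unfilled results.
#' @return List with `mae` (named per property), `n_designs`,
#'   `n_unstable`.
#' @export
nfp_error <- function(results, oracle = NULL, decoder = "identity") {
  stopifnot(length(results) > 0)
  if (!is.null(oracle))
    results <- lapply(results, function(r) {
      if (is.null(r$oracle_status))
        evaluate_design_oracle(r, oracle, decoder) else r
    })
  stat <- vapply(results, function(r) {
    if (is.null(r$oracle_status)) NA_character_ else r$oracle_status
  }, character(1))
  if (anyNA(stat)) stop("designs lack oracle evaluations; pass an oracle")
  ok <- stat == "ok"
  if (!any(ok)) stop("no stable designs to evaluate")
  E <- do.call(rbind, lapply(results[ok], function(r) r$oracle_error))
  colnames(E) <- names(results[[which(ok)[1]]]$targets)
  list(mae = colMeans(E), n_designs = length(results),
       n_unstable = sum(!ok))
}

#' Novelty of generated designs
#'
#' Percentage of designs whose canonical id is absent from a reference
#' set of ids (e.g. the training corpus).
#'
#' @param results List of `design_result`s (or a character vector of
#'   canonical ids).
#' @param reference_ids Character vector of reference canonical ids.
#' @return Percentage in \[0, 100\].
#' @export
novelty <- function(results, reference_ids) {
  ids <- design_ids(results)
  100 * mean(!(ids %in% reference_ids))
}

#' Uniqueness of generated designs
#'
#' Percentage of distinct canonical ids among the designs.
#'
#' @inheritParams novelty
#' @return Percentage in \[0, 100\].
#' @export
uniqueness <- function(results) {
  ids <- design_ids(results)
  100 * length(unique(ids)) / length(ids)
}

design_ids <- function(results) {
  if (is.character(results)) return(results)
  selfies <- vapply(results, `[[`, "", "selfies")
  if (anyNA(selfies)) stop("latent-only designs have no canonical id")
  canonical_id(selfies)
}

#' Surrogate-oracle misalignment
#'
#' The absolute difference, per property, between the oracle-computed
#' design MAE and the surrogate-predicted design MAE. A perfectly aligned
#' surrogate scores 0: it predicts its own design errors exactly.
#'
#' @param results List of `design_result`s with oracle fields filled.
#' @param oracle,decoder Optional oracle to fill missing evaluations.
#' @return Named numeric vector per property (natural units).
#' @export
misalignment <- function(results, oracle = NULL, decoder = "identity") {
  ne <- nfp_error(results, oracle, decoder)
  stat <- vapply(results, `[[`, "", "oracle_status")
  ok <- stat == "ok"
  S <- do.call(rbind, lapply(results[ok], function(r) r$surrogate_error))
  abs(ne$mae - colMeans(S))
}

#' Representation-perturbation study
#'
#' Measures how robust each molecular representation is to a minimal
#' perturbation: Gaussian noise on one atom's 3D coordinates, one random
#' atom-type change, one random string-symbol change, or Gaussian noise
#' on the latent vector (encode, perturb, decode). For each mode it
#' reports the percentage of perturbed molecules that are still stable
#' under the forward process and, over pairs where both the original and
#' the perturbed molecule are stable, the per-property MAE between their
#' properties.
#'
#' @param records List of `molecule_record`s with embedded graphs.
#' @param model A trained `sgp_vae` (needed for the latent mode).
#' @param modes Subset of `c("coord_noise", "atom_type_swap",
#'   "selfies_swap", "latent")`.
#' @param sigma Noise scale (default 0.1: Angstrom for coordinates,
#'   latent units for the latent mode).
#' @param seed Integer seed.
#' @return Data.frame with one row per mode: `mode`, `stable_pct`,
#'   `n_compared`, and `mae_<property>` columns.
#' @export
perturbation_study <- function(records, model = NULL,
                               modes = c("coord_noise", "atom_type_swap",
                                         "selfies_swap", "latent"),
                               sigma = 0.1, seed = 1L) {
  known <- c("coord_noise", "atom_type_swap", "selfies_swap", "latent")
  if (!all(modes %in% known))
    stop("unknown mode(s): ", paste(setdiff(modes, known), collapse = ", "))
  has_graph <- !vapply(records, function(r) is.null(r$graph), logical(1))
  records <- records[has_graph]
  stopifnot(length(records) > 0)
  n <- length(records)

  selfies0 <- vapply(records, `[[`, "", "selfies")
  base <- descriptor_oracle_batch(selfies0, check_geometry = TRUE)
  prop_names <- colnames(base$values)

  # oracle on a perturbed geometry view: re-perceive the molecule from
  # the coordinates, require the given geometry to be a near-equilibrium
  # conformer of what was perceived, then run the same forward process
  # as for any molecular string (embed + geometry round-trip +
  # descriptors)
  geom_oracle <- function(geoms) {
    topos <- ob_perceive_topology_batch(geoms)
    strings <- vapply(seq_along(topos), function(i) {
      tp <- topos[[i]]
      if (is.null(tp)) return(NA_character_)
      s <- tryCatch(topology_to_selfies(tp), error = function(e) NA_character_)
      if (is.na(s)) return(NA_character_)
      if (!conformer_consistent(tp, geoms[[i]]$coords)) return(NA_character_)
      s
    }, character(1))
    out <- list(status = rep("unstable", length(geoms)),
                values = matrix(NA_real_, length(geoms), 3,
                                dimnames = list(NULL, prop_names)))
    live <- which(!is.na(strings))
    if (length(live) > 0) {
      r <- descriptor_oracle_batch(strings[live], check_geometry = TRUE)
      out$status[live] <- r$status
      out$values[live, ] <- r$values
    }
    out
  }

  rows <- list()
  for (mode in modes) {
    if (mode %in% c("coord_noise", "atom_type_swap")) {
      geoms <- lapply(seq_len(n), function(i) {
        p <- perturb(records[[i]], mode, sigma = sigma, seed = seed + i)
        list(element = p$graph$atom_types, coords = p$graph$coords)
      })
      r <- geom_oracle(geoms)
      status <- r$status; vals <- r$values
    } else if (mode == "selfies_swap") {
      pert <- vapply(seq_len(n), function(i) {
        perturb(records[[i]], "selfies_swap", sigma = sigma,
                seed = seed + i)$selfies
      }, character(1))
      r <- descriptor_oracle_batch(pert, check_geometry = TRUE)
      status <- r$status; vals <- r$values
    } else { # latent
      stopifnot(!is.null(model))
      ids <- t(vapply(records, function(rr) tokenize(rr$selfies, model$vocab),
                      integer(model$vocab$max_length)))
      post <- encode(model, ids, lapply(records, `[[`, "graph"))
      Zp <- post$mean + with_seed(seed + 555L,
        matrix(stats::rnorm(length(post$mean), 0, sigma),
               nrow(post$mean), ncol(post$mean)))
      dec <- greedy_selfies(model, Zp)
      r <- descriptor_oracle_batch(dec, check_geometry = TRUE)
      status <- r$status; vals <- r$values
    }
    both <- base$status == "ok" & status == "ok"
    mae <- if (any(both))
      colMeans(abs(vals[both, , drop = FALSE] -
                   base$values[both, , drop = FALSE]))
    else rep(NA_real_, length(prop_names))
    row <- data.frame(mode = mode, stable_pct = 100 * mean(status == "ok"),
                      n_compared = sum(both))
    for (j in seq_along(prop_names))
      row[[paste0("mae_", prop_names[j])]] <- mae[j]
    rows[[mode]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble an evaluation report
#'
#' @param results List of `design_result`s with oracle fields filled.
#' @param reference_ids Reference canonical ids for novelty.
#' @return An `evaluation_report` list: `nfp_mae`, `novelty_pct`,
#'   `uniqueness_pct`, `misalignment`, `n_designs`, `n_unstable`.
#' @export
evaluation_report <- function(results, reference_ids = character(0)) {
  ne <- nfp_error(results)
  structure(list(
    nfp_mae = ne$mae,
    novelty_pct = novelty(results, reference_ids),
    uniqueness_pct = uniqueness(results),
    misalignment = misalignment(results),
    n_designs = ne$n_designs, n_unstable = ne$n_unstable
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$n_designs, " designs (",
      x$n_unstable, " unstable)\n", sep = "")
  cat("  oracle MAE: ",
      paste(sprintf("%s=%.3f", names(x$nfp_mae), x$nfp_mae), collapse = ", "),
      "\n  misalignment: ",
      paste(sprintf("%s=%.3f", names(x$misalignment), x$misalignment),
            collapse = ", "),
      "\n  novelty ", round(x$novelty_pct, 1), "% | uniqueness ",
      round(x$uniqueness_pct, 1), "%\n", sep = "")
  invisible(x)
}

#' Markdown summary of an evaluation report
#'
#' @param report An `evaluation_report`.
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  c("| metric | value |", "|---|---|",
    sprintf("| oracle MAE (%s) | %.4f |", names(report$nfp_mae),
            report$nfp_mae),
    sprintf("| misalignment (%s) | %.4f |", names(report$misalignment),
            report$misalignment),
    sprintf("| novelty | %.1f%% |", report$novelty_pct),
    sprintf("| uniqueness | %.1f%% |", report$uniqueness_pct),
    sprintf("| designs | %d (%d unstable) |", report$n_designs,
            report$n_unstable))
}
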
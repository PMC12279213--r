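#' Uncertainty-aware inverse design in latent space
#'
#' A design is found by gradient descent on
#' `L(z) = sum_k |phi_avg_k(z) - p_k| + lambda * U(z)` in standardized
#' property space: the ensemble's mean prediction is pulled to the target
#' while the epistemic-uncertainty term keeps the search in regions where
#' the surrogate is trustworthy. The winning latent is decoded back into
#' a molecule.
#'
#' @param targets Named numeric vector (or `property_vector`) of target
#'   property values in natural units; a subset of the trained properties
#'   is allowed.
#' @param k Budget of independent optimization tries (default 10); the
#'   best try is retained.
#' @param steps Gradient steps per try (default 500).
#' @param learning_rate Step size in standardized space (default 0.1),
#'   cosine-annealed over `steps`.
#' @param uncertainty_weight Weight lambda on the uncertainty term
#'   (default 1; 0 recovers the naive surrogate-only objective).
#' @param extra_penalties Named list of functions `f(z, decoder)`
#'   returning `list(value = scalar, grad = optional d-vector)`; values
#'   join the objective used for best-iterate selection, gradients (when
#'   given) join the descent direction.
#' @param seed Integer seed; try `i` uses seed + i - 1 for its init.
#' @return A `design_request`.
#' @export
design_request <- function(targets, k = 10L, steps = 500L,
                           learning_rate = 0.1, uncertainty_weight = 1,
                           extra_penalties = list(), seed = 1L) {
  stopifnot(k >= 1, steps >= 0, length(targets) >= 1, !is.null(names(targets)))
  structure(list(
    targets = targets, k = as.integer(k), steps = as.integer(steps),
    learning_rate = learning_rate, uncertainty_weight = uncertainty_weight,
    extra_penalties = extra_penalties, seed = as.integer(seed)
  ), class = "design_request")
}

# Batched gradient descent on the design objective. Z0 is B x d; targets
# Pstd is B x k_sel in standardized space over property columns sel.
# Returns best-objective iterates and per-step mean objective trace.
latent_gd <- function(ensemble, Z0, Pstd, sel, lambda, steps, lr,
                      penalties = list(), decoder = NULL) {
  m <- length(ensemble$members)
  B <- nrow(Z0)
  Z <- Z0
  best_Z <- Z
  best_obj <- rep(Inf, B)
  trace <- matrix(NA_real_, max(steps, 1), B)

  eval_obj <- function(Z) {
    fws <- lapply(ensemble$members, function(net) mlp_forward(net, Z))
    outs <- lapply(fws, function(f) f$out[, sel, drop = FALSE])
    avg <- Reduce(`+`, outs) / m
    sq <- Reduce(`+`, lapply(outs, function(o) o^2)) / m
    U <- pmax(sq - avg^2, 0)
    err <- avg - Pstd
    obj <- rowSums(abs(err)) + lambda * rowSums(U)
    pen_val <- rep(0, B); pen_grad <- NULL
    if (length(penalties) > 0) {
      for (pen in penalties) {
        pv <- pen(Z, decoder)
        pen_val <- pen_val + pv$value
        if (!is.null(pv$grad)) {
          if (is.null(pen_grad)) pen_grad <- matrix(0, B, ncol(Z))
          pen_grad <- pen_grad + pv$grad
        }
      }
    }
    list(fws = fws, outs = outs, avg = avg, U = U, err = err,
         obj = obj + pen_val, pen_grad = pen_grad)
  }

  if (steps == 0) {
    ev <- eval_obj(Z)
    return(list(Z = Z, obj = ev$obj, trace = matrix(ev$obj, 1, B)))
  }

  for (s in seq_len(steps)) {
    ev <- eval_obj(Z)
    better <- ev$obj < best_obj
    best_obj[better] <- ev$obj[better]
    best_Z[better, ] <- Z[better, , drop = FALSE]
    trace[s, ] <- ev$obj

    G <- matrix(0, B, ncol(Z))
    sgn <- sign(ev$err) / m
    for (j in seq_len(m)) {
      gj <- sgn + lambda * 2 * (ev$outs[[j]] - ev$avg) / m
      dY <- matrix(0, B, ensemble$property_dim)
      dY[, sel] <- gj
      G <- G + mlp_backward(ensemble$members[[j]], ev$fws[[j]]$cache, dY)$dX
    }
    if (!is.null(ev$pen_grad)) G <- G + ev$pen_grad
    if (!all(is.finite(G))) stop("non-finite gradient during latent descent")
    Z <- Z - cosine_lr(s, steps, lr) * G
  }
  ev <- eval_obj(Z)
  better <- ev$obj < best_obj
  best_obj[better] <- ev$obj[better]
  best_Z[better, ] <- Z[better, , drop = FALSE]
  list(Z = best_Z, obj = best_obj, trace = trace)
}

# resolve target names against the trained property set; returns list
# (sel = column indices, std = standardized target values)
resolve_targets <- function(targets, ensemble) {
  nm <- names(targets)
  sel <- match(nm, ensemble$property_names)
  if (anyNA(sel))
    stop("unknown target properties: ", paste(nm[is.na(sel)], collapse = ", "))
  mu <- ensemble$stats$mean[sel]; sd <- ensemble$stats$sd[sel]
  list(sel = sel, std = (as.numeric(targets) - mu) / sd)
}

#' Run one optimization try of the design objective
#'
#' @param request A [design_request()] (its `k` is ignored: one try).
#' @param ensemble A trained `surrogate_ensemble`.
#' @param decoder An `sgp_vae` used to decode the winner, or `"identity"`
#'   in closed-loop harnesses.
#' @return A `design_result`: `latent`, `selfies` (NA for identity
#'   decoder), `surrogate_pred`, `surrogate_error` (natural units, per
#'   property), `uncertainty` (standardized), `objective` and
#'   `objective_trace`.
#' @export
optimize_latent <- function(request, ensemble, decoder = "identity") {
  stopifnot(inherits(request, "design_request"),
            !is.null(ensemble$stats))
  rt <- resolve_targets(request$targets, ensemble)
  d <- ensemble$latent_dim
  Z0 <- with_seed(request$seed, matrix(stats::rnorm(d), 1, d))
  gd <- latent_gd(ensemble, Z0, matrix(rt$std, 1), rt$sel,
                  request$uncertainty_weight, request$steps,
                  request$learning_rate, request$extra_penalties, decoder)
  finish_design(gd$Z[1, ], gd$trace[, 1], request, ensemble, decoder, rt)
}

finish_design <- function(z, trace, request, ensemble, decoder, rt) {
  pr <- predict(ensemble, z, natural = TRUE)
  pred <- pr$mean[1, rt$sel]
  names(pred) <- names(request$targets)
  err <- abs(pred - as.numeric(request$targets))
  selfies <- NA_character_
  if (inherits(decoder, "sgp_vae")) selfies <- greedy_selfies(decoder, z)
  structure(list(
    latent = z, selfies = selfies,
    surrogate_pred = pred, surrogate_error = err,
    surrogate_error_total = sum(err),
    uncertainty = pr$uncertainty[1, rt$sel],
    uncertainty_total = sum(pr$uncertainty[1, rt$sel]),
    objective_trace = trace[!is.na(trace)],
    targets = request$targets,
    oracle_props = NULL, oracle_error = NULL, oracle_status = NULL
  ), class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("<design_result> ", if (is.na(x$selfies)) "(latent-only)" else x$selfies,
      "\n  surrogate error: ", round(x$surrogate_error_total, 4),
      "  uncertainty: ", round(x$uncertainty_total, 4), sep = "")
  if (!is.null(x$oracle_error))
    cat("  oracle error: ", round(sum(x$oracle_error), 4), sep = "")
  cat("\n")
  invisible(x)
}

# evaluate a design against the forward oracle, filling oracle_* fields
evaluate_design_oracle <- function(result, oracle, decoder) {
  x <- if (inherits(decoder, "sgp_vae")) result$selfies else result$latent
  r <- oracle(x)
  result$oracle_status <- r$status
  if (r$status == "ok") {
    p <- as.numeric(r$properties)[match(names(result$targets),
                                        names(r$properties))]
    result$oracle_props <- p
    result$oracle_error <- abs(p - as.numeric(result$targets))
  }
  result
}

#' Design a molecule under a k-tries budget
#'
#' Runs `k` independent optimization tries from different seeded
#' initializations. When an oracle is supplied, the try with the lowest
#' oracle absolute error is retained (the evaluation-protocol mode);
#' otherwise the lowest surrogate error decides. All candidates are kept
#' in the result.
#'
#' @param request A [design_request()].
#' @param ensemble A trained `surrogate_ensemble`.
#' @param decoder An `sgp_vae` or `"identity"`.
#' @param oracle Optional oracle function (`x -> oracle_result`); for the
#'   identity decoder it receives the latent, otherwise the decoded
#'   molecular string.
#' @return The best `design_result`, with `candidates` (list of all k
#'   tries) attached.
#' @export
design_molecule <- function(request, ensemble, decoder = "identity",
                            oracle = NULL) {
  stopifnot(inherits(request, "design_request"))
  cands <- vector("list", request$k)
  for (i in seq_len(request$k)) {
    req_i <- request
    req_i$seed <- request$seed + i - 1L
    res <- tryCatch(optimize_latent(req_i, ensemble, decoder),
                    error = function(e) NULL)
    if (!is.null(res) && !is.null(oracle))
      res <- evaluate_design_oracle(res, oracle, decoder)
    cands[[i]] <- res
  }
  ok <- !vapply(cands, is.null, logical(1))
  if (!any(ok)) stop("all ", request$k, " design tries failed")
  score <- vapply(cands, function(r) {
    if (is.null(r)) return(Inf)
    if (!is.null(oracle)) {
      if (is.null(r$oracle_error)) Inf else sum(r$oracle_error)
    } else r$surrogate_error_total
  }, numeric(1))
  best <- cands[[which.min(score)]]
  best$candidates <- cands
  best$selection <- if (!is.null(oracle)) "oracle_error" else "surrogate_error"
  best
}

#' Evenly spaced target values over a range
#'
#' @param range_low,range_high Range endpoints (low < high).
#' @param n Number of values (>= 2), endpoints included.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' target_grid(0, 4, 5)
target_grid <- function(range_low, range_high, n) {
  stopifnot(n >= 2)
  if (!(range_low < range_high)) stop("invalid range: low must be < high")
  seq(range_low, range_high, length.out = n)
}

#' Standard quantum-property target ranges
#'
#' The conventional single-objective target ranges for frontier-orbital
#' energies and dipole moment — HOMO in [-10, 0] eV, LUMO in [-4, 2] eV,
#' dipole in [0, 4] D — and the narrower multi-objective ranges (HOMO
#' [-8, -3], LUMO [-3, 2]) that avoid targets with HOMO above LUMO.
#'
#' @param objective `"single"` or `"multi"`.
#' @return Named list of `c(low, high)` ranges.
#' @export
qm_target_ranges <- function(objective = c("single", "multi")) {
  objective <- match.arg(objective)
  if (objective == "single")
    list(homo = c(-10, 0), lumo = c(-4, 2), dipole = c(0, 4))
  else
    list(homo = c(-8, -3), lumo = c(-3, 2), dipole = c(0, 4))
}

#' Molecular-mass penalty (example extra penalty)
#'
#' Decode-and-score penalty proportional to the molecular mass of the
#' molecule a latent decodes to. It carries no analytic gradient; it
#' steers the search through best-iterate and best-try selection. Use
#' [make_mass_penalty()] to plug it into a [design_request()].
#'
#' @param z Latent vector or matrix (rows = latents).
#' @param decoder An `sgp_vae`.
#' @param scale Mass divisor (default 100 Da) keeping the penalty
#'   commensurate with standardized errors.
#' @return Numeric vector of penalty values.
#' @export
mass_penalty <- function(z, decoder, scale = 100) {
  stopifnot(inherits(decoder, "sgp_vae"))
  s <- greedy_selfies(decoder, z)
  vapply(s, selfies_mass, numeric(1), USE.NAMES = FALSE) / scale
}

#' @rdname mass_penalty
#' @param weight Penalty weight (0 disables it exactly).
#' @export
make_mass_penalty <- function(weight = 1, scale = 100) {
  force(weight); force(scale)
  function(z, decoder) {
    if (weight == 0) return(list(value = 0, grad = NULL))
    list(value = weight * mass_penalty(z, decoder, scale), grad = NULL)
  }
}
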
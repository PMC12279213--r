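# hand-built design results for metric arithmetic
mk_result <- function(selfies, target, surr_err, orc_err,
                      status = "ok", prop = "p") {
  structure(list(
    latent = rnorm(2), selfies = selfies,
    surrogate_pred = stats::setNames(target + surr_err, prop),
    surrogate_error = stats::setNames(surr_err, prop),
    surrogate_error_total = surr_err,
    uncertainty = stats::setNames(0.1, prop), uncertainty_total = 0.1,
    objective_trace = c(1, 0.5),
    targets = stats::setNames(target, prop),
    oracle_props = target + orc_err,
    oracle_error = stats::setNames(abs(orc_err), prop),
    oracle_status = status
  ), class = "design_result")
}

test_that("oracle error is the mean absolute error over stable designs", {
  res <- list(mk_result("[C]", 1, 0.1, 0.2),
              mk_result("[C][C]", 2, 0.2, 0.4))
  ne <- nfp_error(res)
  expect_equal(unname(ne$mae), 0.3)
  expect_equal(ne$n_unstable, 0L)
  # designs exactly on target
  res0 <- list(mk_result("[C]", 1, 0, 0))
  expect_equal(unname(nfp_error(res0)$mae), 0)
  # unstable designs are excluded and counted
  res2 <- c(res, list(mk_result("[O]", 3, 0.1, 99, status = "unstable")))
  ne2 <- nfp_error(res2)
  expect_equal(unname(ne2$mae), 0.3)
  expect_equal(ne2$n_unstable, 1L)
  expect_error(nfp_error(list(mk_result("[C]", 1, 0, 0, status = "unstable"))),
               "no stable designs")
})

test_that("novelty percentages hit their boundary cases", {
  ids <- canonical_id(c("[C]", "[C][C]", "[C][O]", "[C][N]"))
  expect_equal(novelty(ids, ids), 0)
  expect_equal(novelty(ids, character(0)), 100)
  expect_equal(novelty(ids, ids[1:2]), 50)
  expect_equal(novelty(rev(ids), ids[1:2]), 50) # order-invariant
})

test_that("uniqueness percentages hit their boundary cases", {
  a <- canonical_id("[C]"); b <- canonical_id("[C][C]"); c_ <- canonical_id("[C][O]")
  expect_equal(uniqueness(rep(a, 4)), 25)
  expect_equal(uniqueness(c(a, b, c_)), 100)
  expect_equal(uniqueness(c(a, a, b, c_)), 75)
  expect_equal(uniqueness(c(c_, a, b, a)), 75)
})

test_that("misalignment is the absolute gap between the two error estimates", {
  res <- list(mk_result("[C]", 1, 0.06, 0.95),
              mk_result("[C][C]", 2, 0.06, 0.95))
  expect_equal(unname(misalignment(res)), 0.89)
  # symmetric in the two error summaries
  swapped <- list(mk_result("[C]", 1, 0.95, 0.06),
                  mk_result("[C][C]", 2, 0.95, 0.06))
  expect_equal(unname(misalignment(swapped)), 0.89)
  # perfect alignment scores zero
  eq <- list(mk_result("[C]", 1, 0.3, 0.3))
  expect_equal(unname(misalignment(eq)), 0)
})

test_that("metrics are recomputable from the persisted per-design table", {
  res <- list(mk_result("[C]", 1, 0.1, 0.2),
              mk_result("[C][C]", 2, 0.2, 0.4),
              mk_result("[C]", 1.5, 0.3, 0.1))
  path <- tempfile(fileext = ".csv")
  write_design_csv(res, path)
  tab <- read_design_csv(path)
  expect_equal(mean(tab$oracle_error_p), unname(nfp_error(res)$mae))
  expect_equal(abs(mean(tab$oracle_error_p) - mean(tab$surrogate_error_p)),
               unname(misalignment(res)))
  expect_equal(100 * length(unique(tab$canonical_id)) / nrow(tab),
               uniqueness(res))
})

test_that("the evaluation report assembles and prints", {
  res <- list(mk_result("[C]", 1, 0.1, 0.2),
              mk_result("[C][C]", 2, 0.2, 0.4))
  rep <- evaluation_report(res, reference_ids = canonical_id("[C]"))
  expect_equal(rep$novelty_pct, 50)
  expect_equal(rep$uniqueness_pct, 100)
  expect_true(all(rep$misalignment >= 0))
  md <- report_markdown(rep)
  expect_true(any(grepl("novelty", md)))
  expect_output(print(rep), "designs")
})

test_that("the perturbation study reports one complete row per mode", {
  ds <- fx_dataset()
  vae <- fx_vae()
  recs <- ds$records[1:25]
  tab <- perturbation_study(recs, vae, sigma = 0.1, seed = 2)
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$mode, c("coord_noise", "atom_type_swap",
                              "selfies_swap", "latent"))
  expect_true(all(tab$stable_pct >= 0 & tab$stable_pct <= 100))
  expect_true(all(c("mae_mw", "mae_logp", "mae_tpsa") %in% names(tab)))
  expect_error(perturbation_study(recs, vae, modes = "bogus"), "unknown mode")
})

test_that("zero coordinate noise leaves stable molecules' properties unchanged", {
  # restrict to molecules that pass the full stability chain so the
  # baseline is clean
  ds0 <- build_labelled_dataset(fx_corpus(), "descriptors",
                                check_geometry = TRUE)
  recs <- ds0$records[seq_len(min(15, length(ds0$records)))]
  tab <- perturbation_study(recs, model = NULL, modes = "coord_noise",
                            sigma = 0, seed = 3)
  expect_equal(tab$stable_pct, 100)
  expect_equal(tab$mae_mw, 0)
  expect_equal(tab$mae_tpsa, 0)
})
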
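#' Pipeline configuration
#'
#' One YAML-serializable configuration drives the whole pipeline:
#' corpus generation, VAE training, reacquisition, surrogate training,
#' design and evaluation. A single global seed fans out deterministically
#' to per-stage seeds. Unknown keys are rejected at load time, and every
#' run writes its resolved configuration beside its outputs.
#'
#' @param overrides Nested named list overriding defaults.
#' @return A validated `run_config`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    data = list(n_molecules = 200L, max_tokens = 16L, embed = TRUE),
    vae = list(latent_dim = 16L, epochs = 50L, batch_size = 32L, lr = 1e-3),
    oracle = list(kind = "descriptors", command = NULL),
    reacquisition = list(n_latents = 10000L, check_geometry = FALSE),
    ensemble = list(n_members = 5L, epochs = 300L, batch_size = 32L, q = 0.3,
                    lr = 1e-3),
    design = list(property = "mw", n_targets = 10L, range = NULL, k = 10L,
                  lambda = 1, steps = 500L, learning_rate = 0.1),
    evaluation = list(check_geometry = TRUE)
  )
  merge_cfg <- function(base, over, path = "") {
    for (nm in names(over)) {
      if (!nm %in% names(base))
        stop("unknown config key: ", paste0(path, nm))
      if (is.list(base[[nm]]) && is.list(over[[nm]]))
        base[[nm]] <- merge_cfg(base[[nm]], over[[nm]], paste0(path, nm, "."))
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  structure(merge_cfg(cfg, overrides), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

# deterministic per-stage seed fan-out from the global seed
stage_seed <- function(seed, stage) {
  offs <- c(data = 11L, vae = 23L, reacquisition = 37L, ensemble = 53L,
            design = 71L, evaluation = 89L)
  (as.integer(seed) * 977L + offs[[stage]]) %% 2147483647L
}

#' Run the full design pipeline
#'
#' Executes corpus generation, VAE training, latent-property
#' reacquisition, ensemble training, design over a target grid and
#' evaluation, persisting each stage's artifact in `dir`. Stages whose
#' artifact already exists are reused, so a rerun with one artifact
#' deleted re-executes only that stage and the ones after it.
#'
#' @param config A [run_config()].
#' @param dir Run directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the run's artifacts (`report`, paths).
#' @export
run_pipeline <- function(config = run_config(), dir = tempfile("run"),
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rm(list = ls(pipeline_cache), envir = pipeline_cache)
  say <- function(...) if (!quiet) message("[uncertmol] ", ...)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))

  # resolve the configured forward oracle into the three call shapes the
  # stages need (batched labelling, reacquisition, per-string evaluation)
  kind <- config$oracle$kind
  if (!kind %in% c("descriptors", "external_command"))
    stop("unknown oracle kind: ", kind)
  ext <- if (kind == "external_command") external_oracle(config$oracle$command)
  record_oracle <- if (kind == "descriptors") "descriptors"
    else function(record) {
      if (is.null(record$graph))
        oracle_result("unstable", reason = "no_conformer")
      else ext(record$graph)
    }
  string_oracle <- if (kind == "descriptors")
    function(s) descriptor_oracle(s, check_geometry = config$evaluation$check_geometry)
    else function(s) {
      emb <- embed_conformer(s, seed = config$seed)
      if (emb$status != "ok")
        oracle_result("unstable", reason = "embedding_failed")
      else ext(emb$graph)
    }

  paths <- list(
    corpus = file.path(dir, "corpus.selfies"),
    labels = file.path(dir, "labels.csv"),
    vae = file.path(dir, "vae.json"),
    dataset = file.path(dir, "reacquired"),
    ensemble = file.path(dir, "ensemble.json"),
    designs = file.path(dir, "designs.csv"),
    report = file.path(dir, "report.json"),
    manifest = file.path(dir, "manifest.json")
  )

  # ---- stage: data -----------------------------------------------------
  if (!file.exists(paths$labels) || !file.exists(paths$corpus)) {
    say("generating corpus (n = ", config$data$n_molecules, ")")
    spec <- fixture_spec(n_molecules = config$data$n_molecules,
                         max_tokens = config$data$max_tokens,
                         seed = stage_seed(config$seed, "data"))
    corpus <- generate_selfies_corpus(spec, embed = config$data$embed)
    dataset <- build_labelled_dataset(corpus, record_oracle)
    writeLines(vapply(dataset$records, `[[`, "", "selfies"), paths$corpus)
    utils::write.csv(
      cbind(data.frame(molecule = vapply(dataset$records, `[[`, "", "selfies")),
            as.data.frame(dataset$properties)),
      paths$labels, row.names = FALSE)
  } else say("reusing corpus")
  lab <- utils::read.csv(paths$labels, stringsAsFactors = FALSE)
  embed <- isTRUE(config$data$embed)
  records <- {
    smis <- vapply(lab$molecule, selfies_to_smiles, character(1), USE.NAMES = FALSE)
    ids <- ob_canonical(smis)
    graphs <- if (embed) embed3d_batch(lab$molecule,
                                       seed = stage_seed(config$seed, "data"))
              else vector("list", nrow(lab))
    lapply(seq_len(nrow(lab)), function(i) {
      g <- if (!is.null(graphs[[i]]))
        structure(list(atom_types = graphs[[i]]$element,
                       coords = graphs[[i]]$coords,
                       n_atoms = length(graphs[[i]]$element), seed = 0L),
                  class = "molecule_graph") else NULL
      structure(list(selfies = lab$molecule[i], smiles = smis[i],
                     canonical_id = ids[i], tokens = NULL, graph = g),
                class = "molecule_record")
    })
  }
  P <- as.matrix(lab[, setdiff(names(lab), "molecule"), drop = FALSE])
  dataset <- structure(list(records = records, properties = P,
                            names = colnames(P),
                            units = unname(DESCRIPTOR_UNITS[colnames(P)]),
                            stats = standardize_stats(P), n_unstable = 0L),
                       class = "labelled_dataset")

  # ---- stage: vae ------------------------------------------------------
  if (!file.exists(paths$vae)) {
    say("training VAE (", config$vae$epochs, " epochs)")
    vcfg <- vae_config(latent_dim = config$vae$latent_dim,
                       epochs = config$vae$epochs,
                       batch_size = config$vae$batch_size,
                       lr = config$vae$lr,
                       max_length = config$data$max_tokens,
                       seed = stage_seed(config$seed, "vae"))
    vae <- train_vae(dataset, vcfg)
    save_model(vae, paths$vae)
  } else say("reusing VAE")
  vae <- load_model(paths$vae)

  # ---- stage: reacquisition -------------------------------------------
  if (!file.exists(file.path(paths$dataset, "manifest.json"))) {
    say("reacquiring ", config$reacquisition$n_latents, " latent-property pairs")
    Z <- sample_prior_latents(config$reacquisition$n_latents,
                              vae$config$latent_dim,
                              seed = stage_seed(config$seed, "reacquisition"))
    dnew <- if (kind == "descriptors")
      reacquire(Z, vae, "descriptors",
                check_geometry = config$reacquisition$check_geometry,
                seed = stage_seed(config$seed, "reacquisition"))
    else
      reacquire(Z, vae, string_oracle,
                seed = stage_seed(config$seed, "reacquisition"))
    save_dataset(dnew, paths$dataset, oracle_name = kind)
  } else say("reusing reacquired dataset")
  dnew <- load_dataset(paths$dataset)

  # ---- stage: ensemble -------------------------------------------------
  if (!file.exists(paths$ensemble)) {
    say("training surrogate ensemble (", config$ensemble$epochs, " epochs)")
    ecfg <- ensemble_config(n_members = config$ensemble$n_members,
                            epochs = config$ensemble$epochs,
                            batch_size = config$ensemble$batch_size,
                            q = config$ensemble$q, lr = config$ensemble$lr,
                            seed = stage_seed(config$seed, "ensemble"))
    ens <- build_ensemble(ecfg, vae$config$latent_dim, ncol(dnew$properties))
    ens <- train_ensemble(ens, dnew)
    save_model(ens, paths$ensemble)
  } else say("reusing ensemble")
  ens <- load_model(paths$ensemble)

  # ---- stage: design ---------------------------------------------------
  if (!file.exists(paths$designs)) {
    prop <- config$design$property
    rng <- config$design$range
    if (is.null(rng))
      rng <- stats::quantile(dnew$properties[, prop], c(0.1, 0.9),
                             names = FALSE)
    grid <- target_grid(rng[1], rng[2], config$design$n_targets)
    say("designing ", length(grid), " targets on ", prop)
    results <- lapply(seq_along(grid), function(i) {
      req <- design_request(stats::setNames(grid[i], prop),
                            k = config$design$k,
                            steps = config$design$steps,
                            learning_rate = config$design$learning_rate,
                            uncertainty_weight = config$design$lambda,
                            seed = stage_seed(config$seed, "design") + i * 1000L)
      design_molecule(req, ens, vae)
    })
    results <- lapply(results, evaluate_design_oracle,
                      oracle = string_oracle, decoder = vae)
    write_design_csv(results, paths$designs)
    assign("last_results", results, envir = pipeline_cache)
  } else say("reusing designs")

  # ---- stage: evaluation ----------------------------------------------
  results <- get0("last_results", envir = pipeline_cache)
  if (is.null(results)) {
    tab <- read_design_csv(paths$designs)
    report <- report_from_table(tab, dataset)
  } else {
    ref <- vapply(dataset$records, `[[`, "", "canonical_id")
    report <- evaluation_report(results, ref)
  }
  writeLines(jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             paths$report)

  manifest <- list(
    package_version = as.character(utils::packageVersion("uncertmol")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = lapply(stats::setNames(nm = c("data", "vae", "reacquisition",
                                                "ensemble", "design")),
                         function(s) stage_seed(config$seed, s)),
    artifacts = lapply(paths[c("corpus", "labels", "vae", "ensemble",
                               "designs")],
                       function(p) if (file.exists(p))
                         unname(tools::md5sum(p)) else NA)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
                              na = "null"),
             paths$manifest)
  say("done: ", dir)
  invisible(list(dir = dir, report = report, paths = paths))
}

pipeline_cache <- new.env(parent = emptyenv())

# recompute the evaluation report from the persisted per-design table
report_from_table <- function(tab, dataset) {
  err_cols <- grep("^oracle_error_", names(tab), value = TRUE)
  ok <- !is.na(tab$oracle_status) & tab$oracle_status == "ok"
  mae <- colMeans(tab[ok, err_cols, drop = FALSE])
  names(mae) <- sub("^oracle_error_", "", err_cols)
  sur_cols <- grep("^surrogate_error_", names(tab), value = TRUE)
  smae <- colMeans(tab[ok, sur_cols, drop = FALSE])
  ref <- vapply(dataset$records, `[[`, "", "canonical_id")
  ids <- tab$canonical_id[!is.na(tab$canonical_id)]
  structure(list(
    nfp_mae = mae,
    novelty_pct = 100 * mean(!(ids %in% ref)),
    uniqueness_pct = 100 * length(unique(ids)) / length(ids),
    misalignment = abs(mae - stats::setNames(as.numeric(smae), names(mae))),
    n_designs = nrow(tab), n_unstable = sum(!ok)
  ), class = "evaluation_report")
}
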
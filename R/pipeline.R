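# One-config pipeline chaining simulate -> train -> predict -> fit-dr ->
# attribute -> interpret, with seeded manifests. The Rscript front-end lives
# in inst/cli/filmsens; every stage is also callable directly from R.

PIPELINE_STAGES <- c("simulate", "train", "predict", "fit-dr", "attribute",
                     "interpret")

pipeline_defaults <- function() {
  list(
    out_dir = "filmsens_run",
    seed = 1L,
    log_level = "info",
    simulate = list(),                       # simulation_config() overrides
    train = list(variant = "film", epochs = 30L, batch = 256L, lr = 2e-3,
                 straw = FALSE, concentration_transform = "log10uM"),
    predict = list(lines = "heldout"),
    `fit-dr` = list(rise_threshold = 0.2, min_points = 16L, floor = 0.4),
    attribute = list(steps = 50L),
    interpret = list(trials = 5L, n_null = 200L))
}

#' Validate and normalize a pipeline configuration file
#'
#' Reads a YAML config, fills documented defaults, and aggregates all schema
#' errors (unknown keys, duplicated stage blocks, bad values) instead of
#' failing on the first.
#'
#' @param path YAML file path.
#' @return A normalized `filmsens_pipeline_config` list, or an error listing
#'   every problem found.
#' @export
validate_config <- function(path) {
  if (!file.exists(path))
    stop_filmsens("config file not found: %s", path,
                  class = "filmsens_config_error")
  errors <- character(0)
  # yaml silently keeps the last duplicate mapping key; catch dups textually
  toplevel <- grep("^[A-Za-z][A-Za-z0-9_-]*:", readLines(path), value = TRUE)
  keys <- sub(":.*$", "", toplevel)
  if (anyDuplicated(keys))
    errors <- c(errors, sprintf("duplicated stage block(s): %s",
                                paste(unique(keys[duplicated(keys)]),
                                      collapse = ", ")))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    errors <<- c(errors, sprintf("YAML parse failure: %s", conditionMessage(e)))
    NULL
  })
  defaults <- pipeline_defaults()
  if (!is.null(raw)) {
    unknown <- setdiff(names(raw), names(defaults))
    if (length(unknown))
      errors <- c(errors, sprintf("unknown top-level key(s): %s",
                                  paste(unknown, collapse = ", ")))
    for (blk in intersect(names(raw), names(defaults))) {
      if (blk %in% c("out_dir", "seed", "log_level")) next
      if (!is.list(raw[[blk]]) && !is.null(raw[[blk]]))
        errors <- c(errors, sprintf("stage block '%s' must be a mapping", blk))
    }
    bad_seed <- !is.null(raw$seed) &&
      (!is.numeric(raw$seed) || raw$seed != as.integer(raw$seed))
    if (bad_seed) errors <- c(errors, "seed must be an integer")
  }
  if (length(errors))
    stop_filmsens("invalid pipeline config:\n- %s",
                  paste(errors, collapse = "\n- "),
                  class = "filmsens_config_error")
  cfg <- utils::modifyList(defaults, raw)
  structure(cfg, class = "filmsens_pipeline_config")
}

plog <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[filmsens %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

write_manifest <- function(out_dir, manifest) {
  # atomic: write to a temp file in the same directory, then rename
  tmp <- tempfile("manifest-", tmpdir = out_dir, fileext = ".json")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, file.path(out_dir, "manifest.json"))
}

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else
    list(format = "filmsens-manifest-1", stages = list())
}

need_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop_filmsens("stage '%s' needs missing upstream artifact: %s", stage, path,
                  class = "filmsens_pipeline_error")
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages consume and produce only files under the config's output directory;
#' deleting a downstream artifact and rerunning its stage reproduces it from
#' the upstream files. Every stage appends an entry (inputs, outputs, md5
#' hashes, seed, summary metrics) to `manifest.json`, written atomically.
#'
#' @param stage One of `"simulate"`, `"train"`, `"predict"`, `"fit-dr"`,
#'   `"attribute"`, `"interpret"`, or `"all"`.
#' @param config A `filmsens_pipeline_config` from [validate_config()].
#' @return Invisibly, the updated manifest.
#' @export
run_pipeline <- function(stage, config) {
  stopifnot(inherits(config, "filmsens_pipeline_config"))
  if (identical(stage, "all")) {
    for (s in PIPELINE_STAGES) run_pipeline(s, config)
    return(invisible(read_manifest(config$out_dir)))
  }
  if (!stage %in% PIPELINE_STAGES)
    stop_filmsens("unknown stage '%s'; stages: %s, all", stage,
                  paste(PIPELINE_STAGES, collapse = ", "),
                  class = "filmsens_usage_error")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- read_manifest(out)
  seed <- as.integer(config$seed)
  t0 <- Sys.time()
  entry <- list(seed = seed, started = format(t0, "%Y-%m-%d %H:%M:%S"))
  fp <- function(f) file.path(out, f)

  if (stage == "simulate") {
    plog(config, "simulate: generating benchmark dataset (seed %d)", seed)
    sim_over <- config$simulate
    for (nm in c("grid", "w_range"))   # YAML sequences arrive as lists
      if (!is.null(sim_over[[nm]])) sim_over[[nm]] <- as.numeric(unlist(sim_over[[nm]]))
    sim_cfg <- do.call(simulation_config,
                       utils::modifyList(list(seed = seed), sim_over))
    sim <- simulate(sim_cfg)
    write_fixture_bundle(sim$dataset, fp("data"))
    saveRDS(sim$truth, fp("data/truth.rds"))
    entry$outputs <- list.files(fp("data"))
  }

  if (stage == "train") {
    need_artifact(fp("data/manifest.json"), stage)
    bundle <- read_fixture_bundle(fp("data"))
    tc <- config$train
    plog(config, "train: %s variant, %d epochs", tc$variant, tc$epochs)
    fit <- train_benchmark(bundle, variant = tc$variant, seed = seed,
                           straw = isTRUE(tc$straw),
                           options = list(epochs = tc$epochs, batch = tc$batch,
                                          lr = tc$lr, seed = seed))
    save_model(fit$state, fp("model.rds"))
    utils::write.csv(data.frame(epoch = seq_along(fit$history$train_mse),
                                train_mse = fit$history$train_mse,
                                val_r2 = fit$history$val_r2),
                     fp("history.csv"), row.names = FALSE)
    entry$outputs <- c("model.rds", "history.csv")
    entry$metrics <- list(max_val_r2 = fit$history$max_val_r2,
                          best_epoch = fit$history$best_epoch)
  }

  if (stage == "predict") {
    need_artifact(fp("model.rds"), stage)
    bundle <- read_fixture_bundle(fp("data"))
    state <- load_model(fp("model.rds"))
    design <- benchmark_design(bundle,
                               concentration_transform = config$train$concentration_transform)
    lines <- if (identical(config$predict$lines, "heldout"))
      bundle$heldout_lines else config$predict$lines
    plog(config, "predict: %d lines x %d compounds over the default grid",
         length(lines), nrow(bundle$compounds))
    preds <- predict_response_grid(state, design$expr_z, design$fpmat, lines,
                                   bundle$compounds$compound_id,
                                   concentration_transform = design$transform)
    data.table::fwrite(preds, fp("predictions.csv"))
    entry$outputs <- "predictions.csv"
  }

  if (stage == "fit-dr") {
    need_artifact(fp("predictions.csv"), stage)
    preds <- data.table::fread(fp("predictions.csv"), data.table = FALSE)
    fd <- config$`fit-dr`
    pd <- pharmacodynamics(preds, rise_threshold = fd$rise_threshold,
                           min_points = fd$min_points, floor = fd$floor)
    data.table::fwrite(pd, fp("fits.csv"))
    entry$outputs <- "fits.csv"
    entry$metrics <- list(n_ok = sum(pd$qc_status == "ok"),
                          n_pairs = nrow(pd))
    plog(config, "fit-dr: %d/%d pairs passed QC", sum(pd$qc_status == "ok"),
         nrow(pd))
  }

  if (stage == "attribute") {
    need_artifact(fp("fits.csv"), stage)
    bundle <- read_fixture_bundle(fp("data"))
    state <- load_model(fp("model.rds"))
    design <- benchmark_design(bundle,
                               concentration_transform = config$train$concentration_transform)
    pd <- data.table::fread(fp("fits.csv"), data.table = FALSE)
    att <- attribute_at_ic50(state, design$expr_z, design$fpmat, pd,
                             steps = config$attribute$steps,
                             concentration_transform = design$transform)
    adj <- adjust_by_cell_line(att)
    write_attribution_tsv(att, fp("attributions_raw.tsv"))
    write_attribution_tsv(adj, fp("attributions_adjusted.tsv"))
    entry$outputs <- c("attributions_raw.tsv", "attributions_adjusted.tsv")
    entry$metrics <- list(n_attributed = nrow(att$meta),
                          n_skipped = nrow(att$skipped))
    plog(config, "attribute: %d pairs attributed, %d skipped",
         nrow(att$meta), nrow(att$skipped))
  }

  if (stage == "interpret") {
    need_artifact(fp("attributions_adjusted.tsv"), stage)
    bundle <- read_fixture_bundle(fp("data"))
    adj <- read_attribution_tsv(fp("attributions_adjusted.tsv"))
    moa <- bundle$moa
    labels <- moa$moa_class[match(adj$meta$compound_id, moa$compound_id)]
    k <- length(unique(labels))
    amis <- kmeans_ami(adj$matrix, labels, k = k,
                       trials = config$interpret$trials, seed = seed)
    daa_all <- lapply(sort(unique(labels)), function(cl)
      differential_attribution(adj$matrix, labels == cl))
    names(daa_all) <- sort(unique(labels))
    for (cl in names(daa_all))
      data.table::fwrite(daa_all[[cl]], fp(sprintf("daa_%s.csv", cl)))
    graph <- read_ppi_tsv(fp("data/ppi.tsv"))
    genes <- colnames(adj$matrix)
    all_targets <- unique(unlist(moa$targets))
    conn <- lapply(split(moa$targets, moa$moa_class), function(tl) {
      set <- unique(unlist(tl))
      module_connectivity(graph, set, n_null = config$interpret$n_null,
                          seed = seed,
                          null_pools = list(targets = all_targets,
                                            genes = genes))
    })
    report <- list(
      kmeans_ami = amis,
      connectivity = lapply(conn, function(cr)
        list(observed = cr$observed, edges = cr$edges,
             p_targets = unname(cr$p["targets"]),
             p_genes = unname(cr$p["genes"]))))
    jsonlite::write_json(report, fp("interpret.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    entry$outputs <- c("interpret.json", sprintf("daa_%s.csv", names(daa_all)))
    entry$metrics <- list(mean_ami = mean(amis))
    plog(config, "interpret: mean K-means AMI vs MOA classes = %.3f", mean(amis))
  }

  entry$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  entry$md5 <- as.list(tools::md5sum(file.path(out, unlist(entry$outputs))))
  manifest$stages[[stage]] <- entry
  manifest$version <- as.character(utils::packageVersion("filmsens"))
  write_manifest(out, manifest)
  invisible(manifest)
}
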
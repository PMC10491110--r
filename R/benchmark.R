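# End-to-end orchestration of the synthetic benchmark: featurization from a
# simulated dataset, line-held-out training of any variant, grid prediction,
# and pharmacodynamic evaluation against the planted truth.

#' Build train/held-out design matrices from a simulated dataset
#'
#' Standardizes expression on the training lines only, assembles compound
#' feature vectors (true or straw fingerprints), and splits the viability
#' table by the dataset's line split.
#'
#' @param dataset The `dataset` element of [simulate()] (or a bundle from
#'   [read_fixture_bundle()] with a `train_lines`/`heldout_lines` split).
#' @param straw Replace fingerprints with structure-ablating random ones.
#' @param straw_seed Seed for the straw fingerprints.
#' @param concentration_transform Concentration featurization; the benchmark
#'   default is log10 uM, the scale of the log-logistic response process.
#' @return List `train_set`, `val_set` (each `X`, `U`, `y`, `cell_line_id`,
#'   `compound_id`), `expr_z`, `fpmat`, `stats`, `genes`, `transform`.
#' @export
benchmark_design <- function(dataset, straw = FALSE, straw_seed = 1L,
                             concentration_transform = "log10uM") {
  stats <- fit_standardization(dataset$expression[dataset$train_lines, , drop = FALSE])
  expr_z <- apply_standardization(dataset$expression, stats)
  fpmat <- if (straw)
    make_straw_fingerprints(dataset$compounds$compound_id, seed = straw_seed)
  else {
    m <- do.call(rbind, dataset$compounds$fingerprint)
    rownames(m) <- dataset$compounds$compound_id
    m
  }
  viab <- dataset$viability
  tr <- viab$cell_line_id %in% dataset$train_lines
  d_train <- build_design(expr_z, fpmat, viab[tr, , drop = FALSE],
                          concentration_transform)
  d_val <- build_design(expr_z, fpmat, viab[!tr, , drop = FALSE],
                        concentration_transform)
  list(train_set = d_train, val_set = d_val, expr_z = expr_z, fpmat = fpmat,
       stats = stats, genes = colnames(expr_z),
       transform = concentration_transform)
}

#' Train one variant on the benchmark split
#'
#' @param dataset As in [benchmark_design()].
#' @param variant Model variant.
#' @param seed Seed for initialization, batching, and (with `straw`) the
#'   straw fingerprints — identical folds and schedule across variants so the
#'   comparison isolates the architecture/featurization.
#' @param straw Use structure-ablating random fingerprints.
#' @param options Training options (see [train()]); benchmark defaults:
#'   30 epochs, batch 256, lr 2e-3, input-gate L1 0.1 at gate step size 0.01
#'   (the sparse-input regularizer that makes the planted gene-driver rule
#'   identifiable from few training lines).
#' @param config Optional `filmsens_config` overriding the default
#'   architecture (g = 64, c = 32, 2 FiLM layers, trunk 64-32, dropout 0.1).
#' @return List `state`, `history`, `design`.
#' @export
train_benchmark <- function(dataset, variant = "film", seed = 1L,
                            straw = FALSE, options = list(), config = NULL) {
  design <- benchmark_design(dataset, straw = straw, straw_seed = seed)
  cfg <- config %||% model_config(variant, n_genes = length(design$genes))
  state <- init_model(cfg, seed = seed, genes = design$genes,
                      stats = design$stats)
  opts <- utils::modifyList(list(epochs = 30L, batch = 256L, lr = 2e-3,
                                 l1_gate = 0.1, lr_gate = 0.01, seed = seed),
                            options)
  fit <- train(state, design$train_set, design$val_set, opts)
  list(state = fit$state, history = fit$history, design = design)
}

#' Predict a viability grid for (line, compound) pairs
#'
#' Evaluates the model over a concentration grid for every combination of the
#' given lines and compounds, producing the long prediction table consumed by
#' [pharmacodynamics()].
#'
#' @param states A `filmsens_model` or list of them (one `pred_*` column
#'   each).
#' @param expr_z Standardized expression matrix.
#' @param fpmat Fingerprint matrix with compound rownames.
#' @param lines,compounds Ids to cross.
#' @param grid Concentration grid (uM).
#' @param concentration_transform Featurization of concentration; must match
#'   training.
#' @return Data.frame `compound_id, cell_line_id, concentration_uM, pred_*`.
#' @export
predict_response_grid <- function(states, expr_z, fpmat, lines, compounds,
                                  grid = default_grid(),
                                  concentration_transform = "log10uM") {
  if (inherits(states, "filmsens_model")) states <- list(states)
  tab <- expand.grid(cell_line_id = lines, compound_id = compounds,
                     concentration_uM = grid,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$viability <- 0  # placeholder for design assembly
  d <- build_design(expr_z, fpmat, tab, concentration_transform)
  preds <- ensemble_predict(states, d$X, d$U)
  cbind(tab[, c("compound_id", "cell_line_id", "concentration_uM")], preds)
}

#' Evaluate predicted IC50s against the planted truth
#'
#' Fits the dose-response pipeline to model predictions on the held-out lines
#' and reports the Spearman correlation between predicted and true log10
#' IC50 across surviving pairs.
#'
#' @param state Trained model.
#' @param design Output of [benchmark_design()].
#' @param dataset,truth From [simulate()].
#' @param grid Prediction grid.
#' @return List `spearman`, `pd` (pharmacodynamics table with
#'   `true_log10_ic50`), `n_pairs`.
#' @export
evaluate_ic50_recovery <- function(state, design, dataset, truth,
                                   grid = default_grid()) {
  preds <- predict_response_grid(state, design$expr_z, design$fpmat,
                                 dataset$heldout_lines,
                                 dataset$compounds$compound_id, grid,
                                 design$transform)
  pd <- pharmacodynamics(preds)
  pd$true_log10_ic50 <- truth$log10_ic50[cbind(pd$cell_line_id, pd$compound_id)]
  ok <- pd$qc_status == "ok" & is.finite(pd$ic50)
  rho <- stats::cor(log10(pd$ic50[ok]), pd$true_log10_ic50[ok],
                    method = "spearman")
  list(spearman = rho, pd = pd, n_pairs = sum(ok))
}

#' Run the full synthetic benchmark study for one seed
#'
#' Generates the default benchmark dataset, trains all four architecture
#' variants plus the structure-ablated straw control under one shared
#' schedule, and evaluates the complete downstream pipeline on the trained
#' FiLM model: held-out IC50 recovery, IC50-anchored attributions, driver
#' recovery by differential attribution, K-means/AMI against the planted MOA
#' classes (with fingerprint, random-initialization, and permuted-label
#' baselines), attribution soundness correlations, integrated-gradients
#' completeness, PPI-module connectivity of the planted driver modules, and
#' the in-silico knockout contrast.
#'
#' @param seed Integer seed; fixes the dataset, initializations, batching,
#'   and permutation controls.
#' @param options Training options shared by every variant (see
#'   [train_benchmark()]).
#' @param variants Variants to train besides the straw control.
#' @param n_null Null draws per pool for module connectivity.
#' @return A list of study metrics (see the fields set below).
#' @export
benchmark_study <- function(seed, options = list(),
                            variants = c("film", "scale", "shift",
                                         "concatenation"),
                            n_null = 500L) {
  sim <- simulate(simulation_config(seed = seed))
  ds <- sim$dataset; truth <- sim$truth
  fits <- lapply(variants, function(v)
    train_benchmark(ds, variant = v, seed = seed, options = options))
  names(fits) <- variants
  fits$straw <- train_benchmark(ds, variant = "film", seed = seed,
                                straw = TRUE, options = options)
  out <- list(seed = seed,
              r2 = vapply(fits, function(f) f$history$max_val_r2, numeric(1)))
  film <- fits$film
  ev <- evaluate_ic50_recovery(film$state, film$design, ds, truth)
  out$spearman <- ev$spearman
  out$n_pairs <- ev$n_pairs

  att <- attribute_at_ic50(film$state, film$design$expr_z, film$design$fpmat,
                           ev$pd, concentration_transform = film$design$transform)
  adj <- adjust_by_cell_line(att)
  labels <- truth$moa_class[adj$meta$compound_id]

  # driver recovery: per class, top-10 DAA genes vs planted drivers
  hits <- 0L; total <- 0L
  for (k in names(truth$drivers)) {
    total <- total + length(truth$drivers[[k]])
    if (!any(labels == k)) next
    daa <- differential_attribution(adj$matrix, labels == k)
    hits <- hits + sum(truth$drivers[[k]] %in% top_markers(daa, 10L))
  }
  out$driver_recovery <- hits / total

  # connectivity of planted modules against both nulls
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  data.table::fwrite(ds$ppi, tmp, sep = "\t")
  graph <- read_ppi_tsv(tmp)
  pools <- list(targets = unique(unlist(ds$moa$targets)),
                genes = colnames(film$design$expr_z))
  out$connectivity_above95 <- mean(vapply(names(truth$drivers), function(k) {
    cr <- module_connectivity(graph, truth$drivers[[k]], n_null = n_null,
                              seed = derive_seed(seed, match(k, names(truth$drivers))),
                              null_pools = pools)
    all(vapply(cr$null, function(ns)
      cr$observed > stats::quantile(ns, 0.95), logical(1)))
  }, logical(1)))

  # K-means AMI of adjusted attributions vs planted classes, with baselines
  k <- length(unique(labels))
  out$ami <- c(
    attributions = mean(kmeans_ami(adj$matrix, labels, k = k, trials = 5L,
                                   seed = seed)),
    fingerprints = mean(kmeans_ami(film$design$fpmat[adj$meta$compound_id, ],
                                   labels, k = k, trials = 5L, seed = seed)))

  sc <- soundness_checks(film$state, film$design$expr_z, film$design$fpmat,
                         ev$pd, film$design$train_set, film$design$val_set,
                         options = utils::modifyList(
                           list(epochs = 30L, batch = 256L, lr = 2e-3,
                                l1_gate = 0.1, lr_gate = 0.01, seed = seed),
                           options),
                         seed = seed,
                         concentration_transform = film$design$transform)
  out$soundness <- sc$correlations
  for (nm in names(sc$controls)) {
    out$ami[[paste0("control_", nm)]] <- tryCatch({
      ca <- attribute_at_ic50(sc$controls[[nm]], film$design$expr_z,
                              film$design$fpmat, ev$pd,
                              concentration_transform = film$design$transform)
      mean(kmeans_ami(adjust_by_cell_line(ca)$matrix, labels, k = k,
                      trials = 5L, seed = seed))
    }, error = function(e) NA_real_)
  }

  # integrated-gradients completeness at 500 steps over a sample of pairs
  set.seed(derive_seed(seed, 55L))
  take <- sample(nrow(adj$meta), min(12L, nrow(adj$meta)))
  gaps <- t(vapply(take, function(i) {
    x <- film$design$expr_z[adj$meta$cell_line_id[i], ]
    u <- make_compound_features(film$design$fpmat[adj$meta$compound_id[i], ],
                                adj$meta$concentration_used[i],
                                transform = film$design$transform)
    ig <- integrated_gradients(film$state, x, u, steps = 500L)
    c(gap = ig$completeness_gap,
      bound = 1e-3 * abs(ig$prediction - ig$baseline_prediction) + 1e-6)
  }, numeric(2)))
  out$completeness_gap <- stats::median(gaps[, "gap"])
  out$completeness_bound <- stats::median(gaps[, "bound"])

  # knockout of the strongest protective driver of the first class
  k1 <- names(truth$drivers)[1L]
  w1 <- truth$weights[[k1]]
  driver <- names(w1)[which.max(w1)]
  cpds <- names(truth$moa_class)[truth$moa_class == k1]
  ko_expr <- knockout(film$design$expr_z, driver, rows = ds$heldout_lines)
  pd_wt <- pharmacodynamics(predict_response_grid(
    film$state, film$design$expr_z, film$design$fpmat, ds$heldout_lines, cpds,
    concentration_transform = film$design$transform))
  pd_ko <- pharmacodynamics(predict_response_grid(
    film$state, ko_expr, film$design$fpmat, ds$heldout_lines, cpds,
    concentration_transform = film$design$transform))
  m <- merge(pd_wt[, c("compound_id", "cell_line_id", "ic50", "qc_status")],
             pd_ko[, c("compound_id", "cell_line_id", "ic50", "qc_status")],
             by = c("compound_id", "cell_line_id"), suffixes = c("_wt", "_ko"))
  usable <- m$qc_status_wt == "ok" & m$qc_status_ko == "ok" &
    is.finite(m$ic50_wt) & is.finite(m$ic50_ko)
  out$knockout_fraction_lower <- mean(m$ic50_ko[usable] < m$ic50_wt[usable])
  out$knockout_n <- sum(usable)
  out$film <- film
  out$sim <- sim
  out
}
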
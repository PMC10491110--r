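# Integrated-gradients attribution at the predicted IC50, per-cell-line
# adjustment, and the random-init / permuted-label soundness controls.

#' Integrated gradients for an arbitrary differentiable function
#'
#' Core Riemann-sum implementation used by [integrated_gradients()]. The
#' gradient callback receives the interpolated inputs for all steps at once
#' and must return per-row input gradients.
#'
#' @param grad_fn `function(X, U)` returning `list(dX, dU)` of per-row
#'   gradients of the scalar output.
#' @param x,u Query input vectors.
#' @param x0,u0 Baselines (default zero vectors).
#' @param steps Number of interpolation steps m.
#' @param scheme `"midpoint"` (default; its completeness gap shrinks as
#'   1/steps^2) or `"right"` (right-endpoint sum, parity with step-summing
#'   implementations).
#' @return List `gene` (= `(x - x0) * mean path gradient`) and `compound`.
#' @export
ig_core <- function(grad_fn, x, u, x0 = NULL, u0 = NULL, steps = 50L,
                    scheme = c("midpoint", "right")) {
  scheme <- match.arg(scheme)
  if (steps < 1L) stop_filmsens("steps must be >= 1", class = "filmsens_input_error")
  x0 <- x0 %||% numeric(length(x))
  u0 <- u0 %||% numeric(length(u))
  alphas <- if (scheme == "right") seq_len(steps) / steps
            else (seq_len(steps) - 0.5) / steps
  Xs <- outer(alphas, x - x0) + bcast(x0, steps)
  Us <- outer(alphas, u - u0) + bcast(u0, steps)
  g <- grad_fn(Xs, Us)
  if (any(!is.finite(g$dX)) || any(!is.finite(g$dU)))
    stop_filmsens("non-finite gradients during integrated-gradients path",
                  class = "filmsens_attribution_error")
  list(gene = (x - x0) * colMeans(g$dX),
       compound = (u - u0) * colMeans(g$dU))
}

#' Integrated-gradients attribution of one model prediction
#'
#' Path-integral attribution from zero-vector baselines for both the
#' expression and compound inputs, with `steps` linearly interpolated
#' points (evaluation-mode gradients). The completeness gap
#' `|sum(IG) - (F(x,u) - F(x0,u0))|` is returned and shrinks as `steps`
#' grows.
#'
#' @param state A trained `filmsens_model`.
#' @param expression Z-scored expression vector over the training genes.
#' @param compound 513-length compound feature vector.
#' @param steps Interpolation steps (default 50).
#' @param scheme Riemann scheme, see [ig_core()].
#' @return List `gene` (length n_genes), `compound` (length 513),
#'   `completeness_gap`, `prediction`, `baseline_prediction`.
#' @export
integrated_gradients <- function(state, expression, compound, steps = 50L,
                                 scheme = "midpoint") {
  stopifnot(inherits(state, "filmsens_model"))
  grad_fn <- function(Xs, Us) {
    fw <- model_forward(state, Xs, Us, mode = "eval", keep_cache = TRUE)
    bw <- model_backward(state, fw$cache, rep(1, nrow(Xs)))
    list(dX = bw$dX, dU = bw$dU)
  }
  ig <- ig_core(grad_fn, expression, compound, steps = steps, scheme = scheme)
  f_x <- model_forward(state, matrix(expression, 1L), matrix(compound, 1L))$y
  f_0 <- model_forward(state, matrix(0, 1L, length(expression)),
                       matrix(0, 1L, length(compound)))$y
  ig$completeness_gap <- abs(sum(ig$gene) + sum(ig$compound) - (f_x - f_0))
  ig$prediction <- f_x
  ig$baseline_prediction <- f_0
  ig
}

#' Gene attributions at the predicted IC50 for all QC-passing pairs
#'
#' For every (cell line, compound) pair whose pharmacodynamic summary has
#' `qc_status == "ok"` and a defined IC50, computes integrated gradients at
#' that IC50 and extracts the gene part of the attribution. Pairs without a
#' usable IC50 are skipped with a reason.
#'
#' @param state A trained `filmsens_model` (the attribution model; with an
#'   ensemble, conventionally the best-validation member).
#' @param expression_z Z-scored expression matrix (lines x training genes).
#' @param compounds Compound table (or fingerprint matrix with compound
#'   rownames).
#' @param pharmacodynamics Output of [pharmacodynamics()].
#' @param steps,scheme Passed to [integrated_gradients()].
#' @param concentration_transform How concentrations enter the feature
#'   vector; must match the training featurization.
#' @return A `filmsens_attribution` list: `matrix` (pairs x genes), `meta`
#'   (data.frame `cell_line_id, compound_id, concentration_used`),
#'   `normalization = "raw"`, and `skipped`.
#' @export
attribute_at_ic50 <- function(state, expression_z, compounds, pharmacodynamics,
                              steps = 50L, scheme = "midpoint",
                              concentration_transform = c("uM", "log10uM")) {
  concentration_transform <- match.arg(concentration_transform)
  fps <- if (is.matrix(compounds)) compounds else {
    m <- do.call(rbind, compounds$fingerprint); rownames(m) <- compounds$compound_id; m
  }
  pd <- pharmacodynamics
  ok <- pd$qc_status == "ok" & is.finite(pd$ic50)
  skipped <- data.frame(cell_line_id = pd$cell_line_id[!ok],
                        compound_id = pd$compound_id[!ok],
                        reason = ifelse(pd$qc_status[!ok] != "ok",
                                        pd$qc_status[!ok], "ic50_undefined"))
  pd <- pd[ok, , drop = FALSE]
  if (!nrow(pd))
    stop_filmsens("no (cell line, compound) pair survived QC with a defined IC50",
                  class = "filmsens_empty_result_error")
  rows <- matrix(NA_real_, nrow(pd), state$config$n_genes,
                 dimnames = list(NULL, colnames(expression_z)))
  for (i in seq_len(nrow(pd))) {
    x <- expression_z[pd$cell_line_id[i], ]
    u <- make_compound_features(fps[pd$compound_id[i], ], pd$ic50[i],
                                transform = concentration_transform)
    rows[i, ] <- integrated_gradients(state, x, u, steps = steps,
                                      scheme = scheme)$gene
  }
  structure(list(matrix = rows,
                 meta = data.frame(cell_line_id = pd$cell_line_id,
                                   compound_id = pd$compound_id,
                                   concentration_used = pd$ic50),
                 normalization = "raw", skipped = skipped),
            class = "filmsens_attribution")
}

#' Adjust attributions for cell-line effects
#'
#' Standardizes attributions within each cell line: by default every gene
#' column is z-scored across that line's compound records (removing
#' line-level gene effects); `convention = "per_vector"` instead z-scores
#' each record's attribution vector across genes. Zero-variance entries map
#' to 0; lines with a single record are passed through as zeros and flagged.
#'
#' @param attribution A raw `filmsens_attribution`.
#' @param convention `"per_gene"` (default) or `"per_vector"`.
#' @return A `filmsens_attribution` with `normalization = "adjusted"` and a
#'   `single_record_lines` field.
#' @export
adjust_by_cell_line <- function(attribution, convention = c("per_gene", "per_vector")) {
  convention <- match.arg(convention)
  stopifnot(inherits(attribution, "filmsens_attribution"))
  m <- attribution$matrix
  out <- m * 0
  singles <- character(0)
  for (line in unique(attribution$meta$cell_line_id)) {
    i <- which(attribution$meta$cell_line_id == line)
    if (length(i) == 1L) { singles <- c(singles, line); next }
    blk <- m[i, , drop = FALSE]
    if (convention == "per_gene") {
      mu <- colMeans(blk)
      sig <- sqrt(col_vars(blk) * length(i) / (length(i) - 1L))
      z <- (blk - bcast(mu, length(i))) / bcast(ifelse(sig < 1e-12, 1, sig), length(i))
      z[, sig < 1e-12] <- 0
    } else {
      z <- t(apply(blk, 1L, function(r) {
        s <- sd(r); if (!is.finite(s) || s < 1e-12) r * 0 else (r - mean(r)) / s
      }))
    }
    out[i, ] <- z
  }
  structure(list(matrix = out, meta = attribution$meta,
                 normalization = "adjusted", convention = convention,
                 single_record_lines = singles,
                 skipped = attribution$skipped),
            class = "filmsens_attribution")
}

#' Write / read an attribution table
#'
#' TSV layout: a `# normalization: <tag>` comment line, then
#' `cell_line_id  compound_id  concentration_used` followed by one column per
#' gene.
#'
#' @param attribution A `filmsens_attribution`.
#' @param path File path.
#' @export
write_attribution_tsv <- function(attribution, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalization: %s", attribution$normalization), con)
  df <- cbind(attribution$meta, as.data.frame(attribution$matrix))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_attribution_tsv
#' @export
read_attribution_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  tag <- sub("^# normalization: *", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1L,
                          check.names = FALSE)
  structure(list(matrix = as.matrix(df[, -(1:3), drop = FALSE]),
                 meta = df[, 1:3],
                 normalization = tag, skipped = NULL),
            class = "filmsens_attribution")
}

flat_cor <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || !isTRUE(stats::sd(a) > 1e-15) ||
      !isTRUE(stats::sd(b) > 1e-15)) return(NA_real_)
  stats::cor(a, b)
}

#' Attribution soundness checks against control models
#'
#' Builds the two standard controls — an architecturally identical model with
#' randomly initialized parameters, and one trained on permuted viability
#' labels with the same schedule — then computes raw and adjusted attribution
#' matrices for the true model and both controls on identical pairs and
#' reports Pearson correlations of the true model's attributions against the
#' transcriptome inputs and against each control's attributions. A sound
#' attribution should decorrelate from all three after adjustment.
#'
#' @param state The trained `filmsens_model` under test.
#' @param expression_z,compounds,pharmacodynamics As in [attribute_at_ic50()].
#' @param train_set,val_set,options Training data/schedule for the
#'   permuted-label control (identical to the true model's schedule).
#' @param seed Seed controlling the control models and the permutation.
#' @param threshold Soundness pass threshold on adjusted-vs-control |r|.
#' @param concentration_transform Featurization of concentration.
#' @return A `filmsens_soundness` list: `correlations` (data.frame with
#'   `comparison`, `raw_r`, `adjusted_r`), `pass`, and the control states.
#' @export
soundness_checks <- function(state, expression_z, compounds, pharmacodynamics,
                             train_set, val_set, options = list(), seed = 1L,
                             threshold = 0.2,
                             concentration_transform = c("uM", "log10uM")) {
  concentration_transform <- match.arg(concentration_transform)
  rand_state <- init_model(state$config, seed = derive_seed(seed, 101L),
                           genes = state$genes, stats = state$stats)
  set.seed(derive_seed(seed, 202L))
  perm_train <- train_set
  perm_train$y <- sample(train_set$y)
  perm_opts <- options
  perm_opts$seed <- derive_seed(seed, 303L)
  perm_fit <- tryCatch(
    train(init_model(state$config, seed = derive_seed(seed, 404L),
                     genes = state$genes, stats = state$stats),
          perm_train, val_set, perm_opts),
    filmsens_training_diverged_error = function(e) NULL)
  inconclusive <- is.null(perm_fit)
  att <- function(s) attribute_at_ic50(
    s, expression_z, compounds, pharmacodynamics,
    concentration_transform = concentration_transform)
  raw_true <- att(state)
  adj_true <- adjust_by_cell_line(raw_true)
  # lines with a single attributed record adjust to all-zero rows; they carry
  # no information for the correlation checks and are excluded
  keep <- !(raw_true$meta$cell_line_id %in% adj_true$single_record_lines)
  rows_of <- function(a) a$matrix[keep, , drop = FALSE]
  expr_rows <- expression_z[raw_true$meta$cell_line_id[keep], , drop = FALSE]
  raw_rand <- att(rand_state); adj_rand <- adjust_by_cell_line(raw_rand)
  cors <- data.frame(
    comparison = c("transcriptome", "random_init",
                   if (!inconclusive) "permuted_labels"),
    raw_r = c(flat_cor(rows_of(raw_true), expr_rows),
              flat_cor(rows_of(raw_true), rows_of(raw_rand)),
              if (!inconclusive) NA_real_),
    adjusted_r = c(flat_cor(rows_of(adj_true), expr_rows),
                   flat_cor(rows_of(adj_true), rows_of(adj_rand)),
                   if (!inconclusive) NA_real_))
  controls <- list(random_init = rand_state)
  if (!inconclusive) {
    raw_perm <- att(perm_fit$state); adj_perm <- adjust_by_cell_line(raw_perm)
    cors$raw_r[3L] <- flat_cor(rows_of(raw_true), rows_of(raw_perm))
    cors$adjusted_r[3L] <- flat_cor(rows_of(adj_true), rows_of(adj_perm))
    controls$permuted <- perm_fit$state
  }
  ctrl <- cors$comparison != "transcriptome"
  structure(list(correlations = cors,
                 pass = !inconclusive && all(abs(cors$adjusted_r[ctrl]) < threshold),
                 inconclusive = inconclusive,
                 threshold = threshold,
                 controls = controls),
            class = "filmsens_soundness")
}
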
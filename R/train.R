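# Training: cell-line-stratified folds, MSE optimization with validation-R2
# tracking and best-epoch checkpointing, ensembling, seeded random
# hyperparameter search.

#' Assign cell lines to cross-validation folds
#'
#' Stratifies by cell line so every sample of a line inherits that line's
#' fold — the leakage guard for line-held-out evaluation. Fold line-counts
#' differ by at most one.
#'
#' @param cell_line_ids Character vector of cell line ids (duplicates allowed;
#'   folds are assigned to distinct lines).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Named integer vector mapping each distinct line to a fold in
#'   `0:(k-1)`, with attribute `k`.
#' @export
assign_folds <- function(cell_line_ids, k = 5L, seed = 1L) {
  lines <- unique(cell_line_ids)
  if (length(lines) < k)
    stop_filmsens("%d distinct lines cannot fill %d folds", length(lines), k,
                  class = "filmsens_input_error")
  set.seed(as.integer(seed))
  shuffled <- sample(lines)
  folds <- (seq_along(shuffled) - 1L) %% k
  names(folds) <- shuffled
  folds <- folds[lines]
  attr(folds, "k") <- as.integer(k)
  folds
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, skip = character(0)) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in setdiff(names(grads), skip)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

#' Train a model by mini-batch MSE descent
#'
#' Trains with Adam on mean-squared error between predicted and true
#' viability, recording per-epoch training MSE and validation R-squared. The
#' returned state is the checkpoint with the maximum validation R-squared.
#' Train and validation sets must not share cell lines.
#'
#' @param state An initialized `filmsens_model`.
#' @param train_set,val_set Lists with `X` (n x genes z-scores), `U`
#'   (n x 513 compound features), `y` (viability), and optionally
#'   `cell_line_id` (checked for leakage when present in both sets).
#' @param options List: `epochs` (default 30), `batch` (256), `lr` (2e-3),
#'   `l1_gate` (0; L1 proximal shrinkage of the per-gene input gate, the
#'   sparse-input regularizer for few-lines/many-genes training), `seed` (1).
#' @return List `state` (best checkpoint) and `history`
#'   (`filmsens_history`: per-epoch `train_mse`, `val_r2`, `best_epoch`,
#'   `max_val_r2`).
#' @export
train <- function(state, train_set, val_set, options = list()) {
  stopifnot(inherits(state, "filmsens_model"))
  epochs <- options$epochs %||% 30L
  batch <- options$batch %||% 256L
  lr <- options$lr %||% 2e-3
  l1_gate <- options$l1_gate %||% 0
  lr_gate <- options$lr_gate %||% 0.01
  seed <- options$seed %||% 1L
  if (!is.null(train_set$cell_line_id) && !is.null(val_set$cell_line_id)) {
    shared <- intersect(unique(train_set$cell_line_id),
                        unique(val_set$cell_line_id))
    if (length(shared))
      stop_filmsens("train and validation share cell line(s): %s",
                    paste(utils::head(shared, 5L), collapse = ", "),
                    class = "filmsens_leakage_error")
  }
  n <- nrow(train_set$X)
  set.seed(as.integer(seed))
  opt <- adam_init(state$params)
  train_mse <- val_r2 <- numeric(epochs)
  best <- list(r2 = -Inf, params = state$params, bn = state$bn, epoch = 0L)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch)) {
      b <- idx[start:min(start + batch - 1L, n)]
      fw <- model_forward(state, train_set$X[b, , drop = FALSE],
                          train_set$U[b, , drop = FALSE],
                          mode = "train", keep_cache = TRUE)
      for (nm in names(fw$bn_new)) state$bn[[nm]] <- fw$bn_new[[nm]]
      resid <- fw$y - train_set$y[b]
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop_filmsens("training diverged (non-finite loss) at epoch %d", ep,
                      class = "filmsens_training_diverged_error")
      losses <- c(losses, loss)
      bw <- model_backward(state, fw$cache, 2 * resid / length(b))
      st <- adam_step(state$params, bw$grads, opt, lr,
                      skip = if (l1_gate > 0) "gate")
      state$params <- st$params; opt <- st$opt
      if (l1_gate > 0) {
        # the gate trains by plain proximal gradient descent, not Adam:
        # Adam's per-parameter normalization would let uninformative genes
        # resist the L1 shrinkage as strongly as informative ones
        gt <- state$params$gate - lr_gate * bw$grads$gate
        state$params$gate <- sign(gt) * pmax(abs(gt) - lr_gate * l1_gate, 0)
      }
    }
    train_mse[ep] <- mean(losses)
    pred <- model_forward(state, val_set$X, val_set$U, mode = "eval")$y
    val_r2[ep] <- r_squared(pred, val_set$y)
    if (!is.finite(val_r2[ep]))
      stop_filmsens("training diverged (non-finite validation R2) at epoch %d",
                    ep, class = "filmsens_training_diverged_error")
    if (val_r2[ep] > best$r2)
      best <- list(r2 = val_r2[ep], params = state$params, bn = state$bn,
                   epoch = ep)
  }
  state$params <- best$params
  state$bn <- best$bn
  history <- structure(list(train_mse = train_mse, val_r2 = val_r2,
                            best_epoch = best$epoch, max_val_r2 = best$r2),
                       class = "filmsens_history")
  list(state = state, history = history)
}

#' Per-model ensemble predictions
#'
#' Runs each state's evaluation-mode forward pass and returns one prediction
#' column per model; no averaging is performed here, downstream consumers
#' decide pooling.
#'
#' @param states List of `filmsens_model` objects sharing the training gene
#'   list.
#' @param X,U Design matrices as in [train()].
#' @return Data.frame with columns `pred_1 .. pred_k`.
#' @export
ensemble_predict <- function(states, X, U) {
  stopifnot(length(states) >= 1L)
  glists <- lapply(states, function(s) s$genes)
  if (length(unique(vapply(glists, paste, "", collapse = "\r"))) != 1L)
    stop_filmsens("ensemble members disagree on the training gene list",
                  class = "filmsens_ensemble_error")
  preds <- lapply(states, function(s) forward_viability(s, X, U))
  out <- as.data.frame(preds, col.names = paste0("pred_", seq_along(states)))
  names(out) <- paste0("pred_", seq_along(states))
  out
}

#' Seeded random hyperparameter search
#'
#' Draws `budget` configurations uniformly from the space (a named list;
#' numeric length-2 elements are treated as ranges, anything else as a choice
#' set) and maximizes `objective`. Trials whose objective is non-finite are
#' marked failed and the search continues.
#'
#' @param space Named list of ranges/choices; all non-empty.
#' @param budget Number of trials.
#' @param objective Function taking one sampled configuration (named list)
#'   and returning a finite score to maximize.
#' @param seed Integer seed.
#' @return List `best` (configuration), `best_score`, and `trials`
#'   (data.frame log with one row per trial).
#' @export
random_search <- function(space, budget = 20L, objective, seed = 1L) {
  if (budget < 1L) stop_filmsens("budget must be >= 1", class = "filmsens_input_error")
  if (!length(space) || any(!lengths(space)))
    stop_filmsens("all hyperparameter ranges must be non-empty",
                  class = "filmsens_input_error")
  set.seed(as.integer(seed))
  draws <- lapply(seq_len(budget), function(i)
    lapply(space, function(rng) {
      if (is.numeric(rng) && length(rng) == 2L && rng[1] < rng[2])
        stats::runif(1L, rng[1], rng[2])
      else rng[[sample.int(length(rng), 1L)]]
    }))
  scores <- vapply(draws, function(cfg) {
    s <- tryCatch(objective(cfg), error = function(e) NA_real_)
    if (!is.finite(s)) NA_real_ else s
  }, numeric(1L))
  trials <- data.frame(trial = seq_len(budget),
                       score = scores,
                       failed = !is.finite(scores))
  for (nm in names(space))
    trials[[nm]] <- vapply(draws, function(d) format(d[[nm]]), "")
  if (all(trials$failed))
    stop_filmsens("every hyperparameter trial failed", class = "filmsens_input_error")
  best_i <- which.max(scores)
  list(best = draws[[best_i]], best_score = scores[best_i], trials = trials)
}
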
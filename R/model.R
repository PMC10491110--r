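# Conditional viability model y = f(x | n).
#
# Architecture: an inputs encoder embeds z-scored expression (length
# n_genes) into a length-g vector; a conditional encoder embeds the
# 513-length compound feature vector into a length-c vector; a FiLM
# generator predicts per-layer (gamma, beta) of length g from the compound
# embedding; each FiLM layer applies h <- gamma * h + beta followed by a
# linear block (linear, ReLU, batch normalization, dropout); the modulated
# embedding then passes through a linear trunk ending in a length-1 output.
# Variants: "scale" fixes beta = 0, "shift" fixes gamma = 1 (both
# structurally, the heads do not exist), "concatenation" joins the two
# feature vectors before a single unconditioned trunk.
#
# Forward/backward passes are written directly in R matrix algebra so that
# gradients with respect to the *inputs* (needed by integrated gradients)
# fall out of the same code path as parameter gradients.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

#' Model configuration
#'
#' @param variant One of `"film"`, `"scale"`, `"shift"`, `"concatenation"`.
#' @param n_genes Number of expression features (training genes).
#' @param g Expression-embedding width.
#' @param c_width Compound-embedding width.
#' @param n_film Number of FiLM layers (each = modulation + linear block).
#' @param trunk Integer vector of post-FiLM trunk widths.
#' @param dropout Dropout rate in \[0, 1).
#' @param batchnorm Use batch normalization inside linear blocks.
#' @return A `filmsens_config` list.
#' @export
model_config <- function(variant = c("film", "scale", "shift", "concatenation"),
                         n_genes, g = 64L, c_width = 32L, n_film = 2L,
                         trunk = c(64L, 32L), dropout = 0.1,
                         batchnorm = TRUE) {
  variant <- match.arg(variant)
  widths <- c(n_genes, g, c_width, n_film, trunk)
  if (any(widths <= 0) || any(widths != as.integer(widths)))
    stop_filmsens("widths and layer counts must be positive integers",
                  class = "filmsens_config_error")
  if (dropout < 0 || dropout >= 1)
    stop_filmsens("dropout must lie in [0, 1)", class = "filmsens_config_error")
  structure(list(variant = variant, n_genes = as.integer(n_genes),
                 g = as.integer(g), c_width = as.integer(c_width),
                 n_film = as.integer(n_film), trunk = as.integer(trunk),
                 dropout = dropout, batchnorm = isTRUE(batchnorm)),
            class = "filmsens_config")
}

kaiming <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

block_names <- function(cfg) {
  c("ex", if (cfg$variant != "concatenation") "ec",
    paste0("blk", seq_len(cfg$n_film)),
    paste0("t", seq_along(cfg$trunk)))
}

#' Initialize a model state
#'
#' Deterministic given the seed. The FiLM generator's gamma head is
#' initialized to emit values near 1 and the beta head near 0, so training
#' starts close to identity conditioning.
#'
#' @param config A `filmsens_config`.
#' @param seed Integer seed.
#' @param genes Optional character vector of training gene symbols.
#' @param stats Optional `filmsens_std` standardization attached for reuse.
#' @return A `filmsens_model` state.
#' @export
init_model <- function(config, seed, genes = NULL, stats = NULL) {
  stopifnot(inherits(config, "filmsens_config"))
  set.seed(as.integer(seed))
  p <- list()
  p$gate <- rep(1, config$n_genes)
  d_in <- if (config$variant == "concatenation") config$n_genes + 513L else config$n_genes
  p$ex_W <- kaiming(d_in, config$g); p$ex_b <- rep(0.01, config$g)
  if (config$variant != "concatenation") {
    p$ec_W <- kaiming(513L, config$c_width); p$ec_b <- rep(0.01, config$c_width)
    for (l in seq_len(config$n_film)) {
      if (config$variant %in% c("film", "scale")) {
        p[[paste0("gamW", l)]] <- kaiming(config$c_width, config$g) * 0.01
        p[[paste0("gamb", l)]] <- rep(1, config$g)
      }
      if (config$variant %in% c("film", "shift")) {
        p[[paste0("betW", l)]] <- kaiming(config$c_width, config$g) * 0.01
        p[[paste0("betb", l)]] <- numeric(config$g)
      }
    }
  }
  for (l in seq_len(config$n_film)) {
    p[[paste0("blk", l, "_W")]] <- kaiming(config$g, config$g)
    p[[paste0("blk", l, "_b")]] <- rep(0.01, config$g)
  }
  w_prev <- config$g
  for (i in seq_along(config$trunk)) {
    p[[paste0("t", i, "_W")]] <- kaiming(w_prev, config$trunk[i])
    p[[paste0("t", i, "_b")]] <- rep(0.01, config$trunk[i])
    w_prev <- config$trunk[i]
  }
  p$out_W <- kaiming(w_prev, 1L); p$out_b <- 0
  bn <- list()
  if (config$batchnorm) {
    width_of <- function(nm) ncol(p[[paste0(nm, "_W")]])
    for (nm in block_names(config)) {
      w <- width_of(nm)
      p[[paste0(nm, "_bng")]] <- rep(1, w)
      p[[paste0(nm, "_bnb")]] <- numeric(w)
      bn[[nm]] <- list(mean = numeric(w), var = rep(1, w))
    }
  }
  structure(list(config = config, params = p, bn = bn,
                 genes = genes, stats = stats,
                 version = "filmsens-model-1"),
            class = "filmsens_model")
}

# --- linear block: linear -> ReLU -> batchnorm -> dropout -------------------

block_fwd <- function(state, nm, inp, mode, keep) {
  cfg <- state$config; p <- state$params
  bn <- cfg$batchnorm
  run <- if (bn) state$bn[[nm]] else list(mean = 0, var = 1)
  res <- block_fwd_cpp(inp, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]],
                       bn,
                       if (bn) p[[paste0(nm, "_bng")]] else 0,
                       if (bn) p[[paste0(nm, "_bnb")]] else 0,
                       run$mean, run$var, BN_MOMENTUM, BN_EPS,
                       cfg$dropout, if (mode == "train") 1L else 0L, keep)
  list(out = res$out,
       cache = if (keep) list(inp = inp, z = res$z, xhat = res$xhat,
                              istd = res$istd, mask = res$mask) else NULL,
       bn_new = if (!is.null(res$bn_mean))
         list(mean = as.numeric(res$bn_mean), var = as.numeric(res$bn_var))
       else NULL)
}

block_bwd <- function(state, nm, cache, dout, mode, grads) {
  cfg <- state$config; p <- state$params
  bn <- cfg$batchnorm
  res <- block_bwd_cpp(dout, cache$inp, cache$z,
                       if (bn) cache$xhat else NULL,
                       if (bn) cache$istd else NULL,
                       p[[paste0(nm, "_W")]],
                       if (bn) p[[paste0(nm, "_bng")]] else 0,
                       bn, if (mode == "train") 1L else 0L,
                       cache$mask)
  grads[[paste0(nm, "_W")]] <- res$grads$dW
  grads[[paste0(nm, "_b")]] <- as.numeric(res$grads$db)
  if (bn) {
    grads[[paste0(nm, "_bng")]] <- as.numeric(res$grads$dbng)
    grads[[paste0(nm, "_bnb")]] <- as.numeric(res$grads$dbnb)
  }
  list(dinp = res$dinp, grads = grads)
}

# --- full forward / backward ------------------------------------------------

model_forward <- function(state, X, U, mode = c("eval", "train"),
                          clamp_identity = FALSE, keep_cache = FALSE) {
  mode <- match.arg(mode)
  cfg <- state$config; p <- state$params
  n <- nrow(X)
  cache <- list(mode = mode, clamp = clamp_identity)
  bn_new <- list()
  # learnable per-gene input gate; L1-shrunk during training so the model can
  # select informative genes in the n-samples << n-genes regime
  Xg <- X * bcast(p$gate, n)
  if (keep_cache) cache$X_raw <- X
  X <- Xg
  if (cfg$variant == "concatenation") {
    inp <- cbind(X, U)
    bf <- block_fwd(state, "ex", inp, mode, keep_cache)
    h <- bf$out; cache$ex <- bf$cache; bn_new$ex <- bf$bn_new
  } else {
    bf <- block_fwd(state, "ex", X, mode, keep_cache)
    h <- bf$out; cache$ex <- bf$cache; bn_new$ex <- bf$bn_new
    bf <- block_fwd(state, "ec", U, mode, keep_cache)
    ce <- bf$out; cache$ec <- bf$cache; bn_new$ec <- bf$bn_new
    cache$ce <- if (keep_cache) ce else NULL
  }
  for (l in seq_len(cfg$n_film)) {
    if (cfg$variant != "concatenation") {
      if (clamp_identity) {
        if (keep_cache) {
          cache[[paste0("h", l)]] <- h
          cache[[paste0("gam", l)]] <- 1     # identity conditioning
        }
      } else {
        ff <- film_fwd_cpp(h, ce,
                           p[[paste0("gamW", l)]], p[[paste0("gamb", l)]],
                           p[[paste0("betW", l)]], p[[paste0("betb", l)]],
                           keep_cache)
        if (keep_cache) {
          cache[[paste0("h", l)]] <- h
          cache[[paste0("gam", l)]] <- ff$gam
        }
        h <- ff$out
      }
    }
    bf <- block_fwd(state, paste0("blk", l), h, mode, keep_cache)
    h <- bf$out
    cache[[paste0("blk", l)]] <- bf$cache
    bn_new[[paste0("blk", l)]] <- bf$bn_new
  }
  for (i in seq_along(cfg$trunk)) {
    bf <- block_fwd(state, paste0("t", i), h, mode, keep_cache)
    h <- bf$out
    cache[[paste0("t", i)]] <- bf$cache
    bn_new[[paste0("t", i)]] <- bf$bn_new
  }
  y <- as.numeric(h %*% p$out_W + p$out_b)
  if (keep_cache) cache$h_out <- h
  list(y = y, cache = if (keep_cache) cache else NULL,
       bn_new = if (mode == "train") bn_new else NULL)
}

model_backward <- function(state, cache, dY) {
  cfg <- state$config; p <- state$params
  mode <- cache$mode
  n <- length(dY)
  grads <- list()
  dY <- matrix(dY, ncol = 1L)
  grads$out_W <- crossprod(cache$h_out, dY)
  grads$out_b <- sum(dY)
  dh <- dY %*% t(p$out_W)
  for (i in rev(seq_along(cfg$trunk))) {
    bb <- block_bwd(state, paste0("t", i), cache[[paste0("t", i)]], dh, mode, grads)
    dh <- bb$dinp; grads <- bb$grads
  }
  dce <- if (cfg$variant != "concatenation")
    matrix(0, n, cfg$c_width) else NULL
  for (l in rev(seq_len(cfg$n_film))) {
    bb <- block_bwd(state, paste0("blk", l), cache[[paste0("blk", l)]], dh, mode, grads)
    da <- bb$dinp; grads <- bb$grads
    if (cfg$variant == "concatenation") { dh <- da; next }
    h_l <- cache[[paste0("h", l)]]; gam <- cache[[paste0("gam", l)]]
    dh <- da * gam
    if (!cache$clamp) {
      if (cfg$variant %in% c("film", "scale")) {
        dgam <- da * h_l
        grads[[paste0("gamW", l)]] <- crossprod(cache$ce, dgam)
        grads[[paste0("gamb", l)]] <- colSums(dgam)
        dce <- dce + dgam %*% t(p[[paste0("gamW", l)]])
      }
      if (cfg$variant %in% c("film", "shift")) {
        grads[[paste0("betW", l)]] <- crossprod(cache$ce, da)
        grads[[paste0("betb", l)]] <- colSums(da)
        dce <- dce + da %*% t(p[[paste0("betW", l)]])
      }
    }
  }
  if (cfg$variant == "concatenation") {
    bb <- block_bwd(state, "ex", cache$ex, dh, mode, grads)
    grads <- bb$grads
    dXg <- bb$dinp[, seq_len(cfg$n_genes), drop = FALSE]
    dU <- bb$dinp[, cfg$n_genes + seq_len(513L), drop = FALSE]
  } else {
    bb <- block_bwd(state, "ex", cache$ex, dh, mode, grads)
    dXg <- bb$dinp; grads <- bb$grads
    bb <- block_bwd(state, "ec", cache$ec, dce, mode, grads)
    dU <- bb$dinp; grads <- bb$grads
  }
  grads$gate <- colSums(dXg * cache$X_raw)
  dX <- dXg * bcast(p$gate, n)
  list(grads = grads, dX = dX, dU = dU)
}

#' Predict viability for expression/compound input pairs
#'
#' Evaluation-mode forward pass (deterministic: dropout off, batch
#' normalization uses running statistics).
#'
#' @param state A `filmsens_model`.
#' @param expression Z-scored expression: a vector over the training genes or
#'   a matrix with one row per example.
#' @param compound 513-length compound feature vector, or a matrix with one
#'   row per example (aligned with `expression` rows).
#' @return Numeric vector of predicted viabilities.
#' @export
forward_viability <- function(state, expression, compound) {
  stopifnot(inherits(state, "filmsens_model"))
  X <- if (is.matrix(expression)) expression else matrix(expression, nrow = 1L)
  U <- if (is.matrix(compound)) compound else matrix(compound, nrow = 1L)
  if (nrow(U) == 1L && nrow(X) > 1L) U <- U[rep(1L, nrow(X)), , drop = FALSE]
  if (ncol(X) != state$config$n_genes)
    stop_filmsens("expression has %d features, model expects %d",
                  ncol(X), state$config$n_genes, class = "filmsens_shape_error")
  if (ncol(U) != 513L)
    stop_filmsens("compound features must have length 513, got %d", ncol(U),
                  class = "filmsens_shape_error")
  if (nrow(X) != nrow(U))
    stop_filmsens("expression and compound row counts differ",
                  class = "filmsens_shape_error")
  model_forward(state, X, U, mode = "eval")$y
}

#' Extract learned conditioning parameters for a compound input
#'
#' Returns the per-FiLM-layer (gamma, beta) the generator emits for one
#' compound feature vector, for downstream clustering or PCA of the learned
#' conditioning. Structural constraints of the variants hold exactly: the
#' scale variant returns beta = 0 and the shift variant gamma = 1.
#'
#' @param state A `filmsens_model` (variant other than concatenation).
#' @param compound 513-length compound feature vector.
#' @return List with one element per FiLM layer, each `list(gamma, beta)`.
#' @export
extract_conditioning <- function(state, compound) {
  stopifnot(inherits(state, "filmsens_model"))
  cfg <- state$config
  if (cfg$variant == "concatenation")
    stop_filmsens("the concatenation variant has no conditioning parameters",
                  class = "filmsens_unsupported_variant_error")
  U <- matrix(compound, nrow = 1L)
  if (ncol(U) != 513L)
    stop_filmsens("compound features must have length 513",
                  class = "filmsens_shape_error")
  ce <- block_fwd(state, "ec", U, "eval", FALSE)$out
  p <- state$params
  lapply(seq_len(cfg$n_film), function(l) {
    gamma <- if (cfg$variant %in% c("film", "scale"))
      as.numeric(ce %*% p[[paste0("gamW", l)]]) + p[[paste0("gamb", l)]]
    else rep(1, cfg$g)
    beta <- if (cfg$variant %in% c("film", "shift"))
      as.numeric(ce %*% p[[paste0("betW", l)]]) + p[[paste0("betb", l)]]
    else rep(0, cfg$g)
    list(gamma = gamma, beta = beta)
  })
}

#' Save / load a model state
#'
#' The on-disk representation round-trips bit-exactly: reloading and running
#' an evaluation-mode forward pass reproduces outputs identically.
#'
#' @param state A `filmsens_model`.
#' @param path File path.
#' @export
save_model <- function(state, path) {
  stopifnot(inherits(state, "filmsens_model"))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "filmsens_model"))
    stop_filmsens("%s does not contain a filmsens model", path,
                  class = "filmsens_input_error")
  state
}

#' @export
print.filmsens_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<filmsens_model> variant=%s genes=%d g=%d c=%d film_layers=%d trunk=(%s)\n",
              cfg$variant, cfg$n_genes, cfg$g, cfg$c_width, cfg$n_film,
              paste(cfg$trunk, collapse = ",")))
  invisible(x)
}
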
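# Small deterministic fixtures shared across test files. Everything is built
# in code at test time; nothing is read from disk.

toy_config <- function(variant = "film", n_genes = 7L, g = 5L, c_width = 4L,
                       n_film = 2L, trunk = c(6L, 3L), dropout = 0,
                       batchnorm = FALSE) {
  model_config(variant, n_genes = n_genes, g = g, c_width = c_width,
               n_film = n_film, trunk = trunk, dropout = dropout,
               batchnorm = batchnorm)
}

toy_inputs <- function(n = 6L, n_genes = 7L, seed = 9L) {
  set.seed(seed)
  list(X = matrix(rnorm(n * n_genes), n),
       U = cbind(matrix(rbinom(n * 512L, 1L, 0.3), n), runif(n, 0.1, 10)),
       y = runif(n))
}

# noise-free LL4 curve on a grid
ll4_curve <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))

# tiny simulated dataset for fast end-to-end unit tests (not the benchmark)
tiny_sim <- function(seed = 11L) {
  simulate(simulation_config(n_lines = 12L, n_genes = 40L, n_compounds = 8L,
                             n_classes = 2L, m = 2L, s = 24L, sigma = 0.05,
                             heldout_fraction = 0.25, seed = seed))
}
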
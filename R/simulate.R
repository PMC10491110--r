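# Synthetic pharmacogenomic benchmark with planted ground truth: gene-driven
# IC50 surfaces, class-structured fingerprints, a modular PPI graph, and an
# in-silico knockout utility. Every pipeline stage is testable against the
# planted truth without external downloads.

#' Simulation configuration
#'
#' Defaults define the package's standard desk-scale benchmark: 40 cell
#' lines, 200 genes, 30 compounds in 6 MOA classes with 3 disjoint planted
#' driver genes each. A compound's true log10 IC50 for a line is
#' `mu0 + sum_g w_g * x_g` over the drivers of its class (weights uniform in
#' `w_range`, protective: higher driver expression means a more resistant
#' line), clipped to 0.5 log-units inside the concentration grid so absolute
#' IC50s stay identifiable. Viability follows a log-logistic curve with hill
#' slope `b0`, floor `c0`, upper asymptote 1, plus Gaussian noise `sigma`
#' floored at 0. Class fingerprints share `s` signature bits; remaining bits
#' are Bernoulli(`bg_density`).
#'
#' @param n_lines,n_genes,n_compounds,n_classes Problem sizes.
#' @param m Driver genes per class (disjoint across classes).
#' @param s Signature fingerprint bits per class (disjoint).
#' @param w_range Driver weight range on the log10-IC50 scale.
#' @param mu0 Baseline log10 IC50 (default: log-grid center).
#' @param b0 Hill slope of the true curves.
#' @param c0 Viability floor of the true curves, in `[0, 0.4)`.
#' @param sigma Viability noise sd.
#' @param grid Concentration grid (uM).
#' @param bg_density Background fingerprint bit density.
#' @param heldout_fraction Fraction of lines held out from training.
#' @param p_in,p_out PPI edge probabilities within driver modules /
#'   background.
#' @param seed Integer seed; the dataset is reproducible bit-exactly from
#'   (config, seed).
#' @return A `filmsens_simconfig` list.
#' @export
simulation_config <- function(n_lines = 40L, n_genes = 200L, n_compounds = 30L,
                              n_classes = 6L, m = 3L, s = 16L,
                              w_range = c(0.3, 0.6), mu0 = -0.2614,
                              b0 = 1.2, c0 = 0.05, sigma = 0.05,
                              grid = default_grid(), bg_density = 0.1,
                              heldout_fraction = 0.2,
                              p_in = 0.8, p_out = 0.01, seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_genes = as.integer(n_genes),
              n_compounds = as.integer(n_compounds),
              n_classes = as.integer(n_classes), m = as.integer(m),
              s = as.integer(s), w_range = w_range, mu0 = mu0, b0 = b0,
              c0 = c0, sigma = sigma, grid = grid,
              bg_density = bg_density, heldout_fraction = heldout_fraction,
              p_in = p_in, p_out = p_out, seed = as.integer(seed))
  if (cfg$m * cfg$n_classes > cfg$n_genes)
    stop_filmsens("driver sets cannot be disjoint: m * n_classes > n_genes",
                  class = "filmsens_config_error")
  if (cfg$s * cfg$n_classes > 512L)
    stop_filmsens("signature bit sets cannot be disjoint: s * n_classes > 512",
                  class = "filmsens_config_error")
  if (cfg$c0 < 0 || cfg$c0 >= 0.4)
    stop_filmsens("c0 must lie in [0, 0.4)", class = "filmsens_config_error")
  if (cfg$sigma < 0 || any(diff(cfg$grid) <= 0) || any(cfg$grid <= 0))
    stop_filmsens("sigma must be >= 0 and the grid strictly increasing, positive",
                  class = "filmsens_config_error")
  if (cfg$n_compounds < cfg$n_classes)
    stop_filmsens("need at least one compound per class",
                  class = "filmsens_config_error")
  structure(cfg, class = "filmsens_simconfig")
}

#' Simulate a benchmark dataset with planted ground truth
#'
#' @param config A `filmsens_simconfig`.
#' @return List `dataset` (fields `expression`, `compounds`, `viability`,
#'   `moa`, `ppi`, `train_lines`, `heldout_lines`) and `truth`
#'   (`filmsens_truth`: per-class drivers, weights, signature bits, the true
#'   log10-IC50 surface and curve parameters).
#' @export
simulate <- function(config) {
  stopifnot(inherits(config, "filmsens_simconfig"))
  cfg <- config
  set.seed(cfg$seed)
  lines <- sprintf("CL%02d", seq_len(cfg$n_lines))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  cpds <- sprintf("CPD%02d", seq_len(cfg$n_compounds))
  klass <- paste0("class_", rep_len(seq_len(cfg$n_classes), cfg$n_compounds))
  kname <- paste0("class_", seq_len(cfg$n_classes))

  expr <- matrix(stats::rnorm(cfg$n_lines * cfg$n_genes), cfg$n_lines,
                 dimnames = list(lines, genes))

  driver_idx <- split(sample.int(cfg$n_genes, cfg$m * cfg$n_classes),
                      rep(seq_len(cfg$n_classes), each = cfg$m))
  drivers <- lapply(driver_idx, function(i) genes[i])
  names(drivers) <- kname
  weights <- lapply(kname, function(k)
    stats::setNames(stats::runif(cfg$m, cfg$w_range[1], cfg$w_range[2]),
                    drivers[[k]]))
  names(weights) <- kname

  sig_idx <- split(sample.int(512L, cfg$s * cfg$n_classes),
                   rep(seq_len(cfg$n_classes), each = cfg$s))
  names(sig_idx) <- kname
  fp <- matrix(stats::rbinom(cfg$n_compounds * 512L, 1L, cfg$bg_density),
               cfg$n_compounds, 512L, dimnames = list(cpds, NULL))
  for (j in seq_len(cfg$n_compounds)) fp[j, sig_idx[[klass[j]]]] <- 1L

  lo <- log10(cfg$grid[1]) + 0.5
  hi <- log10(cfg$grid[length(cfg$grid)]) - 0.5
  log_ic50 <- matrix(NA_real_, cfg$n_lines, cfg$n_compounds,
                     dimnames = list(lines, cpds))
  for (j in seq_len(cfg$n_compounds)) {
    w <- weights[[klass[j]]]
    shift <- as.numeric(expr[, names(w), drop = FALSE] %*% w)
    log_ic50[, j] <- pmin(pmax(cfg$mu0 + shift, lo), hi)
  }

  n_conc <- length(cfg$grid)
  viab <- expand.grid(cell_line_id = lines, compound_id = cpds,
                      concentration_uM = cfg$grid,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  e_um <- 10^log_ic50[cbind(viab$cell_line_id, viab$compound_id)]
  v <- cfg$c0 + (1 - cfg$c0) /
    (1 + exp(cfg$b0 * (log(viab$concentration_uM) - log(e_um))))
  if (cfg$sigma > 0) v <- v + stats::rnorm(length(v), sd = cfg$sigma)
  viab$viability <- pmax(v, 0)
  viab <- viab[, c("compound_id", "cell_line_id", "concentration_uM", "viability")]

  heldout <- sort(sample(lines, round(cfg$heldout_fraction * cfg$n_lines)))
  compounds <- data.frame(
    compound_id = cpds, smiles = "", moa_class = klass,
    fingerprint = I(lapply(seq_len(cfg$n_compounds), function(j) fp[j, ])),
    targets = I(unname(drivers[klass])))
  moa <- data.frame(compound_id = cpds, moa_class = klass,
                    targets = I(unname(drivers[klass])))
  truth <- structure(list(drivers = drivers, weights = weights,
                          signature_bits = sig_idx, log10_ic50 = log_ic50,
                          moa_class = stats::setNames(klass, cpds),
                          b0 = cfg$b0, c0 = cfg$c0, d = 1, mu0 = cfg$mu0,
                          clip = c(lo, hi)),
                     class = "filmsens_truth")
  ppi <- simulate_ppi(truth, genes = genes, p_in = cfg$p_in, p_out = cfg$p_out,
                      seed = derive_seed(cfg$seed, 77L))
  dataset <- list(expression = expr, compounds = compounds, viability = viab,
                  moa = moa, ppi = ppi,
                  train_lines = setdiff(lines, heldout),
                  heldout_lines = heldout, config = cfg)
  list(dataset = dataset, truth = truth)
}

#' True IC50 of a (line, compound) pair
#'
#' @param truth A `filmsens_truth`.
#' @param line,compound Ids.
#' @return IC50 in uM (`10^log10_ic50`).
#' @export
true_ic50 <- function(truth, line, compound) {
  stopifnot(inherits(truth, "filmsens_truth"))
  if (!(line %in% rownames(truth$log10_ic50)) ||
      !(compound %in% colnames(truth$log10_ic50)))
    stop_filmsens("unknown (line, compound) pair (%s, %s)", line, compound,
                  class = "filmsens_input_error")
  10^truth$log10_ic50[line, compound]
}

#' Simulate a modular PPI edge list around the planted driver sets
#'
#' Within-driver-set gene pairs get an edge with probability `p_in` and a
#' high-confidence file-scale combined score in \[701, 1000\]; all other
#' pairs with probability `p_out` and scores in \[400, 1000\]. Undirected,
#' no self-loops.
#'
#' @param truth A `filmsens_truth`.
#' @param genes Full gene universe (defaults to the genes appearing in the
#'   truth's driver sets plus the expression genes if supplied).
#' @param p_in,p_out Edge probabilities.
#' @param seed Integer seed.
#' @return Data.frame `protein1, protein2, combined_score` (file scale
#'   0-1000).
#' @export
simulate_ppi <- function(truth, genes = NULL, p_in = 0.8, p_out = 0.01,
                         seed = 1L) {
  stopifnot(inherits(truth, "filmsens_truth"),
            p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  genes <- genes %||% rownames(truth$log10_ic50)
  set.seed(as.integer(seed))
  module_of <- rep(NA_integer_, length(genes))
  names(module_of) <- genes
  for (k in seq_along(truth$drivers))
    module_of[truth$drivers[[k]]] <- k
  pairs <- utils::combn(genes, 2L)
  m1 <- module_of[pairs[1L, ]]; m2 <- module_of[pairs[2L, ]]
  same <- !is.na(m1) & !is.na(m2) & m1 == m2
  prob <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pairs)) < prob
  score <- integer(sum(keep))
  in_mod <- same[keep]
  score[in_mod] <- sample(701:1000, sum(in_mod), replace = TRUE)
  score[!in_mod] <- sample(400:1000, sum(!in_mod), replace = TRUE)
  data.frame(protein1 = pairs[1L, keep], protein2 = pairs[2L, keep],
             combined_score = score)
}

#' In-silico knockout of a gene
#'
#' Sets the gene's z-scored expression to `z_value` for the selected rows.
#' Idempotent; everything else unchanged.
#'
#' @param expression Z-scored expression matrix.
#' @param gene Gene symbol to knock out.
#' @param z_value Expression value after knockout (default -3, a strong
#'   depletion on the z scale).
#' @param rows Row ids/indices to modify (default all).
#' @return The modified matrix.
#' @export
knockout <- function(expression, gene, z_value = -3, rows = NULL) {
  if (!(gene %in% colnames(expression)))
    stop_filmsens("unknown gene '%s'", gene, class = "filmsens_input_error")
  rows <- rows %||% seq_len(nrow(expression))
  expression[rows, gene] <- z_value
  expression
}

#' Write / read a fixture bundle
#'
#' Emits `expression.tsv`, `compounds.csv`, `viability.csv`, `moa.csv`,
#' `ppi.tsv`, `split.csv`, and `manifest.json` (config, seed, and per-file
#' md5 hashes). Reading the bundle back reproduces the dataset.
#'
#' @param dataset The `dataset` element of [simulate()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
write_fixture_bundle <- function(dataset, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(directory, f)
  write_expression_tsv(dataset$expression, fp("expression.tsv"))
  write_compound_csv(dataset$compounds, fp("compounds.csv"))
  write_viability_csv(dataset$viability, fp("viability.csv"))
  data.table::fwrite(data.frame(
    compound_id = dataset$moa$compound_id,
    moa_class = dataset$moa$moa_class,
    targets = vapply(dataset$moa$targets, paste, "", collapse = ";")),
    fp("moa.csv"), sep = ",")
  data.table::fwrite(dataset$ppi, fp("ppi.tsv"), sep = "\t")
  data.table::fwrite(data.frame(
    cell_line_id = c(dataset$train_lines, dataset$heldout_lines),
    split = rep(c("train", "heldout"),
                c(length(dataset$train_lines), length(dataset$heldout_lines)))),
    fp("split.csv"), sep = ",")
  files <- c("expression.tsv", "compounds.csv", "viability.csv", "moa.csv",
             "ppi.tsv", "split.csv")
  manifest <- list(
    format = "filmsens-bundle-1",
    seed = dataset$config$seed %||% NA,
    config = dataset$config[setdiff(names(dataset$config), "grid")],
    grid = dataset$config$grid,
    md5 = as.list(tools::md5sum(vapply(files, fp, ""))))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @rdname write_fixture_bundle
#' @export
read_fixture_bundle <- function(directory) {
  fp <- function(f) file.path(directory, f)
  split <- data.table::fread(fp("split.csv"), data.table = FALSE)
  list(expression = read_expression_tsv(fp("expression.tsv")),
       compounds = read_compound_csv(fp("compounds.csv")),
       viability = read_viability_csv(fp("viability.csv")),
       moa = read_moa_csv(fp("moa.csv")),
       ppi = data.table::fread(fp("ppi.tsv"), data.table = FALSE),
       train_lines = split$cell_line_id[split$split == "train"],
       heldout_lines = split$cell_line_id[split$split == "heldout"],
       manifest = jsonlite::read_json(fp("manifest.json")))
}
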
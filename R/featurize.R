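#' @importFrom stats sd
NULL

# ---------------------------------------------------------------------------
# Fingerprints
# ---------------------------------------------------------------------------

#' Compute Morgan (circular) fingerprints from SMILES
#'
#' Computes `n_bits`-bit Morgan fingerprints of the given radius via RDKit.
#' The computation is deterministic and invariant to atom input ordering of
#' equivalent molecules. Requires a `python` interpreter with `rdkit` on the
#' PATH; tables that already carry precomputed fingerprints never need this.
#'
#' @param structures Character vector of SMILES strings.
#' @param radius Neighborhood radius of the circular fingerprint.
#' @param n_bits Fingerprint length in bits.
#' @return A matrix with one row per structure, `n_bits` 0/1 columns, row
#'   names set to the input SMILES.
#' @export
compute_fingerprint <- function(structures, radius = 2L, n_bits = 512L) {
  stopifnot(is.character(structures), length(structures) >= 1L)
  py <- Sys.which("python")
  if (py == "")
    stop_filmsens("no `python` interpreter on PATH; supply precomputed fingerprints instead",
                  class = "filmsens_backend_error")
  script <- paste(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem import AllChem",
    "RDLogger.DisableLog('rdApp.*')",
    sprintf("radius, n_bits = %d, %d", as.integer(radius), as.integer(n_bits)),
    "for line in sys.stdin:",
    "    smi = line.rstrip('\\n')",
    "    mol = Chem.MolFromSmiles(smi)",
    "    if mol is None:",
    "        print('ERROR')",
    "    else:",
    "        fp = AllChem.GetMorganFingerprintAsBitVect(mol, radius, nBits=n_bits)",
    "        print(fp.ToBitString())",
    sep = "\n")
  out <- suppressWarnings(
    system2(py, c("-c", shQuote(script)), input = structures,
            stdout = TRUE, stderr = FALSE))
  if (length(out) != length(structures))
    stop_filmsens("fingerprint backend failed (is rdkit importable from `python`?)",
                  class = "filmsens_backend_error")
  bad <- which(out == "ERROR")
  if (length(bad))
    stop_filmsens("unparseable SMILES: %s",
                  paste(sprintf("'%s'", structures[bad]), collapse = ", "),
                  class = "filmsens_structure_error")
  fp <- t(vapply(strsplit(out, ""), function(b) as.integer(b),
                 integer(n_bits)))
  rownames(fp) <- structures
  fp
}

#' Concatenate a fingerprint with a concentration
#'
#' Builds the 513-length compound feature vector: 512 fingerprint bits
#' followed by the concentration. The concentration enters in raw micromolar
#' units by default; `transform = "log10uM"` switches to log10 micromolar,
#' the scale of the log-logistic response process.
#'
#' @param fingerprint Numeric/integer 0/1 vector, length 512.
#' @param concentration Positive concentration in uM.
#' @param transform `"uM"` (raw, default) or `"log10uM"`.
#' @return Numeric vector of length 513.
#' @export
make_compound_features <- function(fingerprint, concentration,
                                   transform = c("uM", "log10uM")) {
  transform <- match.arg(transform)
  if (length(fingerprint) != 512L || !all(fingerprint %in% c(0, 1)))
    stop_filmsens("fingerprint must be a 512-long 0/1 vector",
                  class = "filmsens_shape_error")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration <= 0)
    stop_filmsens("concentration must be a single finite value > 0 uM",
                  class = "filmsens_domain_error")
  conc <- if (transform == "log10uM") log10(concentration) else concentration
  c(as.numeric(fingerprint), conc)
}

#' Random ("straw") fingerprints that ablate structural information
#'
#' One fixed random 512-bit vector per compound (shared across all of its
#' concentrations), per-bit probability 0.5, pairwise distinct (re-drawn on
#' the astronomically unlikely collision), reproducible by seed.
#'
#' @param compound_ids Character vector of unique compound ids.
#' @param seed Integer seed.
#' @param n_bits Fingerprint length.
#' @return Matrix, one row per id (rownames = ids), 0/1 entries.
#' @export
make_straw_fingerprints <- function(compound_ids, seed, n_bits = 512L) {
  if (anyDuplicated(compound_ids))
    stop_filmsens("duplicate compound ids: %s",
                  paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "),
                  class = "filmsens_input_error")
  set.seed(as.integer(seed))
  n <- length(compound_ids)
  fp <- matrix(sample(c(0L, 1L), n * n_bits, replace = TRUE), nrow = n)
  key <- apply(fp, 1L, paste, collapse = "")
  while (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    fp[i, ] <- sample(c(0L, 1L), n_bits, replace = TRUE)
    key[i] <- paste(fp[i, ], collapse = "")
  }
  rownames(fp) <- compound_ids
  fp
}

# ---------------------------------------------------------------------------
# Standardization
# ---------------------------------------------------------------------------

#' Fit per-gene standardization statistics on training expression
#'
#' @param training_expression Numeric matrix, rows = cell lines/samples,
#'   columns = genes; at least two rows.
#' @return An object of class `filmsens_std`: per-gene mean, sd, and
#'   constant-gene flags. Derived only from the rows supplied.
#' @export
fit_standardization <- function(training_expression) {
  x <- as.matrix(training_expression)
  if (nrow(x) < 2L)
    stop_filmsens("need >= 2 training rows to fit standardization",
                  class = "filmsens_insufficient_data_error")
  mu <- colMeans(x)
  sig <- apply(x, 2L, sd)
  constant <- !is.finite(sig) | sig < 1e-12
  structure(list(mean = mu, sd = sig, constant = constant,
                 genes = colnames(x)),
            class = "filmsens_std")
}

#' Apply (or invert) a fitted standardization
#'
#' Z-scores each gene with the stored training mean and sd. Constant genes
#' map to 0. `invert_standardization` undoes the transform for non-constant
#' genes.
#'
#' @param expression Matrix with the same gene columns the stats were fit on.
#' @param stats A `filmsens_std` object.
#' @return Matrix of z-scores with the input dimnames.
#' @export
apply_standardization <- function(expression, stats) {
  stopifnot(inherits(stats, "filmsens_std"))
  x <- as.matrix(expression)
  if (ncol(x) != length(stats$mean))
    stop_filmsens("expression has %d columns but stats were fit on %d genes",
                  ncol(x), length(stats$mean), class = "filmsens_shape_error")
  z <- (x - bcast(stats$mean, nrow(x))) / bcast(ifelse(stats$constant, 1, stats$sd), nrow(x))
  z[, stats$constant] <- 0
  dimnames(z) <- dimnames(x)
  z
}

#' @rdname apply_standardization
#' @param z Matrix of z-scores.
#' @export
invert_standardization <- function(z, stats) {
  stopifnot(inherits(stats, "filmsens_std"))
  z <- as.matrix(z)
  x <- z * bcast(ifelse(stats$constant, 1, stats$sd), nrow(z)) +
    bcast(stats$mean, nrow(z))
  x
}

#' Align an external expression cohort to the training gene space
#'
#' Reorders columns to the training gene list, mean-imputes genes absent from
#' the external matrix (z = 0 after standardization), standardizes with the
#' training statistics, and reports the imputed fraction.
#'
#' @param external Expression matrix, rows = samples, columns = gene symbols.
#' @param training_genes Ordered character vector of training gene symbols.
#' @param stats `filmsens_std` fitted on the training data over
#'   `training_genes`.
#' @return Standardized matrix over exactly `training_genes`, with attributes
#'   `imputed_genes` and `imputed_fraction`.
#' @export
align_external_profiles <- function(external, training_genes, stats) {
  x <- as.matrix(external)
  colnames(x) <- trimws(colnames(x))
  training_genes <- trimws(training_genes)
  hit <- training_genes %in% colnames(x)
  if (!any(hit))
    stop_filmsens("no overlap between external genes and the training gene list",
                  class = "filmsens_alignment_error")
  out <- matrix(NA_real_, nrow(x), length(training_genes),
                dimnames = list(rownames(x), training_genes))
  out[, training_genes[hit]] <- x[, training_genes[hit], drop = FALSE]
  miss <- training_genes[!hit]
  out[, miss] <- bcast(stats$mean[match(miss, names(stats$mean))], nrow(x))
  z <- apply_standardization(out, stats)
  attr(z, "imputed_genes") <- miss
  attr(z, "imputed_fraction") <- length(miss) / length(training_genes)
  z
}

# ---------------------------------------------------------------------------
# Table IO (expression TSV, compound CSV, viability CSV)
# ---------------------------------------------------------------------------

check_schema <- function(df, required, file) {
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_filmsens("%s: missing required column(s) %s", file,
                  paste(miss, collapse = ", "), class = "filmsens_schema_error")
}

bad_rows_msg <- function(bad, file, what) {
  # +1 for the header line so messages give file line numbers
  stop_filmsens("%s: %s at line(s) %s", file, what,
                paste(utils::head(bad + 1L, 10L), collapse = ", "),
                class = "filmsens_schema_error")
}

#' Read and write expression tables
#'
#' Expression TSV layout: first column `sample_id`, remaining columns one per
#' gene symbol, float abundances. Readers validate the schema and report
#' offending file line numbers.
#'
#' @param path File path.
#' @return `read_expression_tsv`: numeric matrix with sample rownames and
#'   gene colnames.
#' @export
read_expression_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  check_schema(dt, "sample_id", path)
  if (anyDuplicated(dt$sample_id))
    bad_rows_msg(which(duplicated(dt$sample_id)), path, "duplicate sample_id")
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(dt[, -1, drop = FALSE], 1L,
                       function(r) any(is.na(suppressWarnings(as.numeric(r))))))
    bad_rows_msg(bad, path, "non-numeric expression value")
  }
  if (anyNA(m))
    bad_rows_msg(which(rowSums(is.na(m)) > 0), path, "missing expression value")
  rownames(m) <- dt$sample_id
  colnames(m) <- trimws(colnames(m))
  m
}

#' @rdname read_expression_tsv
#' @param expression Matrix, rows = samples, columns = genes.
#' @export
write_expression_tsv <- function(expression, path) {
  df <- data.frame(sample_id = rownames(expression),
                   expression, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read and write compound tables
#'
#' Compound CSV columns: `compound_id,smiles,fingerprint,moa_class,targets`
#' (targets `;`-separated; fingerprint a 512-character 0/1 string). Either
#' `smiles` or `fingerprint` must be present per row; when both are given the
#' precomputed fingerprint wins and a warning is emitted.
#'
#' @param path File path.
#' @param n_bits Expected fingerprint length.
#' @return A data.frame with list-column `fingerprint` (integer vectors) and
#'   list-column `targets` (character vectors).
#' @export
read_compound_csv <- function(path, n_bits = 512L) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = "character", na.strings = NULL)
  check_schema(dt, "compound_id", path)
  for (col in c("smiles", "fingerprint", "moa_class", "targets"))
    if (is.null(dt[[col]])) dt[[col]] <- ""
  if (anyDuplicated(dt$compound_id))
    bad_rows_msg(which(duplicated(dt$compound_id)), path, "duplicate compound_id")
  has_fp <- nzchar(dt$fingerprint)
  has_smi <- nzchar(dt$smiles)
  if (any(!has_fp & !has_smi))
    bad_rows_msg(which(!has_fp & !has_smi), path,
                 "neither smiles nor fingerprint given")
  badlen <- has_fp & (nchar(dt$fingerprint) != n_bits |
                        grepl("[^01]", dt$fingerprint))
  if (any(badlen))
    bad_rows_msg(which(badlen), path,
                 sprintf("fingerprint is not a %d-character 0/1 string", n_bits))
  if (any(has_fp & has_smi))
    warning(sprintf("%s: %d row(s) carry both smiles and fingerprint; using the precomputed fingerprint",
                    path, sum(has_fp & has_smi)))
  fps <- vector("list", nrow(dt))
  fps[has_fp] <- lapply(strsplit(dt$fingerprint[has_fp], ""), as.integer)
  if (any(!has_fp)) {
    m <- compute_fingerprint(dt$smiles[!has_fp], n_bits = n_bits)
    fps[!has_fp] <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  }
  data.frame(compound_id = dt$compound_id,
             smiles = dt$smiles,
             moa_class = dt$moa_class,
             fingerprint = I(fps),
             targets = I(lapply(strsplit(dt$targets, ";", fixed = TRUE),
                                function(t) trimws(t[nzchar(t)]))))
}

#' @rdname read_compound_csv
#' @param compounds Data.frame as returned by `read_compound_csv`.
#' @export
write_compound_csv <- function(compounds, path) {
  df <- data.frame(
    compound_id = compounds$compound_id,
    smiles = compounds$smiles %||% "",
    fingerprint = vapply(compounds$fingerprint, paste, "", collapse = ""),
    moa_class = compounds$moa_class %||% "",
    targets = vapply(compounds$targets, paste, "", collapse = ";"))
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Read and write viability tables
#'
#' Viability CSV columns: `compound_id,cell_line_id,concentration_uM,viability`.
#' Concentrations must be strictly positive and viabilities finite;
#' violations are reported with file line numbers.
#'
#' @param path File path.
#' @return Data.frame with those four columns.
#' @export
read_viability_csv <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  check_schema(dt, c("compound_id", "cell_line_id", "concentration_uM", "viability"),
               path)
  bad <- which(!is.finite(dt$concentration_uM) | dt$concentration_uM <= 0)
  if (length(bad)) bad_rows_msg(bad, path, "non-positive concentration")
  bad <- which(!is.finite(dt$viability))
  if (length(bad)) bad_rows_msg(bad, path, "non-finite viability")
  dt
}

#' @rdname read_viability_csv
#' @param viability Data.frame with the four schema columns.
#' @export
write_viability_csv <- function(viability, path) {
  data.table::fwrite(viability[, c("compound_id", "cell_line_id",
                                   "concentration_uM", "viability")],
                     path, sep = ",")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Design assembly
# ---------------------------------------------------------------------------

#' Assemble model design matrices from standardized expression, compounds,
#' and a viability long table
#'
#' Rows of the result align with rows of `viability`; `X` holds the z-scored
#' expression of each row's cell line, `U` the 513-length compound feature
#' vector at that row's concentration.
#'
#' @param expression_z Standardized expression matrix (lines x genes).
#' @param compounds Compound table with `compound_id` and list-column
#'   `fingerprint` (or a fingerprint matrix with compound rownames).
#' @param viability Long table `compound_id,cell_line_id,concentration_uM,viability`.
#' @param concentration_transform `"uM"` or `"log10uM"` (see
#'   [make_compound_features()]).
#' @return List with `X`, `U`, `y`, `cell_line_id`, `compound_id`, `genes`,
#'   and the transform used.
#' @export
build_design <- function(expression_z, compounds, viability,
                         concentration_transform = c("uM", "log10uM")) {
  concentration_transform <- match.arg(concentration_transform)
  fps <- if (is.matrix(compounds)) compounds else {
    m <- do.call(rbind, compounds$fingerprint)
    rownames(m) <- compounds$compound_id
    m
  }
  li <- match(viability$cell_line_id, rownames(expression_z))
  ci <- match(viability$compound_id, rownames(fps))
  if (anyNA(li))
    stop_filmsens("cell line(s) absent from expression: %s",
                  paste(unique(viability$cell_line_id[is.na(li)]), collapse = ", "),
                  class = "filmsens_input_error")
  if (anyNA(ci))
    stop_filmsens("compound(s) absent from the compound table: %s",
                  paste(unique(viability$compound_id[is.na(ci)]), collapse = ", "),
                  class = "filmsens_input_error")
  conc <- viability$concentration_uM
  if (any(conc <= 0)) stop_filmsens("concentrations must be > 0",
                                    class = "filmsens_domain_error")
  cfeat <- if (concentration_transform == "log10uM") log10(conc) else conc
  list(X = expression_z[li, , drop = FALSE],
       U = cbind(fps[ci, , drop = FALSE], cfeat),
       y = viability$viability,
       cell_line_id = viability$cell_line_id,
       compound_id = viability$compound_id,
       genes = colnames(expression_z),
       concentration_transform = concentration_transform)
}
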
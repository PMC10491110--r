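# Downstream statistics on attribution matrices: control-compound-set
# selection, K-means + adjusted mutual information against MOA labels,
# Leiden clustering, differential attribution analysis, marker extraction,
# cluster ordering, nominal-target contrasts, PPI-module connectivity with
# permutation nulls, and hypergeometric enrichment.

#' Read a MOA table
#'
#' CSV columns `compound_id,moa_class,targets` with `;`-separated targets.
#'
#' @param path File path.
#' @return Data.frame with `compound_id`, `moa_class`, list-column `targets`.
#' @export
read_moa_csv <- function(path) {
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE,
                          colClasses = "character", na.strings = NULL)
  check_schema(dt, c("compound_id", "moa_class"), path)
  if (is.null(dt$targets)) dt$targets <- ""
  if (anyDuplicated(dt$compound_id))
    bad_rows_msg(which(duplicated(dt$compound_id)), path, "duplicate compound_id")
  data.frame(compound_id = dt$compound_id, moa_class = dt$moa_class,
             targets = I(lapply(strsplit(dt$targets, ";", fixed = TRUE),
                                function(t) trimws(t[nzchar(t)]))))
}

#' Select the control compound set (CCS)
#'
#' Keeps MOA classes having at least two compounds each successfully
#' attributed in all required cell lines.
#'
#' @param meta Attribution metadata (`cell_line_id`, `compound_id`), e.g.
#'   the `meta` field of a `filmsens_attribution`.
#' @param moa MOA table (`compound_id`, `moa_class`).
#' @param required_lines Number of lines a compound must cover; defaults to
#'   every line present in `meta`.
#' @return List `compounds` (qualifying compound ids), `classes` (named
#'   character: compound -> class), `class_table`.
#' @export
select_ccs <- function(meta, moa, required_lines = NULL) {
  all_lines <- unique(meta$cell_line_id)
  required_lines <- required_lines %||% length(all_lines)
  cov <- tapply(meta$cell_line_id, meta$compound_id,
                function(l) length(unique(l)))
  qualified <- names(cov)[cov >= required_lines]
  cls <- moa$moa_class[match(qualified, moa$compound_id)]
  keep_classes <- names(which(table(cls) >= 2L))
  compounds <- qualified[cls %in% keep_classes]
  if (!length(compounds))
    stop_filmsens("no MOA class has >= 2 compounds attributed in %d lines",
                  required_lines, class = "filmsens_empty_result_error")
  classes <- cls[cls %in% keep_classes]
  names(classes) <- compounds
  list(compounds = compounds, classes = classes,
       class_table = table(classes))
}

#' Adjusted mutual information between two labelings
#'
#' Chance-adjusted agreement: `(MI - E[MI]) / (mean(H_a, H_b) - E[MI])`,
#' with the expected mutual information taken over the permutation model
#' (fixed marginals). Equals 1 for identical partitions and is invariant to
#' label renaming.
#'
#' @param a,b Two labelings of the same items.
#' @return A single number <= 1.
#' @export
ami <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  n <- length(a)
  tab <- table(a, b)
  ai <- rowSums(tab); bj <- colSums(tab)
  mi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / n * log(n * nij / (ai[i] * bj[j]))
  }
  h <- function(m) { p <- m[m > 0] / n; -sum(p * log(p)) }
  ha <- h(ai); hb <- h(bj)
  # E[MI] under random permutation of one labeling with fixed marginals
  emi <- 0
  for (i in seq_along(ai)) for (j in seq_along(bj)) {
    lo <- max(1L, ai[i] + bj[j] - n); hi <- min(ai[i], bj[j])
    if (lo > hi) next
    for (nij in lo:hi) {
      lp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) + lgamma(n - ai[i] + 1) +
        lgamma(n - bj[j] + 1) - lgamma(n + 1) - lgamma(nij + 1) -
        lgamma(ai[i] - nij + 1) - lgamma(bj[j] - nij + 1) -
        lgamma(n - ai[i] - bj[j] + nij + 1)
      emi <- emi + nij / n * log(n * nij / (ai[i] * bj[j])) * exp(lp)
    }
  }
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-15) return(if (abs(mi - emi) < 1e-15) 1 else 0)
  as.numeric((mi - emi) / denom)
}

#' K-means clustering scored by AMI against reference labels
#'
#' Runs `trials` independently seeded K-means clusterings of the rows of `X`
#' and scores each against `true_labels` with [ami()].
#'
#' @param X Numeric matrix (e.g. adjusted attributions or fingerprints).
#' @param true_labels Reference labeling of the rows.
#' @param k Number of clusters (>= 2).
#' @param trials Number of independent K-means runs.
#' @param seed Integer seed.
#' @return Numeric vector of AMI values, one per trial.
#' @export
kmeans_ami <- function(X, true_labels, k, trials = 5L, seed = 1L) {
  X <- as.matrix(X)
  if (k < 2L || k > nrow(X))
    stop_filmsens("need 2 <= k <= nrow(X)", class = "filmsens_input_error")
  vapply(seq_len(trials), function(t) {
    set.seed(derive_seed(seed, t))
    km <- stats::kmeans(X, centers = k, nstart = 1L, iter.max = 100L)
    ami(km$cluster, true_labels)
  }, numeric(1L))
}

#' Leiden clustering of attribution rows
#'
#' PCA to `min(50, n-1, p)` components, a k-nearest-neighbour graph
#' (Euclidean), then Leiden modularity partitioning at the given resolution.
#'
#' @param X Numeric matrix, rows = samples.
#' @param n_neighbors Neighbourhood size of the kNN graph.
#' @param resolution Leiden resolution parameter; the 0.5 default recovers
#'   well-separated groups without fragmenting them on unweighted kNN graphs.
#' @param seed Integer seed.
#' @return Integer cluster labels (1-based) with attributes `method`,
#'   `parameters`, `seed`.
#' @export
leiden_clusters <- function(X, n_neighbors = 15L, resolution = 0.5, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n <= n_neighbors)
    stop_filmsens("need more rows (%d) than n_neighbors (%d)", n, n_neighbors,
                  class = "filmsens_input_error")
  ncomp <- min(50L, n - 1L, ncol(X))
  pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE)$x[, seq_len(ncomp), drop = FALSE]
  d <- as.matrix(stats::dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- order(d[i, ])[2:(n_neighbors + 1L)]
    cbind(i, nb)
  }))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(as.integer(seed))
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5L)
  labels <- igraph::membership(cl)
  structure(as.integer(labels), method = "leiden",
            parameters = list(n_neighbors = n_neighbors, resolution = resolution),
            seed = seed)
}

#' Differential attribution analysis (DAA)
#'
#' Two-sided Wilcoxon rank-sum test per gene of a sample group against all
#' remaining samples, BH correction across genes, and the mean difference of
#' standard-scaled attributions (group minus rest).
#'
#' @param X Attribution matrix (samples x genes), typically adjusted.
#' @param group_mask Logical vector marking the group rows.
#' @return Data.frame `gene, stat, p, q, mean_diff, rank`, ordered by rank.
#' @export
differential_attribution <- function(X, group_mask) {
  X <- as.matrix(X)
  group_mask <- as.logical(group_mask)
  if (!any(group_mask) || all(group_mask))
    stop_filmsens("both groups must be non-empty", class = "filmsens_input_error")
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") < 1e-12] <- 0
  genes <- colnames(X) %||% paste0("g", seq_len(ncol(X)))
  res <- lapply(seq_len(ncol(X)), function(j) {
    wt <- suppressWarnings(
      stats::wilcox.test(X[group_mask, j], X[!group_mask, j],
                         alternative = "two.sided"))
    c(stat = unname(wt$statistic), p = wt$p.value)
  })
  res <- do.call(rbind, res)
  out <- data.frame(gene = genes, stat = res[, "stat"], p = res[, "p"])
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$mean_diff <- colMeans(Xs[group_mask, , drop = FALSE]) -
    colMeans(Xs[!group_mask, , drop = FALSE])
  ord <- order(out$q, out$p, -abs(out$mean_diff), out$gene)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top differential-attribution markers
#'
#' The `n` most significant genes of a DAA table; ties broken by q, then p,
#' then |mean difference|, then gene symbol (deterministic).
#'
#' @param daa A table from [differential_attribution()].
#' @param n Number of markers.
#' @return Character vector of gene symbols.
#' @export
top_markers <- function(daa, n = 10L) {
  if (!nrow(daa)) stop_filmsens("empty DAA table", class = "filmsens_input_error")
  ord <- order(daa$q, daa$p, -abs(daa$mean_diff), daa$gene)
  utils::head(daa$gene[ord], n)
}

#' Hierarchical ordering of cluster marker profiles
#'
#' Complete-linkage agglomeration on `1 - Pearson r` between cluster
#' profiles. Constant profiles (undefined correlation) are flagged and placed
#' at the maximum distance 2.
#'
#' @param marker_score_matrix Clusters x genes numeric matrix.
#' @return List `order` (leaf order of cluster indices), `tree` (`hclust`),
#'   `flagged` (constant-profile rows).
#' @export
order_clusters <- function(marker_score_matrix) {
  m <- as.matrix(marker_score_matrix)
  if (nrow(m) < 2L)
    stop_filmsens("need >= 2 cluster profiles", class = "filmsens_input_error")
  constant <- apply(m, 1L, function(r) sd(r) < 1e-12 || !is.finite(sd(r)))
  cc <- suppressWarnings(stats::cor(t(m)))
  d <- 1 - cc
  d[!is.finite(d)] <- 2
  tree <- stats::hclust(stats::as.dist(d), method = "complete")
  list(order = tree$order, tree = tree, flagged = which(constant))
}

#' Nominal-target attribution contrast for one MOA class
#'
#' For each nominal target of the class present among the gene columns,
#' tests the class's attribution rows against all other rows (two-sided
#' Wilcoxon rank-sum), BH-corrects across the class's targets, and highlights
#' the target with the largest average attribution difference.
#'
#' @param X Adjusted attribution matrix with gene colnames.
#' @param meta Attribution metadata aligned with rows of `X`.
#' @param moa MOA table with list-column `targets`.
#' @param class_id The MOA class to contrast.
#' @return Data.frame `target, stat, p, q, mean_diff` plus attribute
#'   `highlight`.
#' @export
target_attribution_contrast <- function(X, meta, moa, class_id) {
  cls <- moa$moa_class[match(meta$compound_id, moa$compound_id)]
  mask <- cls == class_id
  if (!any(mask))
    stop_filmsens("no attribution rows for class '%s'", class_id,
                  class = "filmsens_input_error")
  targets <- unique(unlist(moa$targets[moa$moa_class == class_id]))
  present <- intersect(targets, colnames(X))
  if (!length(present))
    stop_filmsens("no nominal target of class '%s' among gene columns (missing: %s)",
                  class_id, paste(targets, collapse = ", "),
                  class = "filmsens_input_error")
  res <- lapply(present, function(g) {
    wt <- suppressWarnings(stats::wilcox.test(X[mask, g], X[!mask, g]))
    data.frame(target = g, stat = unname(wt$statistic), p = wt$p.value,
               mean_diff = mean(X[mask, g]) - mean(X[!mask, g]))
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("target", "stat", "p", "q", "mean_diff")]
  attr(out, "highlight") <- out$target[which.max(out$mean_diff)]
  out
}

#' Read a STRING-dialect PPI edge list into a filtered graph
#'
#' TSV columns `protein1, protein2, combined_score` with scores on the
#' 0-1000 file scale; scores are divided by 1000 and edges kept when the
#' rescaled combined score strictly exceeds `threshold`.
#'
#' @param path Edge-list file.
#' @param threshold High-confidence cutoff on the 0-1 scale.
#' @return An undirected `igraph` graph with `weight` edge attributes.
#' @export
read_ppi_tsv <- function(path, threshold = 0.7) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  check_schema(dt, c("protein1", "protein2", "combined_score"), path)
  bad <- which(!is.finite(dt$combined_score) | dt$combined_score < 0 |
                 dt$combined_score > 1000)
  if (length(bad)) bad_rows_msg(bad, path, "combined_score outside [0, 1000]")
  dt$weight <- dt$combined_score / 1000
  dt <- dt[dt$weight > threshold, , drop = FALSE]
  g <- igraph::graph_from_data_frame(dt[, c("protein1", "protein2", "weight")],
                                     directed = FALSE)
  igraph::simplify(g, edge.attr.comb = "max")
}

#' PPI-module connectivity with two permutation nulls
#'
#' Connectivity of the subgraph induced by a target set, compared against
#' matched-size random draws from (i) a pool of available targets and (ii) a
#' pool of protein-coding genes. The default metric is the average induced
#' degree, `edges / |set|`; raw edge count and density are also reported.
#' Set members absent from the graph count as isolated nodes and are
#' reported. Empirical p uses the add-one correction
#' `(1 + #\{null >= observed\}) / (1 + n_null)`.
#'
#' @param graph An `igraph` PPI graph (e.g. from [read_ppi_tsv()]).
#' @param target_set Character vector of gene symbols.
#' @param n_null Null draws per pool.
#' @param seed Integer seed.
#' @param null_pools Named list with `targets` and/or `genes` pools.
#' @return A `filmsens_connectivity` list: `observed` (metric), `edges`,
#'   `density`, `absent`, per-pool `null` samples and `p`.
#' @export
module_connectivity <- function(graph, target_set, n_null = 1000L, seed = 1L,
                                null_pools = list()) {
  target_set <- unique(target_set)
  if (!length(target_set))
    stop_filmsens("empty target set", class = "filmsens_input_error")
  vs <- igraph::V(graph)$name
  metric_of <- function(set) {
    present <- intersect(set, vs)
    edges <- if (length(present) >= 2L)
      igraph::ecount(igraph::induced_subgraph(graph, present)) else 0L
    edges / length(set)
  }
  absent <- setdiff(target_set, vs)
  present <- intersect(target_set, vs)
  edges <- if (length(present) >= 2L)
    igraph::ecount(igraph::induced_subgraph(graph, present)) else 0L
  k <- length(target_set)
  observed <- edges / k
  set.seed(as.integer(seed))
  nulls <- lapply(null_pools, function(pool) {
    if (length(pool) < k)
      stop_filmsens("null pool smaller than the target set",
                    class = "filmsens_input_error")
    vapply(seq_len(n_null), function(i) metric_of(sample(pool, k)), numeric(1L))
  })
  ps <- vapply(nulls, function(ns) (1 + sum(ns >= observed)) / (1 + length(ns)),
               numeric(1L))
  structure(list(observed = observed, edges = edges,
                 density = if (k >= 2L) edges / choose(k, 2L) else NA_real_,
                 absent = absent, null = nulls, p = ps,
                 n_null = n_null),
            class = "filmsens_connectivity")
}

#' Randomly select one nominal target per MOA class
#'
#' Avoids over-connectivity bias from multiple pathway-adjacent targets of a
#' single class: one target is drawn uniformly per class.
#'
#' @param moa MOA table with list-column `targets`.
#' @param seed Integer seed.
#' @return Named character vector: class -> selected target.
#' @export
random_target_selection <- function(moa, seed = 1L) {
  classes <- split(moa$targets, moa$moa_class)
  set.seed(as.integer(seed))
  out <- vapply(classes, function(tl) {
    pool <- unique(unlist(tl))
    if (!length(pool))
      stop_filmsens("a class has an empty target set",
                    class = "filmsens_input_error")
    pool[sample.int(length(pool), 1L)]
  }, "")
  out
}

#' Upper-tail hypergeometric enrichment p-value
#'
#' `P(X >= k)` for `k` annotated hits in a query of size `n` drawn from a
#' universe of `N` with `K` annotated members.
#'
#' @param N Universe size.
#' @param K Annotated members in the universe.
#' @param n Query size.
#' @param k Overlap.
#' @return The upper-tail probability.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  if (k > min(K, n) || K > N || n > N || any(c(N, K, n, k) < 0))
    stop_filmsens("inconsistent counts: need k <= min(K, n) and K, n <= N",
                  class = "filmsens_input_error")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Centered principal-component projection
#'
#' Centered PCA with orthonormal loadings and a deterministic sign
#' convention: each component's largest-magnitude loading is positive.
#'
#' @param X Numeric matrix, rows = samples.
#' @param n_components Number of components.
#' @return List `scores`, `loadings`, `explained_variance` (fractions).
#' @export
pca_project <- function(X, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L)
    stop_filmsens("need > 1 rows", class = "filmsens_input_error")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  if (n_components > rank_)
    stop_filmsens("n_components (%d) exceeds matrix rank (%d)",
                  n_components, rank_, class = "filmsens_input_error")
  load <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  list(scores = scores, loadings = load,
       explained_variance = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)])
}
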
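test_that("AMI is 1 on identical partitions and invariant to label renaming", {
  a <- c(1, 1, 2, 2, 3, 3, 3)
  expect_equal(ami(a, a), 1.0)
  expect_equal(ami(a, c("x", "x", "y", "y", "z", "z", "z")), 1.0)
  b <- c(1, 2, 1, 2, 3, 3, 1)
  expect_equal(ami(a, b), ami(b, a), tolerance = 1e-12)
  expect_equal(ami(a, b), ami(a + 10, b), tolerance = 1e-12)
})

test_that("AMI matches a brute-force permutation-model oracle on a tiny case", {
  # oracle: expected MI over all 720 permutations of one labeling, then the
  # same chance adjustment with arithmetic-mean entropy normalization
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 1)
  n <- length(a)
  mi_of <- function(x, y) {
    tab <- table(x, y); mi <- 0
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      nij <- tab[i, j]
      if (nij > 0)
        mi <- mi + nij / n * log(n * nij / (sum(tab[i, ]) * sum(tab[, j])))
    }
    mi
  }
  allp <- do.call(rbind, local({
    # enumerate all permutations of 1:6 without extra packages
    res <- list()
    rec <- function(prefix, rest) {
      if (!length(rest)) { res[[length(res) + 1L]] <<- prefix; return() }
      for (r in rest) rec(c(prefix, r), setdiff(rest, r))
    }
    rec(integer(0), 1:6)
    res
  }))
  emi_oracle <- mean(apply(allp, 1, function(p) mi_of(a, b[p])))
  h <- function(x) { pr <- table(x) / n; -sum(pr * log(pr)) }
  ami_oracle <- (mi_of(a, b) - emi_oracle) / ((h(a) + h(b)) / 2 - emi_oracle)
  expect_equal(ami(a, b), ami_oracle, tolerance = 1e-10)
})

test_that("K-means AMI is near zero for shuffled labels on clustered data", {
  set.seed(14)
  X <- rbind(matrix(rnorm(250 * 2, 0), ncol = 2),
             matrix(rnorm(250 * 2, 6), ncol = 2))
  true <- rep(1:2, each = 250)
  shuffled <- sample(true)
  amis_true <- kmeans_ami(X, true, k = 2, trials = 5, seed = 3)
  amis_null <- kmeans_ami(X, shuffled, k = 2, trials = 5, seed = 3)
  expect_length(amis_true, 5L)
  expect_gt(mean(amis_true), 0.9)
  expect_lt(abs(mean(amis_null)), 0.1)
  expect_error(kmeans_ami(X, true, k = 1), class = "filmsens_input_error")
})

test_that("Leiden clustering separates blobs, is seeded, and scales with resolution", {
  set.seed(15)
  blob <- function(mu, n = 30) cbind(rnorm(n, mu[1], 0.3), rnorm(n, mu[2], 0.3))
  X2 <- rbind(blob(c(0, 0)), blob(c(10, 10)))
  cl <- leiden_clusters(X2, n_neighbors = 10, seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:30])), 1L)
  expect_identical(as.integer(cl),
                   as.integer(leiden_clusters(X2, n_neighbors = 10, seed = 1)))
  # 6 well-separated blobs: raising resolution never merges clusters
  centers <- expand.grid(x = c(0, 20, 40), y = c(0, 20))
  X6 <- do.call(rbind, lapply(seq_len(6), function(i)
    blob(as.numeric(centers[i, ]), 25)))
  k_lo <- length(unique(leiden_clusters(X6, 10, resolution = 0.1, seed = 2)))
  k_hi <- length(unique(leiden_clusters(X6, 10, resolution = 2, seed = 2)))
  expect_lte(k_lo, k_hi)
  expect_error(leiden_clusters(X2[1:5, ], n_neighbors = 10),
               class = "filmsens_input_error")
})

test_that("differential attribution finds a planted shift and matches exact enumeration", {
  set.seed(16)
  X <- matrix(rnorm(40 * 30), 40, 30,
              dimnames = list(NULL, sprintf("G%02d", 1:30)))
  mask <- rep(c(TRUE, FALSE), c(12, 28))
  X[mask, "G07"] <- X[mask, "G07"] + 5
  daa <- differential_attribution(X, mask)
  expect_equal(daa$gene[1], "G07")
  expect_lt(daa$q[1], 1e-4)
  expect_equal(daa$rank, seq_len(30))
  # 4 vs 4: p equals the exact rank-sum enumeration over all C(8,4) splits
  x8 <- c(1.3, -0.2, 0.7, 2.1, -1.0, 0.4, -0.6, 1.8)
  m8 <- rep(c(TRUE, FALSE), each = 4)
  w_obs <- sum(rank(x8)[m8]) - 4 * 5 / 2         # Wilcoxon W of the group
  combos <- combn(8, 4)
  w_all <- apply(combos, 2, function(i) sum(rank(x8)[i]) - 10)
  p_oracle <- mean(abs(w_all - 8) >= abs(w_obs - 8))  # two-sided around E[W]=8
  daa8 <- differential_attribution(matrix(x8, ncol = 1,
                                          dimnames = list(NULL, "g")), m8)
  expect_equal(daa8$p, p_oracle, tolerance = 1e-12)
  expect_error(differential_attribution(X, rep(TRUE, 40)),
               class = "filmsens_input_error")
})

test_that("null differential attribution keeps its type-I rate", {
  set.seed(17)
  X <- matrix(rnorm(60 * 1000), 60, 1000)
  daa <- differential_attribution(X, rep(c(TRUE, FALSE), 30))
  rate <- mean(daa$p < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.08)
  # BH q-values are monotone in p and never below p
  ord <- order(daa$p)
  expect_true(all(diff(daa$q[ord]) >= -1e-12))
  expect_true(all(daa$q >= daa$p - 1e-12))
  # and match a from-scratch step-up construction
  m <- nrow(daa)
  q_oracle <- rev(cummin(rev(daa$p[ord] * m / seq_len(m))))
  expect_equal(daa$q[ord], pmin(q_oracle, 1), tolerance = 1e-12)
})

test_that("top markers use the deterministic tie-break chain", {
  daa <- data.frame(gene = c("B", "A", "C", "D"),
                    stat = 1:4,
                    p = c(0.01, 0.01, 0.5, 0.2),
                    q = c(0.02, 0.02, 0.5, 0.3),
                    mean_diff = c(1, 1, 0.1, 0.4))
  expect_identical(top_markers(daa, 2), c("A", "B"))
  expect_identical(top_markers(daa[sample(4), ], 2), c("A", "B"))
  expect_length(top_markers(daa, 10), 4L)
})

test_that("cluster ordering follows complete linkage on correlation distance", {
  a <- c(1, 2, 3, 4)
  profiles <- rbind(c1 = a, c2 = a * 2 - 1,        # r = 1 -> distance 0
                    c3 = -a,                        # r = -1 -> distance 2
                    c4 = c(2, 1, 4, 3))
  oc <- order_clusters(profiles)
  expect_equal(oc$tree$height[1], 0, tolerance = 1e-12)
  m1 <- oc$tree$merge[1, ]
  expect_setequal(-m1, c(1, 2))
  expect_equal(max(oc$tree$height), 2, tolerance = 1e-12)
  # hand 3-vector complete linkage
  v <- rbind(x = c(1, 2, 4), y = c(1, 2, 3), z = c(3, 1, 2))
  d <- 1 - cor(t(v))
  hand <- stats::hclust(stats::as.dist(d), method = "complete")
  ours <- order_clusters(v)
  expect_equal(ours$tree$height, hand$height, tolerance = 1e-12)
  # constant profile flagged at maximum distance
  withflat <- rbind(v, flat = c(1, 1, 1))
  ocf <- suppressWarnings(order_clusters(withflat))
  expect_equal(unname(ocf$flagged), 4L)
})

test_that("nominal-target contrasts highlight the largest attribution difference", {
  set.seed(18)
  genes <- sprintf("G%02d", 1:20)
  X <- matrix(rnorm(30 * 20), 30, 20, dimnames = list(NULL, genes))
  meta <- data.frame(cell_line_id = rep("L", 30),
                     compound_id = sprintf("c%02d", rep(1:10, 3)))
  moa <- data.frame(compound_id = sprintf("c%02d", 1:10),
                    moa_class = rep(c("A", "B"), each = 5),
                    targets = I(c(rep(list(c("G03", "G11")), 5),
                                  rep(list("G17"), 5))))
  rowsA <- moa$moa_class[match(meta$compound_id, moa$compound_id)] == "A"
  X[rowsA, "G03"] <- X[rowsA, "G03"] + 3
  res <- target_attribution_contrast(X, meta, moa, "A")
  expect_equal(attr(res, "highlight"), "G03")
  expect_lt(res$q[res$target == "G03"], 0.01)
  # single-target class: BH leaves p unchanged
  resB <- target_attribution_contrast(X, meta, moa, "B")
  expect_equal(resB$p, resB$q)
  # missing targets are named
  moa_bad <- moa; moa_bad$targets[moa_bad$moa_class == "A"] <- list("ZZZ")
  expect_error(target_attribution_contrast(X, meta, moa_bad, "A"),
               "ZZZ", class = "filmsens_input_error")
})

test_that("module connectivity matches clique arithmetic and exhaustive nulls", {
  # 10-node graph: nodes n1..n4 a clique, n5..n10 sparse
  edges <- rbind(t(combn(paste0("n", 1:4), 2)),
                 c("n5", "n6"), c("n7", "n8"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, 2, name = c("n9", "n10"))
  clique <- module_connectivity(g, paste0("n", 1:4), n_null = 10, seed = 1,
                                null_pools = list(genes = paste0("n", 1:10)))
  expect_equal(clique$edges, 6L)
  expect_equal(clique$observed, 1.5)
  iso <- module_connectivity(g, c("n5", "n9", "n10"), n_null = 10, seed = 1,
                             null_pools = list(genes = paste0("n", 1:10)))
  expect_equal(iso$observed, 0)      # an independent set induces no edges
  expect_equal(module_connectivity(g, c("n9", "n10"), n_null = 5, seed = 1,
                                   null_pools = list())$observed, 0)
  # empirical p against exhaustive enumeration over all C(10,3) subsets
  pool <- paste0("n", 1:10)
  combos <- combn(pool, 3)
  metric <- apply(combos, 2, function(s)
    igraph::ecount(igraph::induced_subgraph(g, s)) / 3)
  target <- c("n1", "n2", "n3")
  obs <- 1  # 3 clique edges / 3
  p_exact <- mean(metric >= obs)
  mc <- module_connectivity(g, target, n_null = 4000, seed = 2,
                            null_pools = list(genes = pool))
  expect_equal(unname(mc$p["genes"]), p_exact, tolerance = 0.02)
  expect_error(module_connectivity(g, character(0)),
               class = "filmsens_input_error")
  # absent nodes are reported, not dropped
  ab <- module_connectivity(g, c("n1", "n2", "ghost"), n_null = 5, seed = 1,
                            null_pools = list())
  expect_equal(ab$absent, "ghost")
})

test_that("random target selection is uniform and seeded", {
  moa <- data.frame(compound_id = c("c1", "c2"),
                    moa_class = c("A", "B"),
                    targets = I(list(c("T1", "T2"), "T3")))
  s1 <- random_target_selection(moa, seed = 5)
  expect_identical(s1, random_target_selection(moa, seed = 5))
  expect_equal(unname(s1["B"]), "T3")
  picks <- vapply(1:1000, function(s) random_target_selection(moa, s)["A"], "")
  frac <- mean(picks == "T1")
  expect_gt(frac, 0.45); expect_lt(frac, 0.55)
  moa$targets[[2]] <- character(0)
  expect_error(random_target_selection(moa, 1), class = "filmsens_input_error")
})

test_that("hypergeometric enrichment matches hand combinatorics", {
  expect_equal(hypergeom_enrichment(10, 5, 4, 4), 5 / 210, tolerance = 1e-12)
  expect_equal(hypergeom_enrichment(10, 5, 4, 0), 1.0)
  # the full pmf sums to 1
  probs <- vapply(0:4, function(k)
    choose(5, k) * choose(5, 4 - k) / choose(10, 4), numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  expect_error(hypergeom_enrichment(10, 5, 4, 5), class = "filmsens_input_error")
  expect_error(hypergeom_enrichment(10, 12, 4, 2), class = "filmsens_input_error")
})

test_that("PCA projection is exact on low-rank data with a fixed sign convention", {
  set.seed(19)
  base <- matrix(rnorm(12 * 2), 12, 2)
  X <- base %*% matrix(rnorm(2 * 6), 2, 6)          # rank 2
  p <- pca_project(X, 2)
  recon <- p$scores %*% t(p$loadings)
  centered <- scale(X, scale = FALSE)
  expect_equal(recon, unname(centered), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(p$explained_variance) <= 1e-12))
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  # hand 3x2 eigen-decomposition oracle
  Y <- matrix(c(1, 2, 4, 1, 3, 9), 3, 2)
  ce <- scale(Y, scale = FALSE)
  ev <- eigen(crossprod(ce) / (3 - 1))
  ours <- pca_project(Y, 1)
  expect_equal(abs(as.numeric(ours$scores)), abs(as.numeric(ce %*% ev$vectors[, 1])),
               tolerance = 1e-10)
  expect_error(pca_project(X, 5), class = "filmsens_input_error")
})

test_that("the control compound set keeps classes with two fully-covered compounds", {
  lines <- paste0("L", 1:7)
  # classes A (2 compounds, full coverage), B (2 compounds, one missing a
  # line), C (1 compound) -> only A qualifies
  meta <- rbind(
    expand.grid(cell_line_id = lines, compound_id = c("a1", "a2", "b1", "c1"),
                stringsAsFactors = FALSE),
    expand.grid(cell_line_id = lines[-1], compound_id = "b2",
                stringsAsFactors = FALSE))
  moa <- data.frame(compound_id = c("a1", "a2", "b1", "b2", "c1"),
                    moa_class = c("A", "A", "B", "B", "C"))
  ccs <- select_ccs(meta, moa)
  expect_setequal(ccs$compounds, c("a1", "a2"))
  expect_equal(unname(ccs$classes[ccs$compounds]), rep("A", 2))
  # a fixture planted with 5 qualifying classes returns exactly 5
  meta5 <- expand.grid(cell_line_id = lines,
                       compound_id = sprintf("d%02d", 1:10),
                       stringsAsFactors = FALSE)
  moa5 <- data.frame(compound_id = sprintf("d%02d", 1:10),
                     moa_class = rep(paste0("K", 1:5), each = 2))
  expect_length(unique(select_ccs(meta5, moa5)$classes), 5L)
  expect_error(select_ccs(meta[1:3, ], moa), class = "filmsens_empty_result_error")
})
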
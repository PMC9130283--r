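test_that("kNN graph: neighbor counts, Jaccard identities, error paths", {
  X <- rbind(c(0, 0), c(1, 0), c(0, 1.2))
  g <- build_knn_jaccard_graph(X, k = 1)
  expect_equal(ncol(g$knn), 1)            # one out-neighbor per node
  expect_equal(nrow(g$knn), 3)
  expect_error(build_knn_jaccard_graph(X, k = 3), "k exceeds sample size")

  # identical neighbor sets give weight 1
  set.seed(1)
  Y <- rbind(matrix(rnorm(20, 0, 0.01), 10),
             matrix(rnorm(20, 10, 0.01), 10))
  gy <- build_knn_jaccard_graph(Y, k = 9)
  w <- igraph::E(gy)$weight
  expect_true(all(w > 0 & w <= 1))
  expect_true(any(abs(w - 1) < 1e-12))
})

test_that("Jaccard weights equal brute-force set computation (n = 50)", {
  set.seed(42)
  X <- matrix(rnorm(50 * 5), 50)
  k <- 7
  g <- build_knn_jaccard_graph(X, k = k)
  nbr <- g$knn
  sets <- lapply(seq_len(nrow(X)), function(i) c(i, nbr[i, ]))
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    jac <- length(intersect(sets[[i]], sets[[j]])) /
      length(union(sets[[i]], sets[[j]]))
    expect_equal(w[e], jac)
  }
  # brute-force kNN agreement
  D <- as.matrix(dist(X))
  for (i in sample(50, 5)) {
    bf <- setdiff(order(D[i, ]), i)[1:k]
    expect_setequal(nbr[i, ], bf)
  }
})

test_that("Louvain separates two cliques and handles degenerate graphs", {
  g <- igraph::disjoint_union(igraph::make_full_graph(20),
                              igraph::make_full_graph(20))
  g <- igraph::add_edges(g, c(1, 21))
  igraph::E(g)$weight <- 1
  lab <- louvain_communities(g, seed = 5)
  expect_equal(length(unique(lab)), 2)
  expect_equal(length(unique(lab[1:20])), 1)
  expect_equal(length(unique(lab[21:40])), 1)
  # modularity beats all-singletons
  expect_gt(igraph::modularity(g, lab),
            igraph::modularity(g, seq_len(40)))

  expect_equal(louvain_communities(igraph::make_empty_graph(0, directed = FALSE)),
               integer(0))
  expect_equal(louvain_communities(igraph::make_empty_graph(1, directed = FALSE)),
               1L)
})

test_that("three Gaussian blobs are recovered exactly (ARI = 1)", {
  bd <- blob_data(n_per = 200, sd = 0.5, seed = 9)
  cr <- phenocluster(bd$X, k = 30, seed = 2)
  expect_equal(length(unique(cr$labels)), 3)
  expect_equal(ari(cr$labels, bd$labels), 1)
  if (requireNamespace("mclust", quietly = TRUE))
    expect_equal(mclust::adjustedRandIndex(cr$labels, bd$labels), 1)
})

test_that("clustering is deterministic and permutation invariant", {
  bd <- blob_data(n_per = 80, sd = 0.8, seed = 3)
  a <- phenocluster(bd$X, k = 15, seed = 7)
  b <- phenocluster(bd$X, k = 15, seed = 7)
  expect_identical(a$labels, b$labels)

  set.seed(11)
  perm <- sample(nrow(bd$X))
  c2 <- phenocluster(bd$X[perm, ], k = 15, seed = 7)
  expect_equal(ari(c2$labels, a$labels[perm]), 1)
})

test_that("cluster means equal brute-force group averages", {
  set.seed(8)
  X <- matrix(runif(60 * 4), 60)
  labels <- sample(1:4, 60, replace = TRUE)
  M <- cluster_mean_matrix(X, labels)
  for (c in sort(unique(labels)))
    expect_equal(unname(M[as.character(c), ]),
                 unname(colMeans(X[labels == c, , drop = FALSE])))
  # identical cells: row equals the common profile
  Xc <- matrix(rep(c(0.2, 0.7), each = 10), 10)
  expect_equal(unname(cluster_mean_matrix(Xc, rep(1, 10))[1, ]), c(0.2, 0.7))
})

test_that("k = 30 default is recorded in every cluster result", {
  bd <- blob_data(n_per = 20, sd = 3, seed = 2)
  cr <- phenocluster(bd$X, seed = 1)
  expect_equal(cr$k_neighbors, 30)
  expect_equal(formals(phenocluster)$k, 30)
  expect_equal(cr$seed, 1L)
  expect_equal(sum(cr$cluster_sizes), nrow(bd$X))
})

test_that("optional PCA pre-reduction preserves blob separation", {
  bd <- blob_data(n_per = 100, sd = 0.5, seed = 6)
  b <- phenocluster(bd$X, k = 20, seed = 2, pca = 3)
  # every recovered cluster is pure w.r.t. the generative blobs (PCA may
  # refine, it must never merge distinct blobs)
  tab <- table(b$labels, bd$labels)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(bd$labels[b$labels == b$labels[1]])), 1)
})

test_that("embeddings: determinism, degenerate input, blob separation", {
  skip_if_not_installed("uwot")
  bd <- blob_data(n_per = 60, sd = 0.5, seed = 5)
  e1 <- embed_cells(bd$X, "umap", seed = 4)
  e2 <- embed_cells(bd$X, "umap", seed = 4)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))

  # identical rows: finite output, no exception
  Xd <- matrix(0.5, 10, 4)
  expect_true(all(is.finite(embed_cells(Xd, "umap", seed = 1))))

  expect_error(embed_cells(bd$X, "pca"), "arg")

  skip_if_not_installed("cluster")
  sil <- cluster::silhouette(bd$labels, dist(e1))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("clusters mix cells from replicate samples (no batch effect)", {
  p <- normal_lung_params("mini", n_cells = 500)
  a <- simulate_cell_table(p, seed = 21, sample_id = "A")$table
  b <- simulate_cell_table(p, seed = 22, sample_id = "B")$table
  b$cell_id <- paste0("B", b$cell_id)
  both <- rbind(as.data.frame(a), as.data.frame(b))
  both <- as_cell_table(both, table_markers(a))
  cr <- phenocluster(both, markers = classification_markers(default_panel()),
                     k = 30, seed = 3)
  for (cl in unique(cr$labels)) {
    if (sum(cr$labels == cl) < 50) next
    tabs <- table(both$sample_id[cr$labels == cl])
    frac <- tabs / sum(tabs)
    entropy <- -sum(frac[frac > 0] * log(frac[frac > 0]))
    expect_gt(entropy, 0)
  }
})
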
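#' Build the PhenoGraph-style kNN-Jaccard graph
#'
#' Exact k-nearest-neighbor search (Euclidean, ties broken by row order) on
#' the cell x marker matrix, followed by re-weighting: the undirected edge
#' between two cells connected in the directed kNN graph is weighted by the
#' Jaccard index of their neighborhood sets (the cell plus its k nearest
#' neighbors, so two cells with identical neighborhoods get weight 1);
#' zero-weight edges are dropped.
#'
#' @param X Numeric matrix (cells x markers), no missing values.
#' @param k Number of neighbors (default 30, the published setting).
#' @return An `igraph` weighted undirected graph with a `knn_k` attribute.
#' @export
build_knn_jaccard_graph <- function(X, k = 30) {
  n <- nrow(X)
  if (any(!is.finite(X))) stop("build_knn_jaccard_graph: missing values")
  if (n <= k) stop("k exceeds sample size")
  nn <- RANN::nn2(X, k = k + 1)$nn.idx
  # drop self (usually column 1; guard against exact duplicates)
  nbr <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn[i, ]
    row <- row[row != i]
    nbr[i, ] <- row[seq_len(k)]
  }
  # neighborhood sets include the cell itself
  A <- Matrix::sparseMatrix(i = c(seq_len(n), rep(seq_len(n), k)),
                            j = c(seq_len(n), as.vector(nbr)),
                            x = 1, dims = c(n, n))
  inter <- Matrix::tcrossprod(A)              # |N(i) ^ N(j)|, sets of size k+1
  E <- (A + Matrix::t(A)) > 0
  E <- Matrix::triu(E, k = 1)                 # undirected edges, no self loops
  ed <- Matrix::which(E, arr.ind = TRUE)
  iv <- as.numeric(inter[ed])
  w <- iv / (2 * (k + 1) - iv)
  keep <- w > 0
  g <- igraph::graph_from_edgelist(ed[keep, , drop = FALSE], directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- w[keep]
  g$knn_k <- k
  g$knn <- nbr                                # directed neighbor sets, row i = N(i)
  g
}

#' Louvain community detection
#'
#' Greedy modularity optimization on the weighted graph; deterministic given
#' the seed (which fixes the randomized node-visit order). Labels are
#' 1..C in decreasing community-size order.
#'
#' @param graph An `igraph` graph (weights used if present).
#' @param seed RNG seed.
#' @return Integer vector of per-node community labels.
#' @export
louvain_communities <- function(graph, seed = 1L) {
  if (igraph::vcount(graph) == 0) return(integer(0))
  set.seed(seed)
  cl <- igraph::cluster_louvain(graph)
  mem <- igraph::membership(cl)
  # relabel by decreasing size for stable downstream reporting
  sz <- sort(table(mem), decreasing = TRUE)
  lut <- stats::setNames(seq_along(sz), names(sz))
  as.integer(lut[as.character(mem)])
}

#' Per-cluster mean expression matrix
#'
#' Row `c` is the per-marker mean over the cells of cluster `c`. Empty labels
#' are excluded with a warning.
#'
#' @param X Cell x marker matrix (rescaled 0-1), or a `cell_table`.
#' @param labels Integer cluster labels aligned with rows.
#' @return Numeric matrix clusters x markers.
#' @export
cluster_mean_matrix <- function(X, labels) {
  if (inherits(X, "cell_table")) X <- feature_matrix(X)
  stopifnot(nrow(X) == length(labels))
  labs <- sort(unique(labels))
  empty <- setdiff(seq_len(max(c(labels, 0))), labs)
  if (length(empty)) warning("cluster_mean_matrix: empty label(s) excluded: ",
                             paste(empty, collapse = ", "))
  M <- rowsum(X, labels) / as.vector(table(labels))
  rownames(M) <- labs
  M
}

#' 2D embedding for visualization
#'
#' Calls the standard t-SNE (Rtsne) or UMAP (uwot) implementations; the
#' embedding is for plotting only, no downstream computation depends on it.
#' Identical seeds give identical output.
#'
#' @param X Cell x marker matrix.
#' @param method `"umap"` or `"tsne"`.
#' @param seed RNG seed.
#' @return Numeric matrix (cells x 2), columns `e1`, `e2`.
#' @export
embed_cells <- function(X, method = c("umap", "tsne"), seed = 1L) {
  method <- match.arg(method)
  n <- nrow(X)
  set.seed(seed)
  X <- X + matrix(rnorm(length(X), 0, 1e-9), n)  # guard degenerate duplicates
  emb <- if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE))
      stop("embed_cells: Rtsne not installed")
    perp <- max(1, min(30, floor((n - 1) / 3)))
    Rtsne::Rtsne(X, perplexity = perp, check_duplicates = FALSE,
                 pca = FALSE, max_iter = 500)$Y
  } else {
    if (!requireNamespace("uwot", quietly = TRUE))
      stop("embed_cells: uwot not installed")
    uwot::umap(X, n_neighbors = min(30, n - 1), n_threads = 1,
               n_sgd_threads = 1, seed = seed)
  }
  colnames(emb) <- c("e1", "e2")
  emb
}

#' PhenoGraph-style clustering of a cell table
#'
#' The full phenoclustering stage: kNN graph on the rescaled classification
#' markers, Jaccard re-weighting, Louvain communities, per-cluster mean
#' matrix, and (optionally) a 2D embedding.
#'
#' @param table A `cell_table` (or plain feature matrix).
#' @param markers Markers to cluster on; defaults to all markers of the
#'   table (the pipeline passes the panel's classification set).
#' @param k Neighbors (default 30).
#' @param seed RNG seed, recorded in the result.
#' @param embedding `"none"`, `"umap"` or `"tsne"`.
#' @param pca Optional number of principal components to pre-reduce the
#'   feature space before the kNN search (`NULL`, the default, clusters on
#'   the raw marker matrix — with ~23 markers no reduction is needed).
#' @return A `cluster_result`: list with `labels`, `cluster_means`,
#'   `cluster_sizes`, `k_neighbors`, `seed`, `embedding`.
#' @export
phenocluster <- function(table, markers = NULL, k = 30, seed = 1L,
                         embedding = "none", pca = NULL) {
  X <- if (inherits(table, "cell_table")) {
    if (is.null(markers)) markers <- table_markers(table)
    feature_matrix(table, markers)
  } else as.matrix(table)
  Xg <- if (!is.null(pca)) {
    npc <- min(as.integer(pca), ncol(X), nrow(X) - 1L)
    stats::prcomp(X, rank. = npc)$x
  } else X
  g <- build_knn_jaccard_graph(Xg, k = k)
  labels <- louvain_communities(g, seed = seed)
  res <- list(labels = labels,
              cluster_means = cluster_mean_matrix(X, labels),
              cluster_sizes = as.integer(table(labels)),
              k_neighbors = k, seed = as.integer(seed),
              embedding = NULL)
  if (!identical(embedding, "none"))
    res$embedding <- embed_cells(X, method = embedding, seed = seed)
  structure(res, class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$labels), "cells in",
      nrow(x$cluster_means), "clusters (k =", x$k_neighbors,
      ", seed =", x$seed, ")\n")
  invisible(x)
}

#' Serialize a cluster result to CSV
#'
#' Writes `cell_id, cluster, e1, e2` plus a `<path>_means.csv` with the
#' cluster mean matrix.
#'
#' @param result A `cluster_result`.
#' @param cell_ids Cell identifiers aligned with labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_result <- function(result, cell_ids, path) {
  emb <- result$embedding
  df <- data.frame(cell_id = cell_ids, cluster = result$labels,
                   e1 = if (is.null(emb)) NA_real_ else emb[, 1],
                   e2 = if (is.null(emb)) NA_real_ else emb[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  mpath <- sub("\\.csv$", "_means.csv", path)
  utils::write.csv(data.frame(cluster = rownames(result$cluster_means),
                              result$cluster_means, check.names = FALSE),
                   mpath, row.names = FALSE)
  invisible(path)
}
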
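# Shared fixtures: small, fast synthetic inputs built in code.

tiny_params <- function(..., seed = 1L) {
  normal_lung_params("mini", seed = seed, ...)
}

# A small flat-field params object for focused image tests: no structures
# beyond what the composition asks for.
flat_params <- function(n_cells = 80, field_um = c(400, 400),
                        composition = c(AT1 = 1), seed = 1L, ...) {
  tissue_params(field_um = field_um, n_cells = n_cells,
                composition = composition, placement = "field",
                seed = seed, ...)
}

# Draw a clean image of non-touching disks; returns list(img, centers).
disk_image <- function(n = 20, dim_px = c(200, 200), radius = 6,
                       value = 200, min_gap = 4, seed = 1) {
  set.seed(seed)
  img <- matrix(0L, dim_px[1], dim_px[2])
  centers <- matrix(numeric(0), ncol = 2)
  guard <- 0
  while (nrow(centers) < n && guard < 20000) {
    guard <- guard + 1
    p <- runif(2, radius + 2, dim_px - radius - 2)
    if (nrow(centers) == 0 ||
        all((centers[, 1] - p[1])^2 + (centers[, 2] - p[2])^2 >
            (2 * radius + min_gap)^2)) {
      centers <- rbind(centers, p)
      xs <- max(1, floor(p[1] - radius - 1)):min(dim_px[1], ceiling(p[1] + radius + 1))
      ys <- max(1, floor(p[2] - radius - 1)):min(dim_px[2], ceiling(p[2] + radius + 1))
      for (x in xs) for (y in ys) {
        d <- sqrt((x - p[1])^2 + (y - p[2])^2)
        cov <- min(max(radius + 0.5 - d, 0), 1)
        img[x, y] <- max(img[x, y], as.integer(round(value * cov)))
      }
    }
  }
  stopifnot(nrow(centers) == n)
  list(img = img, centers = centers)
}

# Gaussian blob data for clustering tests, in a marker-space-like
# dimensionality (kNN graphs of low-dimensional point clouds carry local
# geometric substructure that modularity legitimately resolves; marker
# profiles live in ~20 dimensions where type clouds are single communities).
blob_data <- function(n_per = 200,
                      centers = rbind(rep(0, 6),
                                      c(6, rep(0, 5)),
                                      c(0, 6, rep(0, 4))),
                      sd = 0.5, seed = 1) {
  set.seed(seed)
  d <- ncol(centers)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * d, rep(centers[i, ], each = n_per), sd), n_per)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}

# Adjusted Rand index (small closed-form implementation used as a test
# utility; cross-checked against mclust in the clustering suite).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(tab)
  si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  nt <- choose(sum(tab), 2)
  exp_idx <- si * sj / nt
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
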
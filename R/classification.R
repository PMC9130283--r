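#' Call per-cluster marker positivity
#'
#' Decides, for every (cluster, marker) pair, whether the cluster expresses
#' the marker, from the cluster mean-expression matrix (rescaled 0-1).
#'
#' Methods:
#' * `"kmeans"` (default): per marker, split the across-cluster means into a
#'   low and a high group by 1-D 2-means; clusters above the midpoint of the
#'   two centers are positive. If the centers are closer than `min_sep`
#'   (no real positive population) every cluster is negative. Robust to
#'   markers expressed by many clusters (e.g. pan-epithelial) and to
#'   intermediate-level populations.
#' * `"zscore"`: positive when the cluster mean exceeds the across-cluster
#'   mean + `z` x SD (strict inequality, so a zero-variance marker is called
#'   negative everywhere).
#' * `"fixed"`: positive above the absolute `fixed_cutoff`. Also the
#'   fallback when only one cluster exists.
#'
#' @param cluster_means Clusters x markers matrix (0-1 scale).
#' @param method `"kmeans"`, `"zscore"` or `"fixed"`.
#' @param z Z-score multiplier for `"zscore"`.
#' @param min_sep Minimum center separation for `"kmeans"` (0-1 scale).
#' @param fixed_cutoff Absolute cutoff for `"fixed"`/single-cluster fallback.
#' @return Logical matrix, clusters x markers.
#' @export
call_marker_positivity <- function(cluster_means,
                                   method = c("kmeans", "zscore", "fixed"),
                                   z = 1, min_sep = 0.1, fixed_cutoff = 0.25) {
  method <- match.arg(method)
  cm <- as.matrix(cluster_means)
  out <- matrix(FALSE, nrow(cm), ncol(cm), dimnames = dimnames(cm))
  if (nrow(cm) == 1 && method != "fixed") method <- "fixed"
  for (j in seq_len(ncol(cm))) {
    v <- cm[, j]
    out[, j] <- switch(method,
      fixed = v > fixed_cutoff,
      zscore = v > mean(v) + z * stats::sd(v),
      kmeans = {
        if (max(v) - min(v) < min_sep) rep(FALSE, length(v)) else {
          km <- stats::kmeans(v, centers = range(v))
          ctr <- sort(km$centers[, 1])
          if (diff(ctr) < min_sep) rep(FALSE, length(v))
          else v > mean(ctr)
        }
      })
  }
  out
}

#' Assign cell types to phenoclusters
#'
#' Scores every cluster against every signature row:
#' `score = #POS matched - #POS missed - penalty * #NEG violated`, the
#' argmax wins, with three overriding rules:
#' 1. a cluster whose positive markers span two or more mutually exclusive
#'    lineage compartments is discarded as a hybrid artifact (juxtaposed
#'    cells merged by nucleus-seeded segmentation);
#' 2. a cluster with no positive marker is discarded as a null phenotype
#'    (uninterpretable);
#' 3. a cluster positive for at least one AT1-restricted and one
#'    AT2-restricted marker is the transitional AT type (the defining
#'    co-expression), overriding the argmax.
#' Ties are broken by the fixed row order of the signature matrix.
#'
#' @param positivity Logical clusters x markers matrix.
#' @param signature A [build_signature_matrix()] result.
#' @param penalty Weight of NEG violations.
#' @param lineage Named marker -> compartment vector; `NULL` uses the
#'   packaged [lineage_groups()].
#' @return A `cell_type_assignment` data.frame: `cluster`, `type` (or
#'   `"DISCARD"`), `score`, `reason`, plus a `scores` attribute (cluster x
#'   type matrix).
#' @export
assign_cluster_types <- function(positivity, signature, penalty = 1,
                                 lineage = NULL) {
  if (is.null(lineage)) lineage <- lineage_groups()
  markers <- intersect(colnames(positivity), colnames(signature))
  sig <- signature[, markers, drop = FALSE]
  pos <- positivity[, markers, drop = FALSE]
  types <- rownames(sig)
  sets <- alveolar_marker_sets(signature)

  score_mat <- matrix(NA_real_, nrow(pos), length(types),
                      dimnames = list(rownames(pos), types))
  res <- data.frame(cluster = if (is.null(rownames(pos)))
                      seq_len(nrow(pos)) else rownames(pos),
                    type = NA_character_, score = NA_real_,
                    reason = "", stringsAsFactors = FALSE)
  for (ci in seq_len(nrow(pos))) {
    p <- pos[ci, ]
    for (ti in seq_along(types)) {
      s <- sig[ti, ]
      score_mat[ci, ti] <- sum(p & s == "POS") - sum(!p & s == "POS") -
        penalty * sum(p & s == "NEG")
    }
    on <- markers[p]
    if (length(on) == 0) {
      res$type[ci] <- "DISCARD"; res$reason[ci] <- "null phenotype"
      next
    }
    gr <- unique(lineage[on[on %in% names(lineage)]])
    if (length(gr) >= 2) {
      res$type[ci] <- "DISCARD"
      res$reason[ci] <- paste0("hybrid lineage: ",
                               paste(sort(gr), collapse = "+"))
      next
    }
    if (any(sets$at1 %in% on) && any(sets$at2 %in% on)) {
      res$type[ci] <- "transitional_AT"
      res$score[ci] <- score_mat[ci, "transitional_AT"]
      res$reason[ci] <- "AT1+AT2 co-expression"
      next
    }
    best <- which.max(score_mat[ci, ])      # first max = fixed priority order
    res$type[ci] <- types[best]
    res$score[ci] <- score_mat[ci, best]
  }
  attr(res, "scores") <- score_mat
  attr(res, "positivity") <- pos
  class(res) <- c("cell_type_assignment", class(res))
  res
}

#' Merge assigned clusters into major types
#'
#' Maps fine labels to the major types (alveolar subtypes merge into
#' `alveolar`, everything else stays itself); `DISCARD` clusters stay
#' discarded and are excluded from all composition denominators downstream.
#'
#' @param assignment A `cell_type_assignment`.
#' @param all_stromal If `TRUE`, also merge `myofibroblast_smc` and
#'   `stromal` into `all_stromal`.
#' @return Named character vector cluster -> major type.
#' @export
merge_major_types <- function(assignment, all_stromal = FALSE) {
  if (nrow(assignment) == 0) return(stats::setNames(character(0), character(0)))
  mm <- major_type_map()
  if (all_stromal) mm[c("myofibroblast_smc", "stromal")] <- "all_stromal"
  mm <- c(mm, DISCARD = "DISCARD")
  stats::setNames(unname(mm[assignment$type]), assignment$cluster)
}

#' Classify all cells of a clustered table
#'
#' Runs positivity calling, signature scoring and major-type merging on a
#' clustering result and appends `cluster`, `cell_type` and `major_type`
#' columns to the cell table. Cells of discarded clusters carry
#' `"DISCARD"`.
#'
#' @param table A `cell_table`.
#' @param clustering A `cluster_result` aligned with `table` rows.
#' @param panel Marker panel (for the signature); default packaged panel.
#' @param positivity_method,penalty,... Passed to
#'   [call_marker_positivity()] / [assign_cluster_types()].
#' @return The annotated `cell_table`, with the `assignment` attached as an
#'   attribute.
#' @export
classify_cells <- function(table, clustering, panel = default_panel(),
                           positivity_method = "kmeans", penalty = 1, ...) {
  sig <- build_signature_matrix(panel)
  cm <- clustering$cluster_means[, intersect(colnames(clustering$cluster_means),
                                             colnames(sig)), drop = FALSE]
  pos <- call_marker_positivity(cm, method = positivity_method, ...)
  asg <- assign_cluster_types(pos, sig, penalty = penalty)
  map <- stats::setNames(asg$type, asg$cluster)
  mmap <- merge_major_types(asg)
  table$cluster <- clustering$labels
  table$cell_type <- unname(map[as.character(clustering$labels)])
  table$major_type <- unname(mmap[as.character(clustering$labels)])
  attr(table, "assignment") <- asg
  table
}
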
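#' Per-sample cell-type composition
#'
#' Percentages of each fine type and each major type per sample, computed
#' over classified cells only (discarded artifact clusters are excluded from
#' every denominator). Derived aggregates `alveolar_total` (AT1 + AT2 +
#' transitional AT) and `all_stromal` (stromal + myofibroblast/SMC) are
#' included.
#'
#' @param table A classified `cell_table` (with `cell_type` column).
#' @return A `composition_table` data.frame: one row per (sample, label)
#'   with `percent`, `n_cells`, plus per-sample `n_classified`/`n_discarded`
#'   in the `counts` attribute.
#' @export
composition <- function(table) {
  if (is.null(table$cell_type)) stop("composition: no cell_type column")
  samples <- unique(table$sample_id)
  rows <- list(); counts <- list()
  for (s in samples) {
    sub <- table[table$sample_id == s, ]
    cls <- sub$cell_type[sub$cell_type != "DISCARD" & !is.na(sub$cell_type)]
    n <- length(cls)
    if (n == 0) stop("composition: zero classified cells in sample ", s)
    tab <- table(factor(cls, levels = cell_type_labels()))
    pct <- 100 * as.numeric(tab) / n
    fine <- data.frame(sample_id = s, label = names(tab), level = "fine",
                       percent = pct, n_cells = as.integer(tab))
    mm <- major_type_map()
    mtab <- tapply(as.numeric(tab), mm[names(tab)], sum)
    major <- data.frame(sample_id = s, label = names(mtab), level = "major",
                        percent = 100 * as.numeric(mtab) / n,
                        n_cells = as.integer(mtab))
    agg <- data.frame(
      sample_id = s,
      label = c("alveolar_total", "all_stromal"),
      level = "aggregate",
      percent = c(sum(pct[names(tab) %in% c("AT1", "AT2", "transitional_AT")]),
                  sum(pct[names(tab) %in% c("stromal", "myofibroblast_smc")])),
      n_cells = c(sum(tab[c("AT1", "AT2", "transitional_AT")]),
                  sum(tab[c("stromal", "myofibroblast_smc")])))
    rows[[s]] <- rbind(fine, major, agg)
    counts[[s]] <- data.frame(sample_id = s, n_classified = n,
                              n_discarded = sum(sub$cell_type == "DISCARD",
                                                na.rm = TRUE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "counts") <- do.call(rbind, counts)
  class(out) <- c("composition_table", class(out))
  out
}

#' Group composition statistics (mean +/- SD across samples)
#'
#' Unweighted across-sample mean and SD of the per-sample percentages, per
#' treatment group.
#'
#' @param comp A [composition()] result.
#' @param groups Named vector sample_id -> group; `NULL` treats all samples
#'   as one group.
#' @return data.frame `group`, `label`, `level`, `mean`, `sd`, `n_samples`.
#' @export
composition_groups <- function(comp, groups = NULL) {
  if (is.null(groups))
    groups <- stats::setNames(rep("all", length(unique(comp$sample_id))),
                              unique(comp$sample_id))
  comp$group <- unname(groups[comp$sample_id])
  sp <- split(comp, list(comp$group, comp$label, comp$level), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(group = d$group[1], label = d$label[1], level = d$level[1],
               mean = mean(d$percent),
               sd = if (nrow(d) > 1) stats::sd(d$percent) else 0,
               n_samples = nrow(d))))
  rownames(out) <- NULL
  out
}

#' Per-type marker intensity summaries (Tukey boxplot statistics)
#'
#' Median, quartiles, 1.5 x IQR whiskers and outlier count of a marker's
#' rescaled (0-1) intensity per major type, optionally per group.
#'
#' @param table A classified `cell_table`.
#' @param marker Marker short name (default `"P-gP"`).
#' @param groups Optional named vector sample_id -> group.
#' @return An `intensity_summary` data.frame: `major_type`, `group`,
#'   `lower_whisker`, `q1`, `median`, `q3`, `upper_whisker`, `n_outliers`,
#'   `n_cells`.
#' @export
marker_by_type <- function(table, marker = "P-gP", groups = NULL) {
  col <- paste0(marker, "_scaled")
  if (!col %in% names(table)) stop("marker_by_type: unknown marker: ", marker)
  if (is.null(table$major_type)) stop("marker_by_type: table not classified")
  keep <- !is.na(table$major_type) & table$major_type != "DISCARD"
  sub <- as.data.frame(table)[keep, ]
  sub$group <- if (is.null(groups)) "all" else unname(groups[sub$sample_id])
  sp <- split(sub, list(sub$major_type, sub$group), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    bs <- grDevices::boxplot.stats(d[[col]])
    data.frame(major_type = d$major_type[1], group = d$group[1],
               lower_whisker = bs$stats[1], q1 = bs$stats[2],
               median = bs$stats[3], q3 = bs$stats[4],
               upper_whisker = bs$stats[5],
               n_outliers = length(bs$out), n_cells = nrow(d))
  }))
  rownames(out) <- NULL
  class(out) <- c("intensity_summary", class(out))
  out
}

#' Composition trajectories across a treatment time course
#'
#' Group mean +/- SD of every label's percentage per timepoint, plus the L1
#' (total variation x 2) distance of each timepoint's mean fine composition
#' from the first (control) timepoint.
#'
#' @param comp A [composition()] result covering all samples.
#' @param timepoints Named vector sample_id -> timepoint label.
#' @param order Timepoint ordering; defaults to the order of first
#'   appearance.
#' @return List with `trajectory` (data.frame label x timepoint stats) and
#'   `l1_to_control` (named numeric).
#' @export
timecourse_report <- function(comp, timepoints, order = NULL) {
  if (length(unique(unname(timepoints))) < 2)
    stop("timecourse_report: need >= 2 timepoints")
  if (is.null(order)) order <- unique(unname(timepoints))
  gr <- composition_groups(comp, groups = timepoints)
  gr$group <- factor(gr$group, levels = order)
  gr <- gr[order(gr$group, gr$label), ]
  fine <- gr[gr$level == "fine", ]
  ctrl <- fine[fine$group == order[1], ]
  ref <- stats::setNames(ctrl$mean, ctrl$label)
  l1 <- vapply(order, function(tp) {
    d <- fine[fine$group == tp, ]
    sum(abs(stats::setNames(d$mean, d$label)[names(ref)] - ref))
  }, numeric(1))
  list(trajectory = gr, l1_to_control = l1)
}
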
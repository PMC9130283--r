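#' Sample a virtual TMA core from a cell table
#'
#' Pure filter: rows whose centroid (micron coordinates) lies strictly
#' inside the circle.
#'
#' @param table A `cell_table`.
#' @param center_um Circle center `c(x, y)` in microns.
#' @param diameter_mm Core diameter in mm.
#' @param bounds_um Section bounds `c(x, y)` in microns; default inferred
#'   from the table extent. The circle must lie inside the bounds.
#' @return The filtered `cell_table`.
#' @export
sample_core <- function(table, center_um, diameter_mm,
                        bounds_um = c(max(table$x_um), max(table$y_um))) {
  r <- diameter_mm * 1000 / 2
  if (center_um[1] - r < 0 || center_um[2] - r < 0 ||
      center_um[1] + r > bounds_um[1] || center_um[2] + r > bounds_um[2])
    stop("sample_core: circle out of section bounds")
  d2 <- (table$x_um - center_um[1])^2 + (table$y_um - center_um[2])^2
  out <- table[d2 < r^2, ]
  attr(out, "markers") <- table_markers(table)
  class(out) <- class(table)
  out
}

#' Is a population identifiable in a clustered, classified result?
#'
#' Operationalizes "rediscovered": the population counts as identified when
#' some cluster is assigned to it with at least `min_cells` cells and a
#' signature completeness (fraction of the type's POS markers called
#' positive in that cluster) of at least `min_purity`.
#'
#' @param assignment A `cell_type_assignment` (with its `positivity`
#'   attribute).
#' @param cluster_sizes Integer sizes aligned with assignment rows.
#' @param population Major-type label to look for.
#' @param signature The signature matrix used for assignment.
#' @param min_cells Minimum cluster size (default 20).
#' @param min_purity Minimum signature completeness (default 0.6).
#' @return Logical.
#' @export
population_identifiable <- function(assignment, cluster_sizes, population,
                                    signature, min_cells = 20,
                                    min_purity = 0.6) {
  mm <- c(major_type_map(), DISCARD = "DISCARD")
  pos <- attr(assignment, "positivity")
  hit <- which(mm[assignment$type] == population |
                 assignment$type == population)
  for (ci in hit) {
    if (cluster_sizes[ci] < min_cells) next
    ty <- assignment$type[ci]
    ps <- colnames(signature)[signature[ty, ] == "POS"]
    ps <- intersect(ps, colnames(pos))
    completeness <- if (length(ps)) mean(pos[ci, ps]) else 0
    if (completeness >= min_purity) return(TRUE)
  }
  FALSE
}

#' Core-size adequacy test
#'
#' Re-clusters and re-classifies every core independently with the same
#' configuration as the whole section and checks whether all main
#' populations found in the whole-section analysis are rediscovered. A core
#' is adequate iff nothing is missing; cores with fewer than `k + 1` cells
#' are reported as having insufficient cells.
#'
#' @param whole_table A classified whole-section `cell_table` (from
#'   [classify_cells()]).
#' @param core_tables Named list of `cell_table`s (e.g. from
#'   [sample_core()]).
#' @param panel Marker panel.
#' @param k kNN parameter (default 30).
#' @param seed Seed used for every re-clustering.
#' @param min_cells,min_purity Identifiability thresholds.
#' @param populations Populations that must be rediscovered; default: the
#'   major types identifiable in the whole-section result.
#' @return List of `adequacy_report`s (one per core): core name, n_cells,
#'   populations expected/recovered/missing, verdict.
#' @export
adequacy_test <- function(whole_table, core_tables, panel = default_panel(),
                          k = 30, seed = 1L, min_cells = 20,
                          min_purity = 0.6, populations = NULL) {
  sig <- build_signature_matrix(panel)
  cls_markers <- classification_markers(panel)
  if (is.null(populations)) {
    wa <- attr(whole_table, "assignment")
    if (is.null(wa)) stop("adequacy_test: whole_table lacks its assignment")
    wsz <- as.integer(table(whole_table$cluster))
    majors <- unique(unname(major_type_map()))
    populations <- majors[vapply(majors, function(p)
      population_identifiable(wa, wsz, p, sig, min_cells, min_purity),
      logical(1))]
  }
  reports <- list()
  for (nm in names(core_tables)) {
    ct <- core_tables[[nm]]
    n <- nrow(ct)
    if (n < k + 1) {
      reports[[nm]] <- structure(
        list(core = nm, n_cells = n, populations_expected = populations,
             populations_recovered = character(0),
             missing = populations, adequate = FALSE,
             note = "insufficient cells"),
        class = "adequacy_report")
      next
    }
    cr <- phenocluster(ct, markers = intersect(cls_markers,
                                               table_markers(ct)),
                       k = k, seed = seed)
    cc <- classify_cells(ct, cr, panel)
    asg <- attr(cc, "assignment")
    sz <- as.integer(table(cr$labels))
    rec <- populations[vapply(populations, function(p)
      population_identifiable(asg, sz, p, sig, min_cells, min_purity),
      logical(1))]
    reports[[nm]] <- structure(
      list(core = nm, n_cells = n, populations_expected = populations,
           populations_recovered = rec,
           missing = setdiff(populations, rec),
           adequate = length(setdiff(populations, rec)) == 0, note = ""),
      class = "adequacy_report")
  }
  reports
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf("core %s: %d cells, %s%s\n", x$core, x$n_cells,
              if (x$adequate) "ADEQUATE" else
                paste("missing:", paste(x$missing, collapse = ", ")),
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Run the full virtual-TMA core-size validation
#'
#' Simulates one whole section, runs the whole-section clustering +
#' classification, plants `cores_per_diameter` virtual cores per requested
#' diameter, and runs [adequacy_test()] on each.
#'
#' @param params Whole-section [tissue_params()]; default the
#'   `whole_section` preset.
#' @param diameters_mm Core diameters (default 1 and 2 mm).
#' @param cores_per_diameter Cores per diameter (default 4).
#' @param seed Master seed.
#' @param k,min_cells,min_purity See [adequacy_test()].
#' @param panel Marker panel.
#' @return List with `reports`, `per_diameter` (fraction of adequate cores
#'   and macrophage-recovery fraction per diameter), `whole_populations`.
#' @export
tma_validation <- function(params = normal_lung_params("whole_section"),
                           diameters_mm = c(1, 2), cores_per_diameter = 4,
                           seed = 1L, k = 30, min_cells = 20,
                           min_purity = 0.6, panel = default_panel()) {
  sim <- simulate_cell_table(params, seed = derive_seed(seed, 1))
  tab <- sim$table
  cr <- phenocluster(tab, markers = classification_markers(panel),
                     k = k, seed = derive_seed(seed, 2))
  whole <- classify_cells(tab, cr, panel)

  set.seed(derive_seed(seed, 3))
  dia <- rep(diameters_mm, each = cores_per_diameter)
  layout <- plant_core_layout(params, dia)
  mpp <- params$microns_per_pixel
  cores <- list()
  for (i in seq_len(nrow(layout))) {
    nm <- sprintf("d%gmm_c%d", layout$diameter_mm[i],
                  sum(dia[seq_len(i)] == dia[i]))
    cores[[nm]] <- sample_core(tab,
                               center_um = c(layout$x_px[i], layout$y_px[i]) * mpp,
                               diameter_mm = layout$diameter_mm[i],
                               bounds_um = params$field_um)
  }
  reports <- adequacy_test(whole, cores, panel, k = k,
                           seed = derive_seed(seed, 4),
                           min_cells = min_cells, min_purity = min_purity)
  per_d <- do.call(rbind, lapply(unique(dia), function(d) {
    rs <- reports[dia == d]
    data.frame(diameter_mm = d,
               n_cores = length(rs),
               frac_adequate = mean(vapply(rs, `[[`, logical(1), "adequate")),
               frac_macrophage = mean(vapply(rs, function(r)
                 !"macrophage" %in% r$missing, logical(1))))
  }))
  list(reports = reports, per_diameter = per_d,
       whole_populations = reports[[1]]$populations_expected)
}
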
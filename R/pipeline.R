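#' Pipeline run configuration
#'
#' One object carrying every stage parameter plus the master seed; each
#' stochastic stage consumes a sub-seed derived deterministically from it
#' (see [derive_seed()]).
#'
#' @param panel_path Panel YAML; `NULL` uses the packaged default.
#' @param preset Tissue preset name for simulated input.
#' @param threshold Segmentation threshold method.
#' @param ring_px Cytoplasmic ring width (px).
#' @param min_area_px Minimum nucleus area.
#' @param k kNN parameter (default 30, recorded in every cluster result).
#' @param positivity_method,positivity_z Positivity calling settings.
#' @param penalty NEG-violation penalty in type scoring.
#' @param adequacy_min_cells,adequacy_min_purity TMA thresholds.
#' @param embedding `"none"`, `"umap"` or `"tsne"`.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
pipeline_config <- function(panel_path = NULL, preset = "core2mm",
                            threshold = "isodata", ring_px = 2,
                            min_area_px = 20, k = 30,
                            positivity_method = "kmeans", positivity_z = 1,
                            penalty = 1, adequacy_min_cells = 20,
                            adequacy_min_purity = 0.6, embedding = "none",
                            seed = 1L) {
  cfg <- list(panel_path = panel_path, preset = preset, threshold = threshold,
              ring_px = ring_px, min_area_px = min_area_px, k = k,
              positivity_method = positivity_method,
              positivity_z = positivity_z, penalty = penalty,
              adequacy_min_cells = adequacy_min_cells,
              adequacy_min_purity = adequacy_min_purity,
              embedding = embedding, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline end to end
#'
#' Stages, in order: synthetic acquisition (or a provided stack) ->
#' registration onto the round-1 DAPI frame -> autofluorescence subtraction
#' -> DAPI nuclear segmentation -> ring expansion -> feature extraction ->
#' phenoclustering (k = 30) -> signature classification -> composition.
#' Every output carries the seed and a configuration hash; outputs are
#' written under `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @param stack Optional [image_stack()] input; by default a synthetic
#'   section is generated from `config$preset`.
#' @param effect Optional [treatment_preset()] effect for the simulation.
#' @param out_dir Optional output directory.
#' @param sample_id Sample identifier.
#' @return List with `table` (classified `cell_table`), `clustering`,
#'   `assignment`, `composition`, `nuclei`, `transforms`, `truth` (when
#'   simulated), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), stack = NULL,
                         effect = NULL, out_dir = NULL, sample_id = "S1") {
  panel <- if (is.null(config$panel_path)) default_panel() else
    load_panel(config$panel_path)
  truth <- NULL
  if (is.null(stack)) {
    params <- normal_lung_params(config$preset,
                                 seed = derive_seed(config$seed, 1))
    sec <- generate_section(params, effect = effect, panel = panel)
    stack <- sec$stack
    truth <- sec$truth
  }

  aligned <- register_stack(stack)
  transforms <- attr(aligned, "transforms")
  rm(stack); invisible(gc(FALSE))           # 8-bit stacks are large; free early
  clean <- subtract_stack_af(aligned)
  rm(aligned); invisible(gc(FALSE))

  dapi <- stack_image(clean, round = 1, channel = "DAPI")
  nuclei <- segment_nuclei(dapi, min_area_px = config$min_area_px,
                           method = config$threshold)
  cells <- expand_to_cells(nuclei, ring_px = config$ring_px)

  tab <- extract_features(clean, cells, panel, sample_id = sample_id)
  rm(clean); invisible(gc(FALSE))
  clustering <- phenocluster(tab, markers = classification_markers(panel),
                             k = config$k,
                             seed = derive_seed(config$seed, 2),
                             embedding = config$embedding)
  tab <- classify_cells(tab, clustering, panel,
                        positivity_method = config$positivity_method,
                        z = config$positivity_z, penalty = config$penalty)
  comp <- composition(tab)

  cfg_hash <- substr(.config_hash(config), 1, 12)
  res <- list(table = tab, clustering = clustering,
              assignment = attr(tab, "assignment"),
              composition = comp, nuclei = nuclei,
              transforms = transforms,
              truth = truth, config = config,
              config_hash = cfg_hash, seed = config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cell_table(tab, file.path(out_dir, "cell_table.csv"))
    write_cluster_result(clustering, tab$cell_id,
                         file.path(out_dir, "clusters.csv"))
    utils::write.csv(as.data.frame(comp),
                     file.path(out_dir, "composition.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(res$assignment),
                     file.path(out_dir, "assignment.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, config_hash = cfg_hash,
           config = unclass(config),
           transforms = lapply(res$transforms, unclass),
           n_cells = nrow(tab),
           n_clusters = nrow(clustering$cluster_means),
           n_discarded = sum(tab$cell_type == "DISCARD")),
      file.path(out_dir, "run_meta.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  res
}

.config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  # small deterministic polynomial hash; avoids external digest deps
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Match pipeline cells to ground-truth cells by centroid
#'
#' Greedy nearest-centroid matching within a radius, used to benchmark
#' segmentation and end-to-end phenotyping against the generator's ground
#' truth.
#'
#' @param table A `cell_table` (or any data.frame with `x_px`, `y_px`).
#' @param truth A generator ground-truth data.frame.
#' @param radius_px Match radius (default 5).
#' @return data.frame `cell_idx`, `truth_idx`, `dist` (one row per matched
#'   pair; unmatched entries absent).
#' @export
match_to_truth <- function(table, truth, radius_px = 5) {
  if (nrow(table) == 0 || nrow(truth) == 0)
    return(data.frame(cell_idx = integer(0), truth_idx = integer(0),
                      dist = numeric(0)))
  nn <- RANN::nn2(truth[, c("x_px", "y_px")], table[, c("x_px", "y_px")],
                  k = 1)
  cand <- data.frame(cell_idx = seq_len(nrow(table)),
                     truth_idx = nn$nn.idx[, 1], dist = nn$nn.dists[, 1])
  cand <- cand[cand$dist <= radius_px, ]
  cand <- cand[order(cand$dist), ]
  cand <- cand[!duplicated(cand$truth_idx), ]
  cand[order(cand$cell_idx), ]
}
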
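#' @importFrom stats median sd quantile rnorm runif rbeta kmeans setNames
#' @importFrom utils read.csv write.csv head
NULL

#' Cell-type vocabulary
#'
#' The fixed label vocabulary of the pipeline: the eight major lung cell types
#' with the alveolar epithelium subdivided into its AT1, AT2 and transitional
#' AT1/AT2 subtypes, and myofibroblasts/smooth-muscle kept separate from other
#' stromal cells (the two are groupable as "all stromal" downstream).
#'
#' @return Character vector of the 11 cell-type labels, in the fixed priority
#'   order used for tie-breaking during cluster assignment.
#' @export
cell_type_labels <- function() {
  c("AT1", "AT2", "transitional_AT", "bronchial_goblet",
    "vasculature", "myofibroblast_smc", "stromal",
    "T_cell", "B_cell", "macrophage", "neutrophil")
}

#' Major-type grouping of the fine cell-type labels
#'
#' Maps each fine label to its major type: the three alveolar subtypes merge
#' into `alveolar`; every other label is its own major type.
#'
#' @return Named character vector, names are fine labels.
#' @export
major_type_map <- function() {
  lab <- cell_type_labels()
  major <- lab
  major[lab %in% c("AT1", "AT2", "transitional_AT")] <- "alveolar"
  names(major) <- lab
  major
}

.channels <- c("FITC", "TRITC", "FARRED", "DAPI")

#' Load a marker panel from a YAML file
#'
#' Reads the staining design: one record per primary antibody with its short
#' name, staining round, fluor channel, host species/isotype, the cell types
#' it is a signature for, and whether it enters the classification feature
#' set. The packaged default (`default_panel()`) is the 24-antibody, 11-round
#' mouse lung design.
#'
#' @param path Path to a panel YAML file.
#' @return A `marker_panel` object.
#' @export
load_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$markers) || length(doc$markers) == 0)
    stop("panel validation: panel defines zero markers")
  mk <- do.call(rbind, lapply(doc$markers, function(m) {
    data.frame(short_name = as.character(m$short_name),
               round = as.integer(m$round),
               channel = as.character(m$channel),
               host = as.character(m$host %||% ""),
               classify = isTRUE(m$classify %||% TRUE),
               stringsAsFactors = FALSE)
  }))
  targets <- lapply(doc$markers, function(m) as.character(unlist(m$targets)))
  names(targets) <- mk$short_name
  p <- structure(list(markers = mk, targets = targets,
                      n_rounds = as.integer(doc$n_rounds %||% max(mk$round)),
                      name = doc$name %||% basename(path)),
                 class = "marker_panel")
  validate_panel(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a marker panel
#'
#' Enforces the panel invariants: unique marker names, known channel tokens,
#' rounds >= 1, at most 3 non-DAPI markers per round (the design carries 3
#' fluor channels plus DAPI), one fluor channel per marker per round, every
#' round carrying at least one marker, and target labels drawn from
#' [cell_type_labels()].
#'
#' @param panel A `marker_panel`.
#' @return The panel, invisibly; stops with a validation error otherwise.
#' @export
validate_panel <- function(panel) {
  mk <- panel$markers
  if (anyDuplicated(mk$short_name))
    stop("panel validation: duplicate marker short_name: ",
         paste(unique(mk$short_name[duplicated(mk$short_name)]), collapse = ", "))
  bad <- setdiff(mk$channel, .channels)
  if (length(bad)) stop("panel validation: unknown channel token: ",
                        paste(bad, collapse = ", "))
  if (any(mk$round < 1L)) stop("panel validation: staining_round must be >= 1")
  nd <- mk[mk$channel != "DAPI", ]
  per_round <- table(nd$round)
  if (any(per_round > 3))
    stop("panel validation: more than 3 non-DAPI markers in round ",
         paste(names(per_round)[per_round > 3], collapse = ", "))
  rc <- paste(nd$round, nd$channel)
  if (anyDuplicated(rc))
    stop("panel validation: duplicated round+channel pair: ",
         paste(unique(rc[duplicated(rc)]), collapse = "; "))
  if (!all(seq_len(panel$n_rounds) %in% mk$round))
    stop("panel validation: every round must carry at least one marker")
  badt <- setdiff(unlist(panel$targets), cell_type_labels())
  if (length(badt))
    stop("panel validation: unknown cell-type label in targets: ",
         paste(badt, collapse = ", "))
  invisible(panel)
}

#' The packaged default mouse lung panel
#'
#' @return The 24-marker, 11-round `marker_panel` shipped with the package.
#' @export
default_panel <- function() {
  load_panel(system.file("extdata", "mouse_lung_panel.yaml",
                         package = "plexlung"))
}

#' Write a marker panel to YAML
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p, f))` reproduces `p`
#' field for field.
#'
#' @param panel A `marker_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  mk <- panel$markers
  doc <- list(
    name = panel$name, n_rounds = panel$n_rounds,
    markers = lapply(seq_len(nrow(mk)), function(i) {
      list(short_name = mk$short_name[i], round = mk$round[i],
           channel = mk$channel[i], host = mk$host[i],
           classify = mk$classify[i],
           targets = as.list(panel$targets[[mk$short_name[i]]]))
    }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Markers used for classification
#'
#' The non-DAPI markers flagged `classify: true`. For the default panel this
#' is 23 of the 24 primaries (BCRP is carried as measured-only); these are the
#' features the phenoclustering runs on.
#'
#' @param panel A `marker_panel`.
#' @return Character vector of marker short names.
#' @export
classification_markers <- function(panel) {
  mk <- panel$markers
  mk$short_name[mk$classify & mk$channel != "DAPI"]
}

#' Build the cell-type signature matrix
#'
#' Converts the per-marker target lists into a cell-type x marker matrix with
#' entries `POS` (the marker is a signature of that type), `NEG` (signature of
#' some other type, so its presence argues against this one) or `ANY`
#' (lineage-neutral markers with no targets, e.g. P-gP). The transitional AT
#' row is positive for both the AT1-restricted and the AT2-restricted marker
#' sets, encoding its defining co-expression.
#'
#' @param panel A `marker_panel`.
#' @param types Cell-type rows; defaults to the full vocabulary.
#' @return A character matrix of class `signature_matrix`.
#' @export
build_signature_matrix <- function(panel, types = cell_type_labels()) {
  markers <- classification_markers(panel)
  sig <- matrix("ANY", nrow = length(types), ncol = length(markers),
                dimnames = list(types, markers))
  for (m in markers) {
    tg <- panel$targets[[m]]
    if (length(tg) == 0) next
    sig[, m] <- ifelse(types %in% tg, "POS", "NEG")
  }
  npos <- rowSums(sig == "POS")
  if (any(npos == 0))
    stop("signature matrix: cell type with no POS marker: ",
         paste(types[npos == 0], collapse = ", "))
  structure(sig, class = c("signature_matrix", class(sig)))
}

#' AT1- and AT2-restricted marker sets
#'
#' Markers positive for one alveolar flat/progenitor identity but not the
#' other; co-positivity of both sets is the transitional-AT call.
#'
#' @param sig A `signature_matrix`.
#' @return List with elements `at1` and `at2`.
#' @export
alveolar_marker_sets <- function(sig) {
  list(at1 = colnames(sig)[sig["AT1", ] == "POS" & sig["AT2", ] == "NEG"],
       at2 = colnames(sig)[sig["AT2", ] == "POS" & sig["AT1", ] == "NEG"])
}

#' Marker lineage compartments
#'
#' The packaged mutually-exclusive lineage grouping of the classification
#' markers (epithelial / hematopoietic / mesenchymal / vascular), used to
#' flag hybrid-signature artifact clusters.
#'
#' @param path Optional alternative YAML file.
#' @return Named character vector mapping marker -> compartment; markers not
#'   listed in any compartment are absent.
#' @export
lineage_groups <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lineage_groups.yaml", package = "plexlung")
  doc <- yaml::read_yaml(path)
  out <- character(0)
  for (g in names(doc)) out[as.character(unlist(doc[[g]]))] <- g
  out
}

#' @export
print.marker_panel <- function(x, ...) {
  cat("marker_panel '", x$name, "': ", nrow(x$markers), " markers over ",
      x$n_rounds, " rounds (", length(classification_markers(x)),
      " used for classification)\n", sep = "")
  print(x$markers[, c("short_name", "round", "channel", "classify")],
        row.names = FALSE)
  invisible(x)
}
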
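#' Single-cell feature table
#'
#' The per-cell table of the pipeline: one row per segmented cell with its
#' nuclear centroid (px and um), ROI area, per-marker mean intensity on the
#' raw 0-255 scale and rescaled to 0-1 (`mean_rescaled = mean_raw / 255`),
#' and a sample identifier. Downstream stages append `cluster`, `cell_type`
#' and `major_type` columns.
#'
#' @param x A `data.frame` with the schema columns.
#' @param markers Character vector of marker names (column prefixes).
#' @return `x` with class `cell_table` and a `markers` attribute.
#' @export
as_cell_table <- function(x, markers) {
  need <- c("cell_id", "x_px", "y_px", "x_um", "y_um", "area_px",
            paste0(markers, "_raw"), paste0(markers, "_scaled"), "sample_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cell_table: missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$cell_id)) stop("cell_table: cell_id must be unique")
  class(x) <- unique(c("cell_table", class(x)))
  attr(x, "markers") <- markers
  x
}

#' Markers recorded in a cell table
#'
#' @param table A `cell_table`.
#' @return Character vector of marker names.
#' @export
table_markers <- function(table) attr(table, "markers")

#' Extract per-cell marker features from a registered stack
#'
#' One row per ROI label: the mean intensity of every panel marker over the
#' (expanded) ROI plus the nuclear centroid. Marker columns follow panel
#' order; rescaled values are `raw / 255` exactly.
#'
#' @param stack A registered, AF-subtracted [image_stack()].
#' @param cells A [label_mask()] from [expand_to_cells()] (its
#'   `nuclear_table` attribute supplies centroids; a plain nuclear mask
#'   works too).
#' @param panel A `marker_panel`.
#' @param sample_id Sample identifier stored in the table.
#' @return A [as_cell_table()] object.
#' @export
extract_features <- function(stack, cells, panel, sample_id = "S1") {
  mk <- panel$markers[panel$markers$channel != "DAPI", ]
  have <- stack$key
  missing <- mk$short_name[!vapply(seq_len(nrow(mk)), function(i)
    any(!is.na(have$marker) & have$marker == mk$short_name[i] &
          have$round == mk$round[i]), logical(1))]
  if (length(missing))
    stop("extract_features: no image for marker(s): ",
         paste(missing, collapse = ", "))
  m <- cells$mask
  if (!all(dim(m) == dim(stack$images[[1]])))
    stop("extract_features: mask shape does not match images")
  nuc <- attr(cells, "nuclear_table")
  if (is.null(nuc)) nuc <- cells$table
  tab <- cells$table
  n <- nrow(tab)
  mpp <- stack$microns_per_pixel

  idx <- which(m > 0)
  labs <- m[idx]
  out <- data.frame(cell_id = tab$label,
                    x_px = nuc$x, y_px = nuc$y,
                    x_um = nuc$x * mpp, y_um = nuc$y * mpp,
                    area_px = tab$area)
  for (i in seq_len(nrow(mk))) {
    img <- stack_image(stack, round = mk$round[i], marker = mk$short_name[i])
    means <- if (n > 0) {
      s <- rowsum(as.numeric(img[idx]), labs)
      as.numeric(s[, 1]) / tab$area
    } else numeric(0)
    out[[paste0(mk$short_name[i], "_raw")]] <- means
  }
  for (nm in mk$short_name)
    out[[paste0(nm, "_scaled")]] <- out[[paste0(nm, "_raw")]] / 255
  out$sample_id <- rep(sample_id, nrow(out))
  as_cell_table(out, mk$short_name)
}

#' Write a cell table to CSV
#'
#' Comma-separated, `.` decimal, UTF-8, header row; numeric values keep full
#' precision (round-trips losslessly to at least 6 significant digits).
#'
#' @param table A `cell_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cell table written by [write_cell_table()]
#'
#' @param path CSV path.
#' @param markers Expected marker set; by default inferred from the
#'   `_raw`/`_scaled` column pairs.
#' @return A `cell_table`.
#' @export
read_cell_table <- function(path, markers = NULL) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 fileEncoding = "UTF-8"),
                 error = function(e) stop("read_cell_table: parse error: ",
                                          conditionMessage(e)))
  if (is.null(markers)) {
    raw <- sub("_raw$", "", grep("_raw$", names(df), value = TRUE))
    sca <- sub("_scaled$", "", grep("_scaled$", names(df), value = TRUE))
    markers <- intersect(raw, sca)
  }
  as_cell_table(df, markers)
}

#' Matrix of classification features
#'
#' The cell x marker matrix the clustering runs on. The default is the
#' linear 0-1 rescale; `"zscore"` standardizes each marker across cells and
#' `"arcsinh:<c>"` applies `asinh(raw / c)` (e.g. `"arcsinh:5"`) for users
#' preferring mass-cytometry-style transforms.
#'
#' @param table A `cell_table`.
#' @param markers Markers to use (default: all in the table).
#' @param normalize `"linear"`, `"zscore"` or `"arcsinh:<cofactor>"`.
#' @return Numeric matrix with `cell_id` rownames.
#' @export
feature_matrix <- function(table, markers = table_markers(table),
                           normalize = "linear") {
  X <- as.matrix(as.data.frame(table)[, paste0(markers, "_scaled"),
                                      drop = FALSE])
  colnames(X) <- markers
  rownames(X) <- table$cell_id
  if (identical(normalize, "linear")) return(X)
  if (identical(normalize, "zscore")) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    return(scale(X, scale = s))
  }
  if (grepl("^arcsinh:", normalize)) {
    cf <- as.numeric(sub("^arcsinh:", "", normalize))
    if (!is.finite(cf) || cf <= 0) stop("feature_matrix: bad arcsinh cofactor")
    return(asinh(X * 255 / cf))
  }
  stop("feature_matrix: unknown normalize: ", normalize)
}
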
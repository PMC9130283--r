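#' Isodata automatic threshold
#'
#' The iterative intermeans (isodata-family) global threshold on the 8-bit
#' histogram: starting from the image mean, the threshold is repeatedly set
#' to the average of the mean intensity below and the mean above until it
#' stabilizes. This matches the behaviour of the common "default" automatic
#' threshold of interactive image analysis tools.
#'
#' @param img Integer matrix (0..255).
#' @return The threshold value; foreground is `img > threshold`.
#' @export
threshold_isodata <- function(img) {
  h <- tabulate(as.integer(img) + 1L, nbins = 256L)
  v <- 0:255
  t0 <- sum(h * v) / sum(h)
  for (it in 1:100) {
    lo <- v <= t0
    m1 <- if (any(h[lo] > 0)) sum(h[lo] * v[lo]) / sum(h[lo]) else 0
    m2 <- if (any(h[!lo] > 0)) sum(h[!lo] * v[!lo]) / sum(h[!lo]) else 255
    t1 <- (m1 + m2) / 2
    if (abs(t1 - t0) < 0.5) break
    t0 <- t1
  }
  t0
}

#' Label mask
#'
#' An integer image (0 = background, labels 1..N) plus the per-label table
#' of centroids and areas.
#'
#' @param mask Integer matrix of labels.
#' @return A `label_mask` with elements `mask` and `table`
#'   (`label`, `x`, `y`, `area`).
#' @export
label_mask <- function(mask) {
  storage.mode(mask) <- "integer"
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs)) {
    idx <- which(mask > 0)
    l <- mask[idx]
    xs <- ((idx - 1) %% nrow(mask)) + 1
    ys <- ((idx - 1) %/% nrow(mask)) + 1
    area <- tabulate(l, nbins = max(l))[labs]
    cx <- rowsum(xs, l)[, 1] / area
    cy <- rowsum(ys, l)[, 1] / area
    tab <- data.frame(label = labs, x = as.numeric(cx), y = as.numeric(cy),
                      area = as.integer(area))
  } else {
    tab <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = integer(0))
  }
  structure(list(mask = mask, table = tab), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat("label_mask:", nrow(x$table), "labels,",
      sum(x$table$area), "foreground px\n")
  invisible(x)
}

# relabel 1..N in raster order of first occurrence
.relabel <- function(mask) {
  labs <- unique(mask[mask > 0])
  if (!length(labs)) return(mask)
  lut <- integer(max(labs))
  lut[sort(labs)] <- seq_along(labs)
  pos <- mask > 0
  mask[pos] <- lut[mask[pos]]
  mask
}

#' Segment nuclei in a DAPI image
#'
#' Global automatic threshold (isodata by default), distance-transform
#' watershed to split touching nuclei, connected components, and an area
#' filter. A blank image yields an empty mask.
#'
#' @param dapi Integer matrix (0..255).
#' @param min_area_px Minimum object area (px^2).
#' @param max_area_px Maximum area; `NULL` uses 10x the median object area.
#' @param method `"isodata"`, `"otsu"` or `"fixed:<v>"`.
#' @param h Watershed h-minima suppression (tolerance).
#' @return A [label_mask()].
#' @export
segment_nuclei <- function(dapi, min_area_px = 20, max_area_px = NULL,
                           method = "isodata", h = 1) {
  thr <- if (identical(method, "isodata")) {
    threshold_isodata(dapi)
  } else if (identical(method, "otsu")) {
    EBImage::otsu(.as_ebimage(dapi), range = c(0, 1)) * 255
  } else if (grepl("^fixed:", method)) {
    as.numeric(sub("^fixed:", "", method))
  } else stop("segment_nuclei: unknown threshold method: ", method)
  bw <- dapi > thr
  if (!any(bw)) return(label_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  dm <- EBImage::distmap(EBImage::Image(bw * 1))
  ws <- EBImage::watershed(dm, tolerance = h, ext = 1)
  m <- EBImage::imageData(ws)
  storage.mode(m) <- "integer"
  areas <- tabulate(m[m > 0])
  if (is.null(max_area_px)) {
    med <- stats::median(areas[areas > 0])
    max_area_px <- if (is.na(med)) Inf else 10 * med
  }
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  m[!(m %in% keep)] <- 0L
  label_mask(.relabel(m))
}

#' Expand nuclei into pseudo-cell ROIs
#'
#' Dilates every label by `ring_px` without crossing into a neighboring
#' label: the ring pixels are partitioned by geodesic distance to the
#' nearest nucleus (Voronoi-style propagation), so adjacent cells share a
#' boundary but never overlap, and the label count is unchanged. Centroids
#' in the returned table remain the nuclear centroids.
#'
#' @param mask A [label_mask()] of nuclei.
#' @param ring_px Ring width in pixels (>= 0).
#' @return A [label_mask()] of expanded cells, with a `nuclear_table`
#'   attribute preserving the nuclear centroids.
#' @export
expand_to_cells <- function(mask, ring_px = 2) {
  if (ring_px < 0) stop("expand_to_cells: ring_px must be >= 0")
  if (ring_px == 0 || nrow(mask$table) == 0) {
    out <- mask
    attr(out, "nuclear_table") <- mask$table
    return(out)
  }
  seeds <- mask$mask
  brush <- EBImage::makeBrush(2 * ring_px + 1, shape = "disc")
  region <- EBImage::dilate(EBImage::Image(seeds > 0), brush)
  pr <- EBImage::propagate(EBImage::Image(matrix(0, nrow(seeds), ncol(seeds))),
                           EBImage::Image(seeds),
                           mask = region > 0, lambda = 1e8)
  m <- EBImage::imageData(pr)
  storage.mode(m) <- "integer"
  out <- label_mask(m)
  # keep nuclear centroids alongside the expanded areas
  nuc <- mask$table
  out$table <- merge(out$table[, c("label", "area")],
                     nuc[, c("label", "x", "y")], by = "label")
  out$table <- out$table[order(out$table$label), c("label", "x", "y", "area")]
  attr(out, "nuclear_table") <- nuc
  out
}
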
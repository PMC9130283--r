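#' Normal mouse lung composition preset
#'
#' The published normal-lung cell-type fractions used as generative
#' parameters: AT1 22%, AT2 14%, transitional AT 32%, bronchial/goblet 7%,
#' endothelium 3%, myofibroblast/SMC 2%, other stromal 0.7%, T 7%, B 3%,
#' macrophage/DC 4%, neutrophil 1%. The printed values sum to 95.7 and are
#' renormalized here to a proper composition.
#'
#' @return Named numeric vector over [cell_type_labels()], summing to 1.
#' @export
normal_lung_composition <- function() {
  w <- c(AT1 = 22, AT2 = 14, transitional_AT = 32, bronchial_goblet = 7,
         vasculature = 3, myofibroblast_smc = 2, stromal = 0.7,
         T_cell = 7, B_cell = 3, macrophage = 4, neutrophil = 1)
  w / sum(w)
}

#' Synthetic tissue generation parameters
#'
#' Bundles everything the generator needs: field geometry, cell density and
#' composition, the nucleus size model, the per-(type, marker) intensity
#' model, autofluorescence, inter-round misalignment, crowding and spillover.
#' Intensities are on the 0-255 (8-bit) scale.
#'
#' Defaults describe a 2 mm TMA core at 0.92 um/px: ~6,029 cells (the
#' average per-core yield the density is anchored to), marker-positive mean
#' 140 +/- 45, transitional AT expressing both alveolar marker sets at 0.7x,
#' autofluorescence in FITC/TRITC only, <=10 px / <=2 deg per-round rigid
#' misalignment, 5% deliberately touching nucleus pairs, and a small
#' neighbor-spillover fraction emulating pseudo-cell signal leakage.
#'
#' @param field_um Field size `c(x, y)` in microns.
#' @param microns_per_pixel Pixel scale.
#' @param n_cells Number of cells to place.
#' @param composition Named fractions over [cell_type_labels()]; must sum to 1.
#' @param nucleus_radius_um `c(mean, sd)` nucleus radius in microns.
#' @param pos_intensity `c(mean, sd)` of the truncated-normal positive-marker
#'   intensity on 0-255.
#' @param transitional_factor Intensity scaling of the transitional-AT
#'   positive markers relative to full positives.
#' @param dapi_intensity `c(mean, sd)` nuclear DAPI intensity.
#' @param pgp_baseline Constitutive P-gP mean intensity (all types).
#' @param pgp_sd_frac P-gP per-cell SD as a fraction of its mean.
#' @param background_level Dark background level of marker images.
#' @param pixel_noise_sd Per-pixel Gaussian camera noise SD.
#' @param autofluorescence List with `FITC`/`TRITC` entries `c(constant,
#'   texture)`; far-red carries no autofluorescence.
#' @param misalignment `c(max_translation_px, max_rotation_deg)` per round.
#' @param touching_fraction Fraction of cells planted touching another cell.
#' @param spillover_beta `c(shape1, shape2)` of the Beta-distributed fraction
#'   of a cell's observed signal contributed by its nearest neighbor (table
#'   path; in the image path leakage arises physically from ROI overlap).
#' @param sample_jitter Dirichlet precision for per-mouse composition jitter
#'   (used only by cohort simulation).
#' @param placement `"core"` (cells inside the inscribed circle of diameter
#'   `core_diameter_mm`) or `"field"` (whole field minus margin).
#' @param core_diameter_mm Core diameter for `placement = "core"`.
#' @param seed Default RNG seed used when an operation is not given one.
#' @return A `tissue_params` object.
#' @export
tissue_params <- function(field_um = c(2200, 2200),
                          microns_per_pixel = 0.92,
                          n_cells = 6029,
                          composition = normal_lung_composition(),
                          nucleus_radius_um = c(3.5, 0.5),
                          pos_intensity = c(140, 45),
                          transitional_factor = 0.7,
                          dapi_intensity = c(190, 25),
                          pgp_baseline = 60,
                          pgp_sd_frac = 0.3,
                          background_level = 8,
                          pixel_noise_sd = 3,
                          autofluorescence = list(FITC = c(25, 15),
                                                  TRITC = c(15, 10)),
                          misalignment = c(10, 2),
                          touching_fraction = 0.05,
                          spillover_beta = c(1.2, 8.8),
                          sample_jitter = 60,
                          placement = c("core", "field"),
                          core_diameter_mm = 2,
                          seed = 1L) {
  placement <- match.arg(placement)
  composition <- composition[composition > 0]
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9)
    stop("tissue_params: composition fractions must be >= 0 and sum to 1")
  if (!all(names(composition) %in% cell_type_labels()))
    stop("tissue_params: unknown cell type in composition")
  if (pos_intensity[1] < 0 || pos_intensity[1] > 255)
    stop("tissue_params: intensity means must lie in [0, 255]")
  structure(list(field_um = field_um, microns_per_pixel = microns_per_pixel,
                 n_cells = as.integer(n_cells), composition = composition,
                 nucleus_radius_um = nucleus_radius_um,
                 pos_intensity = pos_intensity,
                 transitional_factor = transitional_factor,
                 dapi_intensity = dapi_intensity,
                 pgp_baseline = pgp_baseline, pgp_sd_frac = pgp_sd_frac,
                 background_level = background_level,
                 pixel_noise_sd = pixel_noise_sd,
                 autofluorescence = autofluorescence,
                 misalignment = misalignment,
                 touching_fraction = touching_fraction,
                 spillover_beta = spillover_beta,
                 sample_jitter = sample_jitter,
                 placement = placement,
                 core_diameter_mm = core_diameter_mm,
                 seed = as.integer(seed)),
            class = "tissue_params")
}

#' Packaged tissue presets
#'
#' `"core2mm"`: one 2 mm TMA core (6,029 cells at 0.92 um/px), the study
#' condition for composition recovery. `"whole_section"`: a 4.6 x 4.6 mm
#' section at the same density (~39k cells, the whole-slide scale used for
#' core-size validation). `"mini"`: a small fast field for examples/tests.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [tissue_params()].
#' @return A `tissue_params` object.
#' @export
normal_lung_params <- function(preset = c("core2mm", "whole_section", "mini"),
                               ...) {
  preset <- match.arg(preset)
  density_per_mm2 <- 6029 / (pi * 1^2)     # cells per mm^2 at the 2 mm core anchor
  base <- switch(preset,
    core2mm = list(field_um = c(2200, 2200), n_cells = 6029L,
                   placement = "core", core_diameter_mm = 2),
    whole_section = {
      side <- 5200            # hosts the 4 x 2 mm + 4 x 1 mm virtual-core design
      n <- as.integer(round((side - 60)^2 / 1e6 * density_per_mm2))
      list(field_um = c(side, side), n_cells = n, placement = "field")
    },
    mini = list(field_um = c(600, 600), n_cells = 220L, placement = "field"))
  args <- utils::modifyList(base, list(...))
  do.call(tissue_params, args)
}

#' Bleomycin treatment presets
#'
#' Packaged composition and P-gP effects per timepoint, encoding the
#' published time course: a transient AT1 reduction and progressive AT2 +
#' transitional-AT decline through day 21, progressive stromal increase with
#' a late myofibroblast/SMC rise, near-control recovery at day 28, and P-gP
#' induction in every type except bronchial/goblet cells, with delayed onset
#' in the stromal compartment.
#'
#' @param timepoint One of `"saline"`, `"d7"`, `"d14"`, `"d21"`, `"d28"`.
#' @return A `treatment_effect` with elements `timepoint`,
#'   `composition_override` (sums to 1) and `pgp_multiplier`.
#' @export
treatment_preset <- function(timepoint = c("saline", "d7", "d14", "d21", "d28")) {
  timepoint <- match.arg(timepoint)
  lab <- cell_type_labels()
  comp <- switch(timepoint,
    saline = c(22,   14, 32, 7,   3,   2,   0.7, 7,   3,   4,   1),
    d7     = c(17,   12, 28, 7.5, 3.2, 2.3, 2.5, 8,   3.5, 5.5, 2),
    d14    = c(15,    9, 24, 7.5, 3.2, 3.5, 6,   9,   3,   5,   1.8),
    d21    = c(17,    7, 20, 7.5, 3.2, 6,   9,   9,   2,   3.5, 0.8),
    d28    = c(21,   13, 31, 7.4, 3.1, 2.6, 1.5, 7.5, 2.8, 4,   0.9))
  names(comp) <- lab
  mult <- switch(timepoint,
    saline = rep(1, 11),
    d7     = c(1.5, 1.5, 1.5, 1, 1.4, 1.3, 1.0, 1.4, 1.4, 1.4, 1.4),
    d14    = c(1.9, 1.9, 1.9, 1, 1.8, 1.7, 1.6, 1.7, 1.7, 1.7, 1.7),
    d21    = c(2.1, 2.1, 2.1, 1, 2.0, 1.9, 1.9, 1.9, 1.9, 1.9, 1.9),
    d28    = c(1.6, 1.6, 1.6, 1, 1.5, 1.5, 1.4, 1.5, 1.5, 1.5, 1.5))
  names(mult) <- lab
  structure(list(timepoint = timepoint,
                 composition_override = comp / sum(comp),
                 pgp_multiplier = mult),
            class = "treatment_effect")
}

# Resolve the effect argument: NULL means "untreated, use the params
# composition"; an explicit treatment_effect overrides the composition.
.effect_or_default <- function(effect, params) {
  if (is.null(effect)) {
    mult <- rep(1, length(cell_type_labels()))
    names(mult) <- cell_type_labels()
    return(structure(list(timepoint = "saline",
                          composition_override = params$composition,
                          pgp_multiplier = mult),
                     class = "treatment_effect"))
  }
  stopifnot(inherits(effect, "treatment_effect"))
  effect
}

# Truncated-normal draw by resampling (exact truncation on [lo, hi]).
rtnorm <- function(n, mean, sd, lo = 0, hi = 255) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  it <- 0L
  while (length(bad) && it < 100L) {
    x[bad] <- rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lo | x[bad] > hi]
    it <- it + 1L
  }
  x[x < lo] <- lo; x[x > hi] <- hi
  x
}

# --- cell placement -------------------------------------------------------

# Quadratic Bezier points
.bezier <- function(p0, p1, p2, t) {
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

# Place n cells of the given types in the field: vasculature/myofibroblast
# along random Bezier "vessel" tubes, bronchial cells on circular "airway"
# rims, stromal partly perivascular, everything else uniform; a hard-core
# minimum spacing is enforced except for a configured fraction of
# deliberately touching pairs.
.place_cells <- function(params, types) {
  n <- length(types)
  mpp <- params$microns_per_pixel
  fx <- params$field_um[1] / mpp; fy <- params$field_um[2] / mpp
  r_mean <- params$nucleus_radius_um[1] / mpp
  r_sd <- params$nucleus_radius_um[2] / mpp
  dmin <- 1.8 * r_mean
  margin <- 30 / mpp

  in_region <- if (params$placement == "core") {
    cx <- fx / 2; cy <- fy / 2
    rad <- params$core_diameter_mm * 1000 / (2 * mpp)
    if (2 * rad > min(fx, fy))
      stop("placement: core diameter exceeds field")
    function(x, y) (x - cx)^2 + (y - cy)^2 <= rad^2
  } else {
    function(x, y) x > margin & x < fx - margin & y > margin & y < fy - margin
  }
  area_px <- if (params$placement == "core")
    pi * (params$core_diameter_mm * 1000 / (2 * mpp))^2
  else (fx - 2 * margin) * (fy - 2 * margin)
  if (n * dmin^2 > 0.7 * area_px) stop("overcrowded field")
  rand_pt <- function() {
    repeat {
      x <- runif(1, 1, fx); y <- runif(1, 1, fy)
      if (in_region(x, y)) return(c(x, y))
    }
  }

  area_mm2 <- prod(params$field_um) / 1e6
  nv <- max(1L, round(area_mm2 * 1.2))
  vessels <- lapply(seq_len(nv), function(i) {
    p <- replicate(3, rand_pt())
    .bezier(p[, 1], p[, 2], p[, 3], seq(0, 1, length.out = 60))
  })
  nb <- max(1L, round(area_mm2 * 0.5))
  bronchi <- lapply(seq_len(nb), function(i) {
    c(rand_pt(), runif(1, 40, 90) / mpp)   # cx, cy, radius
  })

  propose <- function(type) {
    if (type %in% c("vasculature", "myofibroblast_smc")) {
      v <- vessels[[sample.int(nv, 1)]]
      p <- v[sample.int(nrow(v), 1), ]
      sdj <- if (type == "vasculature") 8 else 14
      p + rnorm(2, 0, sdj / mpp)
    } else if (type == "bronchial_goblet") {
      b <- bronchi[[sample.int(nb, 1)]]
      a <- runif(1, 0, 2 * pi)
      rr <- b[3] + rnorm(1, 0, 5 / mpp)
      c(b[1] + rr * cos(a), b[2] + rr * sin(a))
    } else if (type == "stromal" && runif(1) < 0.5) {
      v <- vessels[[sample.int(nv, 1)]]
      v[sample.int(nrow(v), 1), ] + rnorm(2, 0, 20 / mpp)
    } else {
      c(runif(1, 1, fx), runif(1, 1, fy))
    }
  }

  # grid-backed hard-core rejection
  gsz <- max(dmin, 1)
  gkey <- function(x, y) paste(floor(x / gsz), floor(y / gsz))
  grid <- new.env(hash = TRUE, parent = emptyenv())
  near_ok <- function(x, y, d) {
    gx <- floor(x / gsz); gy <- floor(y / gsz)
    for (ix in (gx - 1):(gx + 1)) for (iy in (gy - 1):(gy + 1)) {
      pts <- grid[[paste(ix, iy)]]
      if (!is.null(pts) &&
          any((pts[, 1] - x)^2 + (pts[, 2] - y)^2 < d^2)) return(FALSE)
    }
    TRUE
  }
  push <- function(x, y) {
    k <- gkey(x, y)
    grid[[k]] <- rbind(grid[[k]], c(x, y))
  }

  xs <- numeric(n); ys <- numeric(n)
  n_touch <- round(params$touching_fraction * n)
  touch_idx <- if (n_touch > 0 && n > 1) seq_len(n_touch) + (n - n_touch) else integer(0)
  radius <- pmax(rtnorm(n, r_mean, r_sd, lo = max(1.5, r_mean - 3 * r_sd),
                        hi = r_mean + 3 * r_sd), 1.5)
  for (i in seq_len(n)) {
    if (i %in% touch_idx) {
      j <- sample.int(i - 1L, 1)
      a <- runif(1, 0, 2 * pi)
      d <- 0.75 * (radius[i] + radius[j])
      xs[i] <- xs[j] + d * cos(a); ys[i] <- ys[j] + d * sin(a)
      if (!in_region(xs[i], ys[i])) { xs[i] <- xs[j]; ys[i] <- ys[j] + d }
      push(xs[i], ys[i])
      next
    }
    placed <- FALSE
    for (try in 1:60) {
      p <- propose(types[i])
      if (!in_region(p[1], p[2])) next
      if (near_ok(p[1], p[2], dmin)) {
        xs[i] <- p[1]; ys[i] <- p[2]; push(p[1], p[2]); placed <- TRUE
        break
      }
    }
    if (!placed) {             # dense field: accept a uniform point anyway
      p <- rand_pt()
      xs[i] <- p[1]; ys[i] <- p[2]; push(p[1], p[2])
    }
  }
  aspect <- ifelse(types == "stromal", 3, 1)
  data.frame(cell_id = seq_len(n), true_type = types,
             x_px = xs, y_px = ys, radius_px = radius,
             aspect = aspect, phi = runif(n, 0, pi),
             touching = seq_len(n) %in% touch_idx)
}

# Per-cell true mean intensity for every marker (0 where not expressed).
.true_intensities <- function(cells, panel, effect, params) {
  sig <- build_signature_matrix(panel)
  markers <- panel$markers$short_name[panel$markers$channel != "DAPI"]
  M <- matrix(0, nrow(cells), length(markers),
              dimnames = list(NULL, markers))
  if (nrow(cells) == 0) return(M)
  for (m in markers) {
    if (m == "P-gP") {
      mu <- params$pgp_baseline * effect$pgp_multiplier[cells$true_type]
      M[, m] <- rtnorm(nrow(cells), mu, params$pgp_sd_frac * mu)
      next
    }
    if (!m %in% colnames(sig)) next               # measured-only, no expression model
    pos <- sig[cells$true_type, m] == "POS"
    if (!any(pos)) next
    f <- ifelse(cells$true_type[pos] == "transitional_AT",
                params$transitional_factor, 1)
    M[pos, m] <- rtnorm(sum(pos), params$pos_intensity[1] * f,
                        params$pos_intensity[2])
  }
  M
}

# Anti-aliased ellipse footprint (a >= b, orientation phi): linear pixel
# indices into an nx x ny canvas plus per-pixel coverage in [0, 1]. The
# caller paints with `canvas[p$idx] <- pmax(canvas[p$idx], v * p$cov)`,
# which stays in place (no canvas copy).
.ellipse_patch <- function(nx, ny, cx, cy, a, b, phi) {
  ext <- ceiling(a + 1)
  x0 <- max(1, floor(cx - ext)); x1 <- min(nx, ceiling(cx + ext))
  y0 <- max(1, floor(cy - ext)); y1 <- min(ny, ceiling(cy + ext))
  if (x0 > x1 || y0 > y1)
    return(list(idx = integer(0), cov = numeric(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- rep(xs - cx, times = length(ys))
  dy <- rep(ys - cy, each = length(xs))
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  w <- (-dx * sin(phi) + dy * cos(phi)) / b
  cov <- pmin(pmax((1 - sqrt(u^2 + w^2)) * b + 0.5, 0), 1)
  keep <- cov > 0
  idx <- (rep(ys - 1L, each = length(xs)) * nx + rep(xs, times = length(ys)))[keep]
  list(idx = idx, cov = cov[keep])
}

.quantize <- function(x) {
  x <- floor(x + 0.5)
  x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Generate one synthetic multi-round multiplexed section
#'
#' Renders the full MILAN acquisition for the given tissue parameters and
#' treatment effect: one DAPI image per staining round (identical tissue,
#' per-round rigid misalignment applied), one image per marker in its
#' designed round/channel, and a blank autofluorescence round (round 0).
#' Nuclei are anti-aliased disks (elongated ellipses for stromal cells);
#' positive markers are painted over the nucleus plus a perinuclear ring;
#' autofluorescence (constant + low-frequency texture) contaminates FITC and
#' TRITC channels only; per-pixel Gaussian noise is added last. The returned
#' ground truth records every cell's type, centroid, nucleus radius and true
#' per-marker mean intensity, and the stack carries the per-round true
#' transforms as an attribute (`true_transforms`).
#'
#' @param params A [tissue_params()] object.
#' @param effect A [treatment_preset()] effect, or `NULL` for an untreated
#'   section using `params$composition` and unit P-gP multipliers.
#' @param panel Marker panel (default: packaged panel).
#' @param seed RNG seed; defaults to `params$seed`.
#' @param keep_aligned If `TRUE`, also return the misalignment-free stack
#'   (`aligned` element) for registration oracles.
#' @return List with elements `stack` (an [image_stack()]), `truth`
#'   (ground-truth `data.frame` with `true_<marker>` columns) and optionally
#'   `aligned`.
#' @export
generate_section <- function(params, effect = NULL,
                             panel = default_panel(), seed = params$seed,
                             keep_aligned = FALSE) {
  set.seed(seed)
  effect <- .effect_or_default(effect, params)
  comp <- effect$composition_override
  comp <- comp[comp > 0]
  comp <- comp / sum(comp)
  n <- params$n_cells
  types <- if (n > 0)
    sample(names(comp), n, replace = TRUE, prob = comp) else character(0)
  cells <- .place_cells(params, types)
  M <- .true_intensities(cells, panel, effect, params)

  mpp <- params$microns_per_pixel
  nx <- round(params$field_um[1] / mpp); ny <- round(params$field_um[2] / mpp)

  # precompute per-cell nucleus and (dilated) signal footprints
  a_nuc <- cells$radius_px * sqrt(cells$aspect)
  b_nuc <- cells$radius_px / sqrt(cells$aspect)
  patch_nuc <- vector("list", n); patch_sig <- vector("list", n)
  for (i in seq_len(n)) {
    patch_nuc[[i]] <- .ellipse_patch(nx, ny, cells$x_px[i], cells$y_px[i],
                                     a_nuc[i], b_nuc[i], cells$phi[i])
    patch_sig[[i]] <- .ellipse_patch(nx, ny, cells$x_px[i], cells$y_px[i],
                                     a_nuc[i] + 3, b_nuc[i] + 3,
                                     cells$phi[i])
  }

  # true (aligned) DAPI
  dapi_true <- matrix(0, nx, ny)
  if (n > 0) {
    dv <- rtnorm(n, params$dapi_intensity[1], params$dapi_intensity[2],
                 lo = 80)
    for (i in seq_len(n)) {
      p <- patch_nuc[[i]]
      dapi_true[p$idx] <- pmax(dapi_true[p$idx], dv[i] * p$cov)
    }
  }

  af <- list(FITC = matrix(0, nx, ny), TRITC = matrix(0, nx, ny))
  for (ch in names(af)) {
    lv <- params$autofluorescence[[ch]]
    if (!is.null(lv) && (lv[1] > 0 || lv[2] > 0))
      af[[ch]] <- lv[1] + lv[2] * (.noise_field(nx, ny) + 1) / 2
  }

  # per-round misalignment (round 1 is the reference frame)
  rounds <- 0:panel$n_rounds
  tr <- data.frame(round = rounds, rotation = 0, dx = 0, dy = 0)
  mis <- params$misalignment
  for (r in rounds[rounds != 1]) {
    i <- which(tr$round == r)
    tr$rotation[i] <- runif(1, -mis[2], mis[2])
    tr$dx[i] <- runif(1, -mis[1], mis[1])
    tr$dy[i] <- runif(1, -mis[1], mis[1])
  }

  mk <- panel$markers[panel$markers$channel != "DAPI", ]
  nm_dapi <- sprintf("R%02d_DAPI", rounds)
  nm_mark <- sprintf("R%02d_%s_%s", mk$round, mk$channel, mk$short_name)
  nm_af <- c("R00_FITC_AF", "R00_TRITC_AF")
  key <- rbind(
    data.frame(name = nm_dapi, round = rounds, channel = "DAPI", marker = NA),
    data.frame(name = nm_af, round = 0L, channel = c("FITC", "TRITC"),
               marker = NA),
    data.frame(name = nm_mark, round = mk$round, channel = mk$channel,
               marker = mk$short_name))

  render_true <- function(ch, mr) {
    if (ch == "DAPI") return(dapi_true)
    base <- matrix(params$background_level + 0, nx, ny)
    if (!is.na(mr)) {
      for (i in which(M[, mr] > 0)) {
        p <- patch_sig[[i]]
        base[p$idx] <- pmax(base[p$idx], M[i, mr] * p$cov)
      }
    }
    if (ch %in% names(af)) base <- base + af[[ch]]
    base
  }

  imgs <- vector("list", nrow(key)); names(imgs) <- key$name
  if (keep_aligned) al <- imgs
  for (j in seq_len(nrow(key))) {
    ti <- .quantize(render_true(key$channel[j], key$marker[j]))
    i <- which(tr$round == key$round[j])
    w <- warp_rigid(ti, tr$rotation[i], tr$dx[i], tr$dy[i])
    imgs[[j]] <- .quantize(w + rnorm(length(w), 0, params$pixel_noise_sd))
    if (keep_aligned)
      al[[j]] <- .quantize(ti + rnorm(length(ti), 0, params$pixel_noise_sd))
  }
  stack <- image_stack(imgs, key, mpp)
  attr(stack, "true_transforms") <- tr

  truth <- cells
  colnames(M) <- paste0("true_", colnames(M))
  truth <- cbind(truth, as.data.frame(M))
  out <- list(stack = stack, truth = truth)
  if (keep_aligned) out$aligned <- image_stack(al, key, mpp)
  out
}

#' Simulate a single-cell feature table directly (imaging-free path)
#'
#' Draws the same tissue (placement, composition, per-cell true intensities)
#' as [generate_section()] but skips pixel rendering: observed per-marker
#' means are the true means mixed with a Beta-distributed fraction of the
#' nearest neighbor's profile (pseudo-cell spillover; larger for touching
#' pairs), plus background and measurement noise. This is the path used for
#' whole-section-scale experiments (TMA validation, treatment cohorts).
#'
#' @inheritParams generate_section
#' @param sample_id Sample identifier stored in the table.
#' @param jitter If `TRUE`, draw this sample's composition from a Dirichlet
#'   around the preset (precision `params$sample_jitter`), emulating
#'   across-mouse variation.
#' @return List with `table` (a [cell_table()]) and `truth`.
#' @export
simulate_cell_table <- function(params, effect = NULL,
                                panel = default_panel(), seed = params$seed,
                                sample_id = "S1", jitter = FALSE) {
  set.seed(seed)
  effect <- .effect_or_default(effect, params)
  comp <- effect$composition_override
  comp <- comp[comp > 0]
  comp <- comp / sum(comp)
  if (jitter) {
    g <- stats::rgamma(length(comp), shape = params$sample_jitter * comp)
    comp <- stats::setNames(g / sum(g), names(comp))
  }
  n <- params$n_cells
  types <- if (n > 0)
    sample(names(comp), n, replace = TRUE, prob = comp) else character(0)
  cells <- .place_cells(params, types)
  M <- .true_intensities(cells, panel, effect, params)
  markers <- colnames(M)
  mpp <- params$microns_per_pixel

  if (n > 1) {
    nb <- RANN::nn2(cells[, c("x_px", "y_px")], k = 2)$nn.idx[, 2]
    lam <- rbeta(n, params$spillover_beta[1], params$spillover_beta[2])
    lam[cells$touching] <- rbeta(sum(cells$touching), 4, 6)
    obs <- (1 - lam) * M + lam * M[nb, , drop = FALSE]
  } else {
    obs <- M
  }
  obs <- obs + rnorm(length(obs), params$background_level, 3)
  obs <- pmin(pmax(obs, 0), 255)

  area <- round(pi * (cells$radius_px + 2)^2)
  tab <- data.frame(cell_id = cells$cell_id,
                    x_px = cells$x_px, y_px = cells$y_px,
                    x_um = cells$x_px * mpp, y_um = cells$y_px * mpp,
                    area_px = area)
  for (m in markers) tab[[paste0(m, "_raw")]] <- obs[, m]
  for (m in markers) tab[[paste0(m, "_scaled")]] <- obs[, m] / 255
  tab$sample_id <- sample_id
  colnames(M) <- paste0("true_", markers)
  list(table = as_cell_table(tab, markers),
       truth = cbind(cells, as.data.frame(M)))
}

#' Simulate a treated-mouse cohort of cell tables
#'
#' One [simulate_cell_table()] draw per mouse per timepoint with per-mouse
#' Dirichlet composition jitter, the data model behind the published
#' time-course figure.
#'
#' @param params A [tissue_params()].
#' @param timepoints Timepoints to simulate.
#' @param mice_per_group Mice per timepoint.
#' @param seed Master seed; each mouse gets a derived sub-seed.
#' @param panel Marker panel.
#' @return `data.frame`-bound cell tables with `sample_id` of the form
#'   `<timepoint>_m<i>`, plus a `sample_info` attribute.
#' @export
simulate_cohort <- function(params, timepoints = c("saline", "d7", "d14",
                                                   "d21", "d28"),
                            mice_per_group = 3, seed = params$seed,
                            panel = default_panel()) {
  out <- list(); info <- list()
  k <- 0L
  for (tp in timepoints) {
    eff <- treatment_preset(tp)
    for (i in seq_len(mice_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s_m%d", tp, i)
      sim <- simulate_cell_table(params, eff, panel,
                                 seed = derive_seed(seed, k),
                                 sample_id = sid, jitter = TRUE)
      sim$table$cell_id <- sprintf("%s_%d", sid, sim$table$cell_id)
      out[[sid]] <- sim$table
      info[[sid]] <- data.frame(sample_id = sid, timepoint = tp, mouse = i)
    }
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  tab <- as_cell_table(tab, attr(out[[1]], "markers"))
  attr(tab, "sample_info") <- do.call(rbind, info)
  tab
}

#' Plan non-overlapping virtual TMA cores
#'
#' Packs circles of the requested diameters into the field on a jittered
#' grid, in pixel coordinates.
#'
#' @param params A [tissue_params()].
#' @param diameters_mm Vector of core diameters (one circle each).
#' @return `data.frame` with `x_px`, `y_px`, `radius_px`, `diameter_mm`.
#' @export
plant_core_layout <- function(params, diameters_mm) {
  mpp <- params$microns_per_pixel
  fx <- params$field_um[1] / mpp; fy <- params$field_um[2] / mpp
  radii <- diameters_mm * 1000 / (2 * mpp)
  if (any(2 * radii > min(fx, fy))) stop("core layout: diameter exceeds field")
  # deterministic raster-grid greedy packing (largest first) with seed-jitter
  ord <- order(radii, decreasing = TRUE)
  res <- data.frame(x_px = rep(NA_real_, length(radii)), y_px = NA_real_,
                    radius_px = radii, diameter_mm = diameters_mm)
  placed <- matrix(numeric(0), ncol = 3)
  for (i in ord) {
    r <- radii[i]
    step <- max(r / 3, 10)
    gx <- seq(r + 1, fx - r - 1, by = step)
    gy <- seq(r + 1, fy - r - 1, by = step)
    if (!length(gx) || !length(gy))
      stop("core layout: circles cannot be packed into the field")
    ok <- FALSE
    for (y0 in gy) {
      for (x0 in gx) {
        x <- min(max(x0 + runif(1, -step / 4, step / 4), r + 1), fx - r - 1)
        y <- min(max(y0 + runif(1, -step / 4, step / 4), r + 1), fy - r - 1)
        if (nrow(placed) == 0 ||
            all((placed[, 1] - x)^2 + (placed[, 2] - y)^2 >
                (placed[, 3] + r + 2)^2)) {
          placed <- rbind(placed, c(x, y, r))
          res$x_px[i] <- x; res$y_px[i] <- y
          ok <- TRUE; break
        }
      }
      if (ok) break
    }
    if (!ok) stop("core layout: circles cannot be packed into the field")
  }
  res
}

#' Derive a stage sub-seed from a master seed
#'
#' Deterministic, collision-spread mapping kept below 2^31.
#'
#' @param seed Master seed (integer).
#' @param k Stage index.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
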
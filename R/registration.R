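#' Rigid transform
#'
#' A rotation (degrees, about the image center) plus a translation in pixels.
#' Applying the transform to a moving image means resampling it so that its
#' content is moved by `p -> R(p - c) + c + t`; [estimate_rigid()] returns the
#' correction transform that brings the moving image onto the reference, so
#' an image shifted by `(+5, -3)` yields a transform with translation
#' `(-5, +3)`.
#'
#' @param rotation Rotation in degrees (positive: +x toward +y).
#' @param dx,dy Translation in pixels.
#' @param reference_round Round whose frame this transform maps into.
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = 0, dx = 0, dy = 0,
                            reference_round = 1L) {
  structure(list(rotation = rotation, dx = dx, dy = dy,
                 reference_round = as.integer(reference_round)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.2f, %.2f) px\n",
              x$rotation, x$dx, x$dy))
  invisible(x)
}

#' Invert a rigid transform
#'
#' Composition of a transform with its inverse is the identity (to numerical
#' precision).
#'
#' @param tr A `rigid_transform`.
#' @return The inverse `rigid_transform`.
#' @export
invert_transform <- function(tr) {
  th <- -tr$rotation * pi / 180
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  t_inv <- -c(tr$dx, tr$dy) %*% R
  rigid_transform(-tr$rotation, t_inv[1], t_inv[2], tr$reference_round)
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `a` then `b` (both about the
#' same image center).
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  thb <- b$rotation * pi / 180
  Rb <- rbind(c(cos(thb), sin(thb)), c(-sin(thb), cos(thb)))
  t_new <- c(a$dx, a$dy) %*% Rb + c(b$dx, b$dy)
  rigid_transform(a$rotation + b$rotation, t_new[1], t_new[2],
                  b$reference_round)
}

# Largest 5-smooth integer <= n (fast FFT length).
.good_fft_size <- function(n) {
  best <- 1
  p2 <- 1
  while (p2 <= n) {
    p23 <- p2
    while (p23 <= n) {
      p235 <- p23
      while (p235 <= n) {
        if (p235 > best) best <- p235
        p235 <- p235 * 5
      }
      p23 <- p23 * 3
    }
    p2 <- p2 * 2
  }
  best
}

# Center-crop both images to FFT-friendly dimensions.
.fft_crop <- function(img) {
  d <- dim(img)
  g <- c(.good_fft_size(d[1]), .good_fft_size(d[2]))
  if (all(g == d)) return(img)
  o <- floor((d - g) / 2)
  img[(o[1] + 1):(o[1] + g[1]), (o[2] + 1):(o[2] + g[2])]
}

# Precompute the FFT side of a reference image for repeated correlation.
.pc_prepare <- function(ref) {
  ref <- .fft_crop(ref)
  a <- ref - mean(ref)
  list(fft = stats::fft(a), ss = sum(a^2), dim = dim(ref))
}

# Phase correlation: translation (dx, dy) such that moving content shifted by
# (dx, dy) matches ref, with parabolic sub-pixel refinement. Returns the
# shift to APPLY to mov (the correction), plus the normalized peak height.
.phase_correlate <- function(ref, mov, ref_prep = NULL) {
  if (is.null(ref_prep)) ref_prep <- .pc_prepare(ref)
  mov <- .fft_crop(mov)
  b <- mov - mean(mov)
  FA <- ref_prep$fft
  FB <- stats::fft(b)
  cp <- FA * Conj(FB)
  mag <- Mod(cp); mag[mag < 1e-12] <- 1e-12
  r <- Re(stats::fft(cp / mag, inverse = TRUE))
  n <- dim(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  # wrap to signed shifts
  sh <- pk - 1
  sh[1] <- if (sh[1] > n[1] / 2) sh[1] - n[1] else sh[1]
  sh[2] <- if (sh[2] > n[2] / 2) sh[2] - n[2] else sh[2]
  # parabolic refinement per axis on the wrapped correlation surface
  val <- function(i, j) r[(i %% n[1]) + 1, (j %% n[2]) + 1]
  i0 <- pk[1] - 1; j0 <- pk[2] - 1
  refine <- function(vm, v0, vp) {
    den <- vm - 2 * v0 + vp
    if (abs(den) < 1e-12) 0 else 0.5 * (vm - vp) / den
  }
  ddx <- refine(val(i0 - 1, j0), val(i0, j0), val(i0 + 1, j0))
  ddy <- refine(val(i0, j0 - 1), val(i0, j0), val(i0, j0 + 1))
  list(dx = sh[1] + ddx, dy = sh[2] + ddy,
       peak = max(r) / (sqrt(ref_prep$ss * sum(b^2)) + 1e-12))
}

.downsample <- function(img, f) {
  if (f <= 1) return(img)
  d <- dim(img)
  EBImage::imageData(EBImage::resize(EBImage::Image(img / 255),
                                     w = round(d[1] / f),
                                     h = round(d[2] / f),
                                     filter = "bilinear")) * 255
}

#' Estimate the rigid transform aligning one DAPI image onto another
#'
#' Coarse-to-fine search over rotation (each candidate scored by the phase
#' correlation peak after rotating the moving image) followed by sub-pixel
#' phase-correlation translation at full resolution. Accurate to well under
#' 0.5 px and 0.1 degrees for misalignments within the search range.
#'
#' @param dapi_ref Reference DAPI image (integer matrix).
#' @param dapi_mov Moving DAPI image, same shape.
#' @param rot_range Maximum |rotation| searched, degrees.
#' @param coarse_step Rotation grid step for the coarse scan, degrees.
#' @param rot_tol Rotation refinement tolerance, degrees.
#' @param reference_round Stored in the result.
#' @return A `rigid_transform` to apply to `dapi_mov` (see [apply_transform()]).
#' @export
estimate_rigid <- function(dapi_ref, dapi_mov, rot_range = 5,
                           coarse_step = 1, rot_tol = 0.02,
                           reference_round = 1L) {
  if (!all(dim(dapi_ref) == dim(dapi_mov)))
    stop("estimate_rigid: images must share shape")
  if (max(dapi_ref) == min(dapi_ref) || max(dapi_mov) == min(dapi_mov))
    stop("no registration signal: blank image")
  d <- dim(dapi_ref)
  f1 <- max(1, min(d) / 256)               # coarse scale
  f2 <- max(1, min(d) / 512)               # rotation refinement scale
  ft <- max(1, min(d) / 1200)              # translation scale
  ref1 <- .downsample(dapi_ref, f1); mov1 <- .downsample(dapi_mov, f1)
  prep1 <- .pc_prepare(ref1)

  score_at <- function(prep, mov, th) {
    m <- if (th == 0) mov else warp_rigid(.quantize(mov), rotation = th)
    .phase_correlate(NULL, m, ref_prep = prep)$peak
  }
  angles <- seq(-rot_range, rot_range, by = coarse_step)
  sc <- vapply(angles, function(a) score_at(prep1, mov1, a), numeric(1))
  best <- angles[which.max(sc)]

  ref2 <- .downsample(dapi_ref, f2); mov2 <- .downsample(dapi_mov, f2)
  prep2 <- .pc_prepare(ref2)
  fine <- seq(best - 0.5, best + 0.5, by = 0.1)
  sc2 <- vapply(fine, function(a) score_at(prep2, mov2, a), numeric(1))
  i <- which.max(sc2)
  rot <- fine[i]
  if (i > 1 && i < length(fine)) {          # parabolic peak interpolation
    den <- sc2[i - 1] - 2 * sc2[i] + sc2[i + 1]
    if (abs(den) > 1e-12)
      rot <- fine[i] + 0.5 * (sc2[i - 1] - sc2[i + 1]) / den * 0.1
  }
  if (abs(rot) < rot_tol) rot <- 0          # snap: avoids needless resampling

  reft <- .downsample(dapi_ref, ft); movt <- .downsample(dapi_mov, ft)
  sct <- min(d) / min(dim(reft))            # realized scale factor
  rotated <- if (rot == 0) movt else
    warp_rigid(.quantize(movt), rotation = rot)
  pc <- .phase_correlate(reft, rotated)
  rigid_transform(rotation = rot, dx = pc$dx * sct, dy = pc$dy * sct,
                  reference_round = reference_round)
}

#' Apply per-round rigid transforms to an image stack
#'
#' Resamples every image of round `r` by round `r`'s transform (bilinear,
#' rounded back to 8-bit; out-of-frame pixels are 0). Identity transforms
#' leave images bit-identical.
#'
#' @param stack An [image_stack()].
#' @param transforms Named list of `rigid_transform`s, names = round numbers
#'   (as character); rounds without an entry are left untouched.
#' @return The aligned `image_stack`.
#' @export
apply_transform <- function(stack, transforms) {
  imgs <- stack$images
  for (i in seq_along(imgs)) {
    r <- as.character(stack$key$round[i])
    tr <- transforms[[r]]
    if (is.null(tr)) next
    if (tr$rotation == 0 && tr$dx == 0 && tr$dy == 0) next
    imgs[[i]] <- warp_rigid(imgs[[i]], tr$rotation, tr$dx, tr$dy)
  }
  out <- image_stack(imgs, stack$key, stack$microns_per_pixel)
  attr(out, "transforms") <- transforms
  out
}

#' Register all rounds of a stack onto the round-1 DAPI frame
#'
#' Estimates one rigid transform per round from its DAPI image against the
#' round-1 DAPI, then applies it to every channel of that round.
#'
#' @param stack An [image_stack()] with one DAPI image per round.
#' @param ... Passed to [estimate_rigid()].
#' @return The aligned stack; the estimated transforms are attached as the
#'   `transforms` attribute (a named list by round).
#' @export
register_stack <- function(stack, ...) {
  k <- stack$key
  rounds <- sort(unique(k$round))
  ref <- stack_image(stack, round = 1, channel = "DAPI")
  transforms <- list()
  for (r in rounds) {
    transforms[[as.character(r)]] <- if (r == 1) rigid_transform() else
      estimate_rigid(ref, stack_image(stack, round = r, channel = "DAPI"),
                     reference_round = 1L, ...)
  }
  apply_transform(stack, transforms)
}

#' Subtract autofluorescence from a marker image
#'
#' Pixel-wise `max(marker - af, 0)`, staying 8-bit. Only FITC and TRITC
#' channels carry autofluorescence; far-red images are left untouched by
#' [subtract_stack_af()].
#'
#' @param marker_img,af_img Integer matrices of the same shape (0..255).
#' @return Integer matrix.
#' @export
subtract_autofluorescence <- function(marker_img, af_img) {
  if (!all(dim(marker_img) == dim(af_img)))
    stop("subtract_autofluorescence: shape mismatch")
  out <- marker_img - af_img
  out[out < 0] <- 0L
  storage.mode(out) <- "integer"
  out
}

#' Subtract the blank-round autofluorescence from all FITC/TRITC markers
#'
#' Uses the round-0 blank images (`R00_FITC_AF`, `R00_TRITC_AF`) as the
#' autofluorescence reference for their channel.
#'
#' @param stack A registered [image_stack()] containing the blank round.
#' @return The stack with AF-subtracted FITC/TRITC marker images.
#' @export
subtract_stack_af <- function(stack) {
  k <- stack$key
  for (ch in c("FITC", "TRITC")) {
    afi <- which(k$round == 0 & k$channel == ch & is.na(k$marker))
    if (length(afi) != 1) next
    af <- stack$images[[afi]]
    for (i in which(k$channel == ch & !is.na(k$marker)))
      stack$images[[i]] <- subtract_autofluorescence(stack$images[[i]], af)
  }
  stack
}
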
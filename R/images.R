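#' Multi-round multi-channel image stack
#'
#' Container for one registered (or raw) MILAN acquisition: a named list of
#' 8-bit images (stored as integer matrices in 0..255, indexed `[x, y]`), a
#' key table mapping each image to its staining round, channel and marker,
#' and the pixel scale. Round 0 is the blank autofluorescence round; each
#' round carries its own DAPI image.
#'
#' Coordinate convention used throughout the package: pixel centers are at
#' integer coordinates, 1-based; `x` is the first matrix dimension, `y` the
#' second; rotation angles are in degrees, positive rotating the +x axis
#' toward +y.
#'
#' @param images Named list of integer matrices, all the same dimension.
#' @param key `data.frame` with columns `name`, `round`, `channel`, `marker`
#'   (marker is `NA` for DAPI/AF images).
#' @param microns_per_pixel Pixel scale, microns per pixel.
#' @return An `image_stack` object.
#' @export
image_stack <- function(images, key, microns_per_pixel) {
  stopifnot(is.list(images), nrow(key) == length(images),
            all(key$name == names(images)))
  dims <- unique(lapply(images, dim))
  if (length(dims) != 1) stop("image_stack: all images must share one shape")
  rng <- range(vapply(images, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 255)
    stop("image_stack: intensities must lie in [0, 255]")
  structure(list(images = images, key = key,
                 microns_per_pixel = microns_per_pixel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat("image_stack: ", length(x$images), " images of ", d[1], "x", d[2],
      " px (", round(x$microns_per_pixel, 3), " um/px), rounds ",
      paste(range(x$key$round), collapse = "-"), "\n", sep = "")
  invisible(x)
}

#' Fetch one image from a stack
#'
#' @param stack An `image_stack`.
#' @param round Staining round.
#' @param channel Channel token, or `marker` to select by marker name.
#' @param marker Optional marker short name.
#' @return Integer matrix.
#' @export
stack_image <- function(stack, round = NULL, channel = NULL, marker = NULL) {
  k <- stack$key
  sel <- rep(TRUE, nrow(k))
  if (!is.null(round)) sel <- sel & k$round == round
  if (!is.null(channel)) sel <- sel & k$channel == channel
  if (!is.null(marker)) sel <- sel & !is.na(k$marker) & k$marker == marker
  i <- which(sel)
  if (length(i) != 1) stop("stack_image: query matched ", length(i), " images")
  stack$images[[i]]
}

.as_ebimage <- function(img) EBImage::Image(img / 255)

.from_ebimage <- function(eb) {
  m <- EBImage::imageData(eb) * 255
  m[m < 0] <- 0; m[m > 255] <- 255
  storage.mode(m) <- "integer"
  m
}

#' Rigidly warp an 8-bit image
#'
#' Applies the content mapping `p -> R(p - c) + c + t` (rotation about the
#' image center plus translation) with bilinear interpolation; pixels mapped
#' from outside the frame are 0. Values are rounded half-up back to 0..255.
#'
#' @param img Integer matrix (0..255).
#' @param rotation Rotation in degrees (positive: +x toward +y).
#' @param dx,dy Translation in pixels along the first/second dimension.
#' @return Integer matrix of the same shape.
#' @export
warp_rigid <- function(img, rotation = 0, dx = 0, dy = 0) {
  if (rotation == 0 && dx == 0 && dy == 0) {
    storage.mode(img) <- "integer"
    return(img)
  }
  th <- rotation * pi / 180
  R <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  ctr <- (dim(img) + 1) / 2 - 0.5          # affine() works in 1-based - 0.5 coords
  off <- ctr - ctr %*% R + c(dx, dy)
  m <- rbind(R, off)
  out <- EBImage::affine(.as_ebimage(img), m, filter = "bilinear", bg.col = 0)
  m2 <- EBImage::imageData(out) * 255
  m2 <- floor(m2 + 0.5)                    # round half up, reproducibly
  m2[m2 < 0] <- 0; m2[m2 > 255] <- 255
  storage.mode(m2) <- "integer"
  m2
}

#' Write an image stack as a multi-page TIFF plus JSON key
#'
#' One 8-bit grayscale page per image, in key order; the round/channel/marker
#' key and the pixel scale go to a JSON sidecar `<path>.json`.
#'
#' @param stack An `image_stack`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack$images, function(m) {
    # tiff expects [row, col] = [y, x] in 0..1
    t(m) / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  jsonlite::write_json(
    list(microns_per_pixel = stack$microns_per_pixel, key = stack$key),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must be present).
#' @return An `image_stack`.
#' @export
read_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  imgs <- lapply(pages, function(p) {
    m <- t(p * 255)
    storage.mode(m) <- "integer"
    m
  })
  key <- as.data.frame(side$key)
  names(imgs) <- key$name
  image_stack(imgs, key, side$microns_per_pixel)
}

# Low-frequency value-noise field (bilinearly upsampled random grid), used for
# autofluorescence texture. Returns a matrix in [-1, 1].
.noise_field <- function(nx, ny, spacing = 64) {
  gx <- max(2, ceiling(nx / spacing) + 1)
  gy <- max(2, ceiling(ny / spacing) + 1)
  coarse <- matrix(runif(gx * gy, -1, 1), gx, gy)
  up <- EBImage::resize(EBImage::Image(coarse), w = nx, h = ny,
                        filter = "bilinear")
  EBImage::imageData(up)
}
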
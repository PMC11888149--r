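#' Construct an 8-bit RGB image
#'
#' The package represents a capsule-endoscopy frame as an `H x W x 3` integer
#' array of 8-bit channel intensities with class `"rgb_image"`. All analysis
#' functions accept this type; conversion to real-valued intensities happens
#' inside the computation modules, never in I/O.
#'
#' @param pixels numeric or integer array of dimension `H x W x 3` with values
#'   in `[0, 255]`. `H` and `W` must both be at least 8 pixels: smaller grids
#'   cannot hold a meaningful endoscopic field of view and are rejected.
#' @return an integer array of class `"rgb_image"`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stopf("pixels must be an H x W x 3 array")
  }
  d <- dim(pixels)
  if (d[1] < 8 || d[2] < 8) {
    stopf("image dimensions %d x %d are below the 8 x 8 minimum", d[1], d[2])
  }
  if (anyNA(pixels) || !all(is.finite(pixels))) {
    stopf("image contains non-finite values")
  }
  if (any(pixels < 0) || any(pixels > 255)) {
    stopf("channel values must lie in [0, 255]")
  }
  if (any(pixels != round(pixels))) {
    stopf("channel values must be integers; round explicitly before coercion")
  }
  storage.mode(pixels) <- "integer"
  structure(pixels, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<rgb_image> %d x %d, 8-bit, channel means (R,G,B) = (%.1f, %.1f, %.1f)\n",
    d[1], d[2], mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3])
  ))
  invisible(x)
}

#' Construct a binary clean/contaminated mask
#'
#' Masks follow the white-equals-clean convention: `TRUE` marks a clean
#' (visible mucosa) pixel, `FALSE` a contaminated one.
#'
#' @param values logical matrix (`H x W`).
#' @return a logical matrix of class `"binary_mask"`.
#' @export
binary_mask <- function(values) {
  if (!is.matrix(values) || !is.logical(values)) {
    stopf("mask values must be a logical matrix")
  }
  if (anyNA(values)) stopf("mask contains NA values")
  structure(values, class = "binary_mask")
}

#' Read an 8-bit PNG image
#'
#' Grayscale inputs are replicated to three channels; an alpha channel, if
#' present, is dropped. Only 8-bit PNGs are accepted.
#'
#' @param path path to a PNG file.
#' @return an [rgb_image].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read image: '%s' does not exist", path)
  a <- tryCatch(png::readPNG(path, info = TRUE),
    error = function(e) stopf("cannot decode '%s' as PNG: %s", path, conditionMessage(e))
  )
  info <- attr(a, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 8) {
    stopf("'%s' has bit depth %d; only 8-bit images are supported", path, info$bit.depth)
  }
  if (is.matrix(a)) a <- array(a, c(dim(a), 1))
  ch <- dim(a)[3]
  if (ch == 2 || ch == 4) a <- a[, , seq_len(ch - 1), drop = FALSE] # drop alpha
  if (dim(a)[3] == 1) a <- a[, , c(1, 1, 1), drop = FALSE]
  rgb_image(round(a[, , 1:3, drop = FALSE] * 255))
}

#' Read a binary ground-truth mask from PNG
#'
#' Pixel values above 127 (of 255) map to clean (`TRUE`), the rest to
#' contaminated (`FALSE`). The soft threshold makes anti-aliased freehand
#' annotations degrade gracefully; genuinely non-binary content is accepted
#' with a warning. RGB mask files must carry the same values in all channels
#' and are read through the first channel.
#'
#' @param path path to a PNG file.
#' @return a [binary_mask].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stopf("cannot read mask: '%s' does not exist", path)
  a <- tryCatch(png::readPNG(path),
    error = function(e) stopf("cannot decode '%s' as PNG: %s", path, conditionMessage(e))
  )
  if (!is.matrix(a)) {
    ch <- dim(a)[3]
    keep <- min(ch, 3) # ignore alpha when checking channel agreement
    if (keep > 1) {
      for (j in 2:keep) {
        if (any(a[, , j] != a[, , 1])) {
          stopf("'%s': RGB mask channels disagree; not a valid binary mask", path)
        }
      }
    }
    a <- a[, , 1]
  }
  v <- round(a * 255)
  if (!all(v %in% c(0, 255))) {
    warning(sprintf("'%s': mask is not strictly binary; thresholding at >127", path),
      call. = FALSE
    )
  }
  binary_mask(v > 127)
}

#' Write a binary mask as a single-channel PNG
#'
#' Clean (`TRUE`) pixels are written as 255, contaminated as 0, so that
#' `read_mask(write_mask(m))` is the identity.
#'
#' @param mask a [binary_mask] or logical matrix.
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.logical(mask) || !is.matrix(mask)) stopf("mask must be a logical matrix")
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("cannot write mask: directory '%s' does not exist", dir)
  m <- matrix(as.double(mask), nrow(mask), ncol(mask))
  png::writePNG(m, target = path)
  invisible(path)
}

# Images are written through the same 8-bit path (used by generate_corpus and
# the command-line tool).
#' Write an 8-bit RGB image as PNG
#' @param image an [rgb_image].
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  image <- as_rgb_image(image)
  dir <- dirname(path)
  if (!dir.exists(dir)) stopf("cannot write image: directory '%s' does not exist", dir)
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) x else rgb_image(x)
}

#' Circular field-of-view mask
#'
#' Capsule frames carry a circular informative region surrounded by dark
#' corners. This helper builds the corresponding pixel mask: `TRUE` inside the
#' centered circle of radius `min(H, W) / 2 * (1 - margin_fraction)`. FOV
#' restriction is opt-in everywhere in the package; by default all annotated
#' pixels take part in fitting and evaluation.
#'
#' @param height,width image dimensions in pixels.
#' @param margin_fraction fraction of the radius trimmed from the circle,
#'   in `[0, 0.5)`.
#' @return a logical `height x width` matrix with at least one `TRUE` entry.
#' @export
circular_fov <- function(height, width, margin_fraction = 0) {
  if (height < 1 || width < 1) stopf("height and width must be positive")
  if (margin_fraction < 0 || margin_fraction >= 0.5) {
    stopf("margin_fraction must lie in [0, 0.5)")
  }
  r <- min(height, width) / 2 * (1 - margin_fraction)
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  dy <- (seq_len(height) - cy)^2
  dx <- (seq_len(width) - cx)^2
  fov <- outer(dy, dx, "+") <= r^2
  if (!any(fov)) stopf("field of view is empty; decrease margin_fraction")
  fov
}

# Shape agreement between an image and its paired mask.
check_pair <- function(image, mask) {
  d <- dim(image)
  if (nrow(mask) != d[1] || ncol(mask) != d[2]) {
    stopf(
      "mask dimensions (%d x %d) do not match image dimensions (%d x %d)",
      nrow(mask), ncol(mask), d[1], d[2]
    )
  }
  invisible(TRUE)
}

#' Read a manifest CSV pairing images with masks
#'
#' @param path CSV file with columns `image_path` and `mask_path` (optionally
#'   `split`); relative paths are resolved against the manifest's directory.
#' @return a data.frame with absolute `image_path` and `mask_path` columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest '%s' does not exist", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_path", "mask_path") %in% names(m))) {
    stopf("manifest must have columns image_path and mask_path")
  }
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$image_path <- fix(m$image_path)
  m$mask_path <- fix(m$mask_path)
  m
}

#' Load all images and masks listed in a manifest
#'
#' @param manifest a data.frame as returned by [read_manifest()].
#' @return a list with elements `images` and `masks` (parallel lists).
#' @export
load_corpus <- function(manifest) {
  images <- lapply(manifest$image_path, read_image)
  masks <- lapply(manifest$mask_path, read_mask)
  for (i in seq_along(images)) check_pair(images[[i]], masks[[i]])
  list(images = images, masks = masks)
}
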
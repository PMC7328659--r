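#' Raster representations
#'
#' Pixel rasters are plain base-R integer arrays throughout the package:
#' an RGB image is an `H x W x 3` array with channel values in `[0, 255]`
#' (channel order red, green, blue), a grayscale image is an `H x W` matrix
#' in `[0, 255]`, and a binary mask is an `H x W` matrix whose only values
#' are 0 (background, black) and 255 (plant tissue, white). The white = plant
#' polarity is fixed package-wide.
#'
#' @name rasters
NULL

#' Test whether a raster is a valid binary mask
#'
#' @param mask An `H x W` numeric matrix.
#' @return `TRUE` if every pixel is 0 or 255.
#' @export
is_binary_mask <- function(mask) {
  is.matrix(mask) && all(mask == 0 | mask == 255)
}

assert_binary <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) {
    stop(sprintf("`%s` must be an H x W matrix", arg), call. = FALSE)
  }
  if (!all(mask == 0 | mask == 255)) {
    bad <- unique(as.vector(mask[mask != 0 & mask != 255]))
    stop(sprintf(
      "`%s` is not binary: found value(s) %s (only 0 and 255 are allowed)",
      arg, paste(utils::head(bad, 5), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(mask)
}

assert_rgb <- function(img, arg = "img") {
  if (!(is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L)) {
    stop(sprintf("`%s` must be an H x W x 3 array", arg), call. = FALSE)
  }
  if (min(img) < 0 || max(img) > 255) {
    stop(sprintf("`%s` has channel values outside [0, 255]", arg), call. = FALSE)
  }
  invisible(img)
}

#' Read an RGB herbarium sheet image
#'
#' Reads a baseline JPEG or a PNG (8- or 16-bit; 16-bit values are rescaled
#' to 8-bit) and returns an `H x W x 3` integer array in `[0, 255]`.
#' Grayscale files are replicated across the three channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a `.jpg`/`.jpeg` or `.png` file.
#' @return An RGB raster array (see [rasters]).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read image: file does not exist: '%s'", path),
         call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw01 <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE)
    ),
    error = function(e) {
      stop(sprintf("failed to decode image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  # readPNG/readJPEG return doubles in [0, 1] regardless of bit depth
  if (length(dim(raw01)) == 2L) {
    raw01 <- array(raw01, dim = c(dim(raw01), 1L))
  }
  nc <- dim(raw01)[3]
  rgb01 <- if (nc == 1L) {
    array(raw01[, , 1], dim = c(dim(raw01)[1:2], 3L))
  } else {
    raw01[, , 1:3, drop = FALSE]
  }
  img <- round(rgb01 * 255)
  storage.mode(img) <- "integer"
  img
}

#' Read a binary mask PNG
#'
#' @param path Path to an 8-bit grayscale PNG written by [write_mask()] (or
#'   any grayscale PNG; multi-channel files use the first channel).
#' @param strict If `TRUE` (default) the file must be strictly binary
#'   ({0, 255}); set `FALSE` to re-import externally edited masks that still
#'   contain intermediate gray values (then pass through [rebinarize()]).
#' @return An `H x W` matrix; binary when `strict = TRUE`.
#' @export
read_mask <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read mask: file does not exist: '%s'", path),
         call. = FALSE)
  }
  raw01 <- tryCatch(png::readPNG(path), error = function(e) {
    stop(sprintf("failed to decode mask '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  if (length(dim(raw01)) == 3L) raw01 <- raw01[, , 1]
  m <- round(raw01 * 255)
  storage.mode(m) <- "integer"
  if (strict) assert_binary(m, arg = path)
  m
}

#' Write a binary mask as a lossless 8-bit grayscale PNG
#'
#' Masks are always written as PNG even though source sheets are JPEG:
#' a lossy codec would introduce intermediate gray values and destroy the
#' binary-mask invariant. The round trip `read_mask(write_mask(m))` is
#' bit-exact.
#'
#' @param mask A binary mask matrix (values 0/255 only; anything else is a
#'   validation error, never silently written).
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  assert_binary(mask)
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

write_image_png <- function(img, path) {
  assert_rgb(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

#' Convert an RGB image to grayscale luma
#'
#' Uses the ITU-R BT.601 luma weights `0.299 R + 0.587 G + 0.114 B`
#' (the default of the common imaging-library conversion this workflow's
#' preprocessing dialect follows), rounded to the nearest integer and
#' clamped to `[0, 255]`.
#'
#' @param img An RGB raster array.
#' @return An `H x W` integer matrix in `[0, 255]`.
#' @export
to_grayscale <- function(img) {
  assert_rgb(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  g <- round(g)
  g[g < 0] <- 0L
  g[g > 255] <- 255L
  storage.mode(g) <- "integer"
  g
}
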
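# Raster geometry: center crop, resize, and projective (homography) warps.
# Coordinates are (x = column, y = row), 1-based pixel centers.

#' Center square crop
#'
#' Crops a raster (H x W matrix or H x W x C array) to the largest centered
#' square (side = the shorter image side).
#'
#' @param raster Matrix or 3-d array.
#' @return The cropped raster.
#' @export
center_square_crop <- function(raster) {
  d <- dim(raster)
  h <- d[1]; w <- d[2]
  s <- min(h, w)
  r0 <- (h - s) %/% 2L
  c0 <- (w - s) %/% 2L
  if (length(d) == 3L) {
    raster[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), , drop = FALSE]
  } else {
    raster[(r0 + 1L):(r0 + s), (c0 + 1L):(c0 + s), drop = FALSE]
  }
}

# source coordinates for resizing n_src -> n_dst: destination pixel centers
# mapped into 1-based source pixel-center coordinates
resize_src_coords <- function(n_dst, n_src) {
  (seq_len(n_dst) - 0.5) * (n_src / n_dst) + 0.5
}

#' Resize by nearest-neighbor sampling
#'
#' Used for masks everywhere: nearest-neighbor never interpolates, so the
#' binary-mask invariant survives any geometry.
#'
#' @param raster Matrix or H x W x C array.
#' @param h,w Target height and width.
#' @return The resized raster, same storage mode as the input.
#' @export
resize_nearest <- function(raster, h, w) {
  d <- dim(raster)
  ri <- pmin(pmax(round(resize_src_coords(h, d[1])), 1L), d[1])
  ci <- pmin(pmax(round(resize_src_coords(w, d[2])), 1L), d[2])
  if (length(d) == 3L) raster[ri, ci, , drop = FALSE] else raster[ri, ci, drop = FALSE]
}

#' Resize by bilinear interpolation
#'
#' Used for photographic content (the sheet image); masks go through
#' [resize_nearest()] instead.
#'
#' @inheritParams resize_nearest
#' @return A numeric raster of the target size (not rounded).
#' @export
resize_bilinear <- function(raster, h, w) {
  d <- dim(raster)
  ys <- pmin(pmax(resize_src_coords(h, d[1]), 1), d[1])
  xs <- pmin(pmax(resize_src_coords(w, d[2]), 1), d[2])
  y0 <- pmin(floor(ys), d[1] - 1L); fy <- ys - y0
  x0 <- pmin(floor(xs), d[2] - 1L); fx <- xs - x0
  interp_plane <- function(m) {
    a <- m[y0, x0, drop = FALSE]; b <- m[y0, x0 + 1L, drop = FALSE]
    c_ <- m[y0 + 1L, x0, drop = FALSE]; dd <- m[y0 + 1L, x0 + 1L, drop = FALSE]
    wfy <- matrix(fy, h, w); wfx <- matrix(fx, h, w, byrow = TRUE)
    a * (1 - wfy) * (1 - wfx) + b * (1 - wfy) * wfx +
      c_ * wfy * (1 - wfx) + dd * wfy * wfx
  }
  if (length(d) == 3L) {
    out <- array(0, dim = c(h, w, d[3]))
    for (ch in seq_len(d[3])) out[, , ch] <- interp_plane(raster[, , ch])
    out
  } else {
    interp_plane(raster)
  }
}

#' Prepare an image/mask pair for the network
#'
#' The data-handling geometry used for both training and prediction:
#' rectangular inputs are center-cropped to the shorter side (the square
#' output "crops" rectangular inputs), then resized to `size x size`. The
#' image is resampled bilinearly; the mask by nearest neighbor so it stays
#' strictly binary.
#'
#' @param img RGB raster array.
#' @param mask Binary mask with the same height/width as `img`, or `NULL`
#'   to prepare an image alone (prediction path).
#' @param size Output side in pixels (default 256).
#' @return List with `image` (`size x size x 3` integer array) and `mask`
#'   (`size x size` binary matrix, or `NULL`).
#' @export
prepare_sample <- function(img, mask = NULL, size = 256) {
  assert_rgb(img)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(img)[1:2])) {
      stop("image and mask dimensions differ", call. = FALSE)
    }
    assert_binary(mask)
  }
  im <- resize_bilinear(center_square_crop(img), size, size)
  im <- round(im)
  im[im < 0] <- 0; im[im > 255] <- 255
  storage.mode(im) <- "integer"
  m <- if (is.null(mask)) NULL else resize_nearest(center_square_crop(mask), size, size)
  list(image = im, mask = m)
}

# --- homographies ------------------------------------------------------------

# 3x3 identity homography
identity_homography <- function() diag(3)

# affine transform about the raster center: flip (x), rotation (degrees,
# counter-clockwise), isotropic zoom. Returns the forward map src -> dst.
affine_about_center <- function(h, w, flip = FALSE, angle_deg = 0, zoom = 1) {
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  scl <- diag(c(zoom, zoom, 1))
  flp <- diag(c(if (flip) -1 else 1, 1, 1))
  to0 <- matrix(c(1, 0, 0, 0, 1, 0, -cx, -cy, 1), 3, 3)
  back <- matrix(c(1, 0, 0, 0, 1, 0, cx, cy, 1), 3, 3)
  back %*% rot %*% scl %*% flp %*% to0
}

# homography mapping the four source corners onto displaced destination
# corners (direct linear transform, 8 unknowns)
corner_homography <- function(src, dst) {
  a <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    a[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    a[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  p <- solve(a, b)
  matrix(c(p[1:3], p[4:6], p[7:8], 1), 3, 3, byrow = TRUE)
}

# Apply a forward homography (src -> dst) to a raster by inverse mapping.
# method "bilinear" clamps samples to the raster; "nearest" fills
# out-of-bounds with `fill` (background for masks).
warp_homography <- function(raster, hom, method = c("bilinear", "nearest"),
                            fill = 0) {
  method <- match.arg(method)
  d <- dim(raster)
  h <- d[1]; w <- d[2]
  hin <- solve(hom)
  gx <- rep(seq_len(w), each = h)
  gy <- rep(seq_len(h), times = w)
  den <- hin[3, 1] * gx + hin[3, 2] * gy + hin[3, 3]
  xs <- (hin[1, 1] * gx + hin[1, 2] * gy + hin[1, 3]) / den
  ys <- (hin[2, 1] * gx + hin[2, 2] * gy + hin[2, 3]) / den
  if (method == "nearest") {
    xi <- round(xs); yi <- round(ys)
    ok <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    xi[!ok] <- 1L; yi[!ok] <- 1L
    idx <- (xi - 1L) * h + yi
    sample_plane <- function(m) {
      v <- m[idx]
      v[!ok] <- fill
      matrix(v, h, w)
    }
  } else {
    xc <- pmin(pmax(xs, 1), w); yc <- pmin(pmax(ys, 1), h)
    x0 <- pmin(floor(xc), w - 1L); fx <- xc - x0
    y0 <- pmin(floor(yc), h - 1L); fy <- yc - y0
    i00 <- (x0 - 1) * h + y0
    sample_plane <- function(m) {
      v <- m[i00] * (1 - fx) * (1 - fy) + m[i00 + h] * fx * (1 - fy) +
        m[i00 + 1] * (1 - fx) * fy + m[i00 + h + 1] * fx * fy
      matrix(v, h, w)
    }
  }
  if (length(d) == 3L) {
    out <- array(0, dim = d)
    for (ch in seq_len(d[3])) out[, , ch] <- sample_plane(raster[, , ch])
    out
  } else {
    sample_plane(raster)
  }
}

#' Flip a raster horizontally
#'
#' @param raster Matrix or H x W x C array.
#' @return The mirrored raster (an involution: flipping twice is identity).
#' @export
flip_horizontal <- function(raster) {
  d <- dim(raster)
  if (length(d) == 3L) raster[, d[2]:1, , drop = FALSE] else raster[, d[2]:1, drop = FALSE]
}
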
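#' Augmentation configuration
#'
#' The training-time augmentation recipe: horizontal flip at probability
#' 0.5, and — each applied independently at probability 0.75 — rotation up
#' to 10 degrees, zoom up to a factor of 1.1, lighting adjustment up to a
#' factor of 0.2 (image only), and perspective warping up to a factor of
#' 0.2. Geometric transforms are applied identically to the image and its
#' mask; the mask is re-binarized after resampling.
#'
#' @param hflip_prob Probability of a horizontal flip (default 0.5).
#' @param transform_prob Probability each other transform fires (default 0.75).
#' @param rot_max_deg Maximum absolute rotation in degrees (default 10).
#' @param zoom_max Maximum zoom factor, `>= 1` (default 1.1).
#' @param light_max Maximum relative brightness/contrast adjustment (default 0.2).
#' @param warp_max Maximum perspective-warp magnitude as a fraction of the
#'   image side (default 0.2); realized as random displacement of the four
#'   corners, each coordinate drawn uniformly within `warp_max/2` of a side.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(hflip_prob = 0.5, transform_prob = 0.75,
                           rot_max_deg = 10, zoom_max = 1.1,
                           light_max = 0.2, warp_max = 0.2) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1,
            transform_prob >= 0, transform_prob <= 1,
            rot_max_deg >= 0, zoom_max >= 1, light_max >= 0, warp_max >= 0)
  structure(list(hflip_prob = hflip_prob, transform_prob = transform_prob,
                 rot_max_deg = rot_max_deg, zoom_max = zoom_max,
                 light_max = light_max, warp_max = warp_max),
            class = "augment_config")
}

# draw one set of augmentation parameters from the current RNG stream
sample_augment_params <- function(cfg, side) {
  p <- list(flip = runif(1) < cfg$hflip_prob, angle = 0, zoom = 1,
            corners = NULL, light = NULL)
  if (cfg$rot_max_deg > 0 && runif(1) < cfg$transform_prob) {
    p$angle <- runif(1, -cfg$rot_max_deg, cfg$rot_max_deg)
  }
  if (cfg$zoom_max > 1 && runif(1) < cfg$transform_prob) {
    p$zoom <- runif(1, 1, cfg$zoom_max)
  }
  if (cfg$warp_max > 0 && runif(1) < cfg$transform_prob) {
    amp <- cfg$warp_max * side / 2
    p$corners <- matrix(runif(8, -amp, amp), 4, 2)
  }
  if (cfg$light_max > 0 && runif(1) < cfg$transform_prob) {
    p$light <- list(brightness = runif(1, 1 - cfg$light_max, 1 + cfg$light_max),
                    contrast = runif(1, 1 - cfg$light_max, 1 + cfg$light_max))
  }
  p
}

# the forward homography encoded by a parameter draw (identity if no
# geometric component fired)
augment_homography <- function(params, side) {
  hom <- affine_about_center(side, side, flip = params$flip,
                             angle_deg = params$angle, zoom = params$zoom)
  if (!is.null(params$corners)) {
    src <- matrix(c(1, 1, side, 1, side, side, 1, side), 4, 2, byrow = TRUE)
    hom <- corner_homography(src, src + params$corners) %*% hom
  }
  hom
}

is_identity_geometry <- function(params) {
  !params$flip && params$angle == 0 && params$zoom == 1 && is.null(params$corners)
}

#' Apply a sampled geometric augmentation to a single raster
#'
#' Exposes the geometric pathway of [augment_pair()] so the identical
#' transform chain can be replayed on another raster (e.g. to verify
#' image/mask alignment).
#'
#' @param raster Square matrix or H x W x C array.
#' @param params A parameter draw as stored in the `params` element of an
#'   [augment_pair()] result.
#' @param method `"bilinear"` (image content) or `"nearest"` (masks).
#' @return The transformed raster.
#' @export
apply_augment_geometry <- function(raster, params, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (is_identity_geometry(params)) return(raster)
  side <- dim(raster)[1]
  if (params$flip && params$angle == 0 && params$zoom == 1 && is.null(params$corners)) {
    return(flip_horizontal(raster))   # exact mirror, no resampling
  }
  warp_homography(raster, augment_homography(params, side), method = method)
}

apply_lighting <- function(img, light) {
  x <- (img - 127.5) * light$contrast + 127.5
  x <- x * light$brightness
  x <- round(x)
  x[x < 0] <- 0; x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Randomly augment an image/mask pair
#'
#' Draws one transform chain from the current RNG stream (seed it for
#' reproducibility) and applies the geometric part identically to the image
#' (bilinear) and the mask (nearest neighbor, re-binarized afterwards); the
#' lighting adjustment touches the image only. With all probabilities 0 the
#' pair is returned unchanged.
#'
#' @param img Square RGB raster array.
#' @param mask Square binary mask of matching size.
#' @param cfg An [augment_config()].
#' @return List with `image`, `mask`, and the sampled `params` (so the
#'   chain can be replayed via [apply_augment_geometry()]).
#' @export
augment_pair <- function(img, mask, cfg = augment_config()) {
  assert_rgb(img)
  assert_binary(mask)
  if (!all(dim(mask) == dim(img)[1:2])) {
    stop("image and mask dimensions differ", call. = FALSE)
  }
  if (dim(img)[1] != dim(img)[2]) {
    stop("augmentation expects square inputs (run prepare_sample() first)",
         call. = FALSE)
  }
  params <- sample_augment_params(cfg, dim(img)[1])
  im <- apply_augment_geometry(img, params, method = "bilinear")
  m <- apply_augment_geometry(mask, params, method = "nearest")
  m <- rebinarize(m)
  if (!is.null(params$light)) {
    im <- apply_lighting(im, params$light)
  } else {
    im <- round(im)
    im[im < 0] <- 0; im[im > 255] <- 255
    storage.mode(im) <- "integer"
  }
  list(image = im, mask = m, params = params)
}
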
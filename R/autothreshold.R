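#' Grayscale histogram
#'
#' Exact integer counts of pixel values 0..255.
#'
#' @param img An `H x W` grayscale matrix in `[0, 255]`.
#' @return An object of class `gray_histogram`: a list with `counts`
#'   (length-256 integer vector, `counts[v + 1]` = number of pixels with
#'   value `v`) and `total` (pixel count).
#' @export
gray_histogram <- function(img) {
  if (!is.matrix(img)) stop("`img` must be an H x W matrix", call. = FALSE)
  if (min(img) < 0 || max(img) > 255) {
    stop("grayscale values must lie in [0, 255]", call. = FALSE)
  }
  counts <- tabulate(as.integer(img) + 1L, nbins = 256L)
  structure(list(counts = counts, total = length(img)),
            class = "gray_histogram")
}

#' Otsu's automatic threshold
#'
#' Picks the threshold `t` in `[0, 255]` that maximizes the between-class
#' variance of the value distribution split into class 0 (values `<= t`) and
#' class 1 (values `> t`); this is equivalent to minimizing the weighted
#' intraclass variance. Computed with cumulative-moment recurrences in one
#' pass over the 256 bins. Ties are broken by the lowest maximizing
#' threshold. A histogram with a single occupied bin (a constant image)
#' does not error: it returns that bin's value flagged `degenerate = TRUE`
#' so batch runs over curated sheets continue.
#'
#' @param hist A [gray_histogram()], or a grayscale matrix (histogrammed
#'   internally).
#' @return An object of class `otsu_result`: list with integer `threshold`,
#'   `between_class_variance` and logical `degenerate`.
#' @export
otsu_threshold <- function(hist) {
  if (is.matrix(hist)) hist <- gray_histogram(hist)
  if (!inherits(hist, "gray_histogram")) {
    stop("`hist` must be a gray_histogram or a grayscale matrix", call. = FALSE)
  }
  counts <- as.numeric(hist$counts)
  total <- sum(counts)
  if (total < 1) stop("empty histogram: total pixel count is 0", call. = FALSE)
  v <- 0:255
  w0 <- cumsum(counts) / total              # P(value <= t)
  m0 <- cumsum(counts * v) / total          # partial first moment
  mu <- m0[256]                             # global mean
  w1 <- 1 - w0
  # between-class variance; undefined (one empty class) -> 0
  num <- (mu * w0 - m0)^2
  den <- w0 * w1
  sigma_b2 <- ifelse(den > 0, num / den, 0)
  degenerate <- sum(counts > 0) == 1L
  t_best <- if (degenerate) {
    which(counts > 0) - 1L      # a constant image: threshold = its value
  } else {
    which.max(sigma_b2) - 1L    # which.max takes the lowest tie
  }
  structure(list(
    threshold = t_best,
    between_class_variance = sigma_b2[t_best + 1L],
    degenerate = degenerate
  ), class = "otsu_result")
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("Otsu threshold: %d (between-class variance %.4f%s)\n",
              x$threshold, x$between_class_variance,
              if (x$degenerate) ", degenerate single-valued image" else ""))
  invisible(x)
}

#' Threshold a grayscale image into a foreground/background mask pair
#'
#' The foreground mask assigns white (255) to the dark class (`value <= t`)
#' — plant tissue is darker than the off-white mounting sheet — and the
#' background mask is its pixelwise inverse.
#'
#' @param img An `H x W` grayscale matrix.
#' @param t Integer threshold in `[0, 255]`.
#' @return An object of class `mask_pair`: list with binary `foreground`
#'   and `background` matrices (pixelwise complements).
#' @export
threshold_to_pair <- function(img, t) {
  if (length(t) != 1L || is.na(t) || t < 0 || t > 255) {
    stop("threshold `t` must be a single integer in [0, 255]", call. = FALSE)
  }
  fg <- matrix(0L, nrow(img), ncol(img))
  fg[img <= t] <- 255L
  structure(list(foreground = fg, background = 255L - fg),
            class = "mask_pair")
}

#' Automatic preliminary mask for a sheet image
#'
#' The composition grayscale -> histogram -> Otsu -> threshold pair: the
#' automatic first stage of the mask-generation workflow, run before any
#' manual editing.
#'
#' @param img An RGB raster array.
#' @return List with `pair` (a `mask_pair`) and `otsu` (the `otsu_result`).
#' @export
auto_mask <- function(img) {
  g <- to_grayscale(img)
  res <- otsu_threshold(gray_histogram(g))
  list(pair = threshold_to_pair(g, res$threshold), otsu = res)
}
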
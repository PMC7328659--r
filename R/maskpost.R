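#' Re-binarize a grayscale mask
#'
#' Externally edited masks (brush and shape tools leave antialiased gray
#' edge pixels) are forced back to strict {0, 255}: pixels strictly above
#' `cutoff` become 255, all others 0. Idempotent on already-binary masks.
#'
#' @param img An `H x W` matrix in `[0, 255]`.
#' @param cutoff Integer in `[0, 254]`; default 127 so that 128 -> 255.
#' @return A binary mask matrix.
#' @export
rebinarize <- function(img, cutoff = 127) {
  if (cutoff < 0 || cutoff > 254) {
    stop("`cutoff` must lie in [0, 254]", call. = FALSE)
  }
  out <- matrix(0L, nrow(img), ncol(img))
  out[img > cutoff] <- 255L
  out
}

# symmetric (edge-repeating) reflection of out-of-range indices into 1..n
reflect_index <- function(i, n) {
  ifelse(i < 1L, 1L - i, ifelse(i > n, 2L * n + 1L - i, i))
}

#' Despeckle a binary mask by neighborhood median filtering
#'
#' Applies a `kernel x kernel` median filter (edges handled by symmetric
#' reflection padding) followed by re-binarization at 127. On a binary
#' mask the median is a majority vote over the neighborhood, so isolated
#' specks — dust and debris mislabeled as plant tissue — smaller than the
#' majority of the window are smoothed away while large blobs and edges are
#' preserved. Implemented with integral-image box counts, which is exactly
#' the brute-force median-then-binarize result.
#'
#' @param mask A binary mask matrix.
#' @param kernel Odd integer window side, `>= 3` and `<= min(H, W)`.
#' @return A binary mask matrix of the same size.
#' @export
despeckle <- function(mask, kernel) {
  assert_binary(mask)
  h <- nrow(mask); w <- ncol(mask)
  if (length(kernel) != 1L || kernel %% 2 == 0 || kernel < 3) {
    stop("`kernel` must be a single odd integer >= 3", call. = FALSE)
  }
  if (kernel > min(h, w)) {
    stop(sprintf("`kernel` (%d) exceeds the smallest image side (%d)",
                 kernel, min(h, w)), call. = FALSE)
  }
  r <- (kernel - 1L) %/% 2L
  ri <- reflect_index((1L - r):(h + r), h)
  ci <- reflect_index((1L - r):(w + r), w)
  padded <- (mask[ri, ci, drop = FALSE] == 255L) * 1L
  # integral image with a zero first row/column
  ii <- matrix(0, h + 2L * r + 1L, w + 2L * r + 1L)
  ii[-1, -1] <- apply(apply(padded, 2, cumsum), 1, cumsum) |> t()
  k <- kernel
  rows <- 1:h; cols <- 1:w
  cnt <- ii[rows + k, cols + k, drop = FALSE] -
    ii[rows, cols + k, drop = FALSE] -
    ii[rows + k, cols, drop = FALSE] +
    ii[rows, cols, drop = FALSE]
  majority <- (k * k + 1) / 2
  out <- matrix(0L, h, w)
  out[cnt >= majority] <- 255L
  out
}

#' Despeckle sweep over several kernel sizes
#'
#' The workflow runs the despeckle step at a few window sizes and a human
#' picks the best-looking candidate; no automatic selection is performed
#' here. All candidates are returned for inspection.
#'
#' @param mask A binary mask matrix.
#' @param kernel_sizes Odd integers `>= 3`; default `c(5, 11, 21)`
#'   (small / medium / large).
#' @return An object of class `blur_sweep`: list with `kernel_sizes` and
#'   `candidates` (one binary mask per size).
#' @export
blur_sweep <- function(mask, kernel_sizes = c(5, 11, 21)) {
  if (length(kernel_sizes) == 0) {
    stop("`kernel_sizes` must contain at least one kernel size", call. = FALSE)
  }
  candidates <- lapply(kernel_sizes, function(k) despeckle(mask, k))
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 candidates = candidates),
            class = "blur_sweep")
}

#' @export
print.blur_sweep <- function(x, ...) {
  cat(sprintf("Despeckle sweep over kernel sizes {%s}: %d candidate mask(s)\n",
              paste(x$kernel_sizes, collapse = ", "), length(x$candidates)))
  invisible(x)
}
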
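# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy an evaluation report
#'
#' @param x A `mask_eval` from [evaluate_model()].
#' @param ... Unused.
#' @return The per-image score tibble.
#' @export
tidy.mask_eval <- function(x, ...) x$per_image

#' One-row summary of an evaluation report
#'
#' @inheritParams tidy.mask_eval
#' @return The overall tibble (n, mean Dice, mean pixel accuracy, total
#'   pixel predictions).
#' @export
glance.mask_eval <- function(x, ...) x$overall

#' Tidy a training history
#'
#' @param x A `segnet_history` from [fit_segnet()].
#' @param ... Unused.
#' @return Long tibble with columns `epoch`, `metric`, `value`.
#' @export
tidy.segnet_history <- function(x, ...) {
  tidyr::pivot_longer(x$epochs, -"epoch",
                      names_to = "metric", values_to = "value")
}

#' One-row summary of a training history
#'
#' @inheritParams tidy.segnet_history
#' @return Tibble with epoch count, final losses and final validation Dice.
#' @export
glance.segnet_history <- function(x, ...) {
  last <- x$epochs[nrow(x$epochs), ]
  tibble::tibble(epochs = nrow(x$epochs),
                 train_loss = last$train_loss,
                 val_loss = last$val_loss,
                 val_dice = last$val_dice,
                 n_train = length(x$split$train),
                 n_val = length(x$split$val))
}

#' Per-family Dice bar chart
#'
#' @param object A `mask_eval`.
#' @param ... Unused.
#' @return A ggplot object: one bar per family, overall mean as a dashed
#'   line.
#' @export
autoplot.mask_eval <- function(object, ...) {
  ggplot2::ggplot(object$per_family,
                  ggplot2::aes(x = stats::reorder(.data$family, .data$mean_dice),
                               y = .data$mean_dice)) +
    ggplot2::geom_col(fill = "#4d7c54") +
    ggplot2::geom_hline(yintercept = object$overall$mean_dice,
                        linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Mean Sørensen–Dice coefficient",
                  title = "Segmentation performance by family") +
    ggplot2::theme_minimal()
}

#' Training curves
#'
#' @param object A `segnet_history`.
#' @param ... Unused.
#' @return A ggplot object with loss curves and validation Dice by epoch.
#' @export
autoplot.segnet_history <- function(object, ...) {
  ggplot2::ggplot(tidy.segnet_history(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               color = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Epoch", y = NULL, color = NULL,
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Display a raster or mask with ggplot2
#'
#' Convenience viewer for sheets and masks.
#'
#' @param raster An RGB array or a grayscale/binary matrix.
#' @return A ggplot object.
#' @export
plot_raster <- function(raster) {
  d <- dim(raster)
  if (length(d) == 3L) {
    hex <- grDevices::rgb(raster[, , 1], raster[, , 2], raster[, , 3],
                          maxColorValue = 255)
  } else {
    v <- raster / 255
    hex <- grDevices::gray(v)
  }
  df <- tibble::tibble(
    x = rep(seq_len(d[2]), each = d[1]),
    y = rep(seq_len(d[1]), times = d[2]),
    fill = as.vector(hex)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = df$fill) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
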
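#' Sørensen–Dice coefficient between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)` over foreground (255) pixel sets. The
#' degenerate both-empty case is defined as 1.0: an empty prediction of an
#' empty truth is correct and should not be penalized.
#'
#' @param pred,truth Binary mask matrices of equal size.
#' @return A value in `[0, 1]`.
#' @export
dice <- function(pred, truth) {
  assert_binary(pred, "pred"); assert_binary(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  p <- pred == 255L; t_ <- truth == 255L
  denom <- sum(p) + sum(t_)
  if (denom == 0) return(1.0)
  2 * sum(p & t_) / denom
}

#' Pixel accuracy between two binary masks
#'
#' The fraction of pixels whose labels agree. Reported alongside Dice
#' because the two differ whenever the classes are imbalanced (accuracy
#' credits correct background, Dice only foreground overlap).
#'
#' @inheritParams dice
#' @return A value in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  assert_binary(pred, "pred"); assert_binary(truth, "truth")
  if (!all(dim(pred) == dim(truth))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  mean(pred == truth)
}

#' Total per-pixel predictions for a batch
#'
#' One `size x size` predicted mask is `size^2` individual pixel
#' predictions; `n` images are `n * size^2` (e.g. one 256 x 256 mask is
#' 65,536 predictions).
#'
#' @param n_images Number of images (`>= 0`).
#' @param size Mask side in pixels.
#' @return The count, as a double (exceeds integer range quickly).
#' @export
count_pixel_predictions <- function(n_images, size = 256) {
  if (n_images < 0) stop("n_images must be >= 0", call. = FALSE)
  as.numeric(n_images) * as.numeric(size)^2
}

# per-family and overall aggregation of a per-image score table
summarize_eval <- function(per_image, size) {
  per_family <- per_image |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(n_images = dplyr::n(),
                     mean_dice = mean(.data$dice),
                     mean_pixel_accuracy = mean(.data$pixel_accuracy),
                     .groups = "drop") |>
    dplyr::arrange(.data$family)
  overall <- tibble::tibble(
    n_images = nrow(per_image),
    mean_dice = mean(per_image$dice),
    mean_pixel_accuracy = mean(per_image$pixel_accuracy),
    total_pixel_predictions = count_pixel_predictions(nrow(per_image), size)
  )
  list(per_family = per_family, overall = overall)
}

#' Evaluate a segmentation model over a manifest
#'
#' For every manifest row the image is read, a mask is predicted, and the
#' ground-truth mask is passed through the identical crop/resize geometry
#' as the prediction ([prepare_sample()]) before scoring — evaluation
#' happens at model resolution, `size^2` pixel predictions per image.
#' Per-family rows are unweighted means of per-image Dice within the
#' `family` column (taken verbatim, case-sensitive); the overall mean is
#' unweighted over images. Unreadable rows are collected as errors and the
#' run continues.
#'
#' @param model A `fern_segnet`.
#' @param manifest A manifest tibble (see [read_manifest()]) with at least
#'   `image` and `mask` columns; `catalog_number` and `family` are carried
#'   into the report when present.
#' @return An object of class `mask_eval`: list of tibbles `per_image`
#'   (catalog_number, family, dice, pixel_accuracy), `per_family`,
#'   `overall`, and `errors`.
#' @export
evaluate_model <- function(model, manifest) {
  stopifnot(inherits(model, "fern_segnet"))
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  size <- model$arch$image_size
  if (is.null(manifest$catalog_number)) {
    manifest$catalog_number <- sprintf("img%04d", seq_len(nrow(manifest)))
  }
  if (is.null(manifest$family)) manifest$family <- "unknown"
  rows <- vector("list", nrow(manifest))
  errs <- list()
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch({
      img <- read_image(manifest$image[i])
      truth <- read_mask(manifest$mask[i])
      truth_sz <- resize_nearest(center_square_crop(truth), size, size)
      pred <- predict_mask(model, img)
      tibble::tibble(catalog_number = manifest$catalog_number[i],
                     family = manifest$family[i],
                     dice = dice(pred, truth_sz),
                     pixel_accuracy = pixel_accuracy(pred, truth_sz))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        catalog_number = manifest$catalog_number[i],
        error = conditionMessage(res))
    } else {
      rows[[i]] <- res
    }
  }
  per_image <- dplyr::bind_rows(rows)
  if (nrow(per_image) == 0) {
    stop("no manifest row could be evaluated", call. = FALSE)
  }
  agg <- summarize_eval(per_image, size)
  structure(list(per_image = per_image, per_family = agg$per_family,
                 overall = agg$overall,
                 errors = dplyr::bind_rows(errs)),
            class = "mask_eval")
}

#' @export
print.mask_eval <- function(x, ...) {
  cat(sprintf("Segmentation evaluation over %d image(s)\n",
              x$overall$n_images))
  cat(sprintf("  mean Dice: %.3f   mean pixel accuracy: %.3f   pixel predictions: %s\n\n",
              x$overall$mean_dice, x$overall$mean_pixel_accuracy,
              format(x$overall$total_pixel_predictions, big.mark = ",")))
  fam <- x$per_family
  cat(sprintf("  %-22s %6s %12s\n", "Family", "n", "mean Dice"))
  for (i in seq_len(nrow(fam))) {
    cat(sprintf("  %-22s %6d %12.3f\n", fam$family[i], fam$n_images[i],
                fam$mean_dice[i]))
  }
  if (nrow(x$errors) > 0) {
    cat(sprintf("\n  %d row(s) failed to evaluate\n", nrow(x$errors)))
  }
  invisible(x)
}

#' Write an evaluation report as CSV files
#'
#' Writes `<stem>_per_image.csv`, `<stem>_per_family.csv` and
#' `<stem>_overall.csv`.
#'
#' @param report A `mask_eval`.
#' @param stem Output path stem.
#' @return The three paths, invisibly.
#' @export
write_eval_report <- function(report, stem) {
  stopifnot(inherits(report, "mask_eval"))
  paths <- paste0(stem, c("_per_image.csv", "_per_family.csv", "_overall.csv"))
  utils::write.csv(report$per_image, paths[1], row.names = FALSE)
  utils::write.csv(report$per_family, paths[2], row.names = FALSE)
  utils::write.csv(report$overall, paths[3], row.names = FALSE)
  invisible(paths)
}
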
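test_that("Dice satisfies its identities and the worked overlap example", {
  withr::local_seed(14)
  a <- random_mask(16, 16, 0.4)
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, 255L - a), 0.0)

  # 2 foreground px each, overlap 1 -> 2*1 / (2+2) = 0.5
  p <- matrix(0L, 3, 3); p[1, 1] <- 255L; p[2, 2] <- 255L
  t_ <- matrix(0L, 3, 3); t_[2, 2] <- 255L; t_[3, 3] <- 255L
  expect_equal(dice(p, t_), 0.5)

  expect_equal(dice(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1.0)
  expect_error(dice(a, random_mask(8, 8)), "differ")
})

test_that("Dice is symmetric on random mask pairs", {
  withr::local_seed(15)
  for (i in 1:20) {
    a <- random_mask(12, 12, runif(1))
    b <- random_mask(12, 12, runif(1))
    expect_equal(dice(a, b), dice(b, a))
  }
})

test_that("pixel accuracy counts shared labels", {
  withr::local_seed(16)
  a <- random_mask(16, 16)
  expect_equal(pixel_accuracy(a, a), 1.0)
  expect_equal(pixel_accuracy(a, 255L - a), 0.0)

  truth <- random_mask(256, 256, 0.3)
  pred <- truth
  flip_idx <- sample(length(pred), 655)
  pred[flip_idx] <- 255L - pred[flip_idx]
  expect_equal(pixel_accuracy(pred, truth), 1 - 655 / 65536)
})

test_that("dice and pixel accuracy differ by at most the agreement structure allows", {
  withr::local_seed(17)
  for (i in 1:20) {
    a <- random_mask(20, 20, runif(1, 0.05, 0.95))
    b <- random_mask(20, 20, runif(1, 0.05, 0.95))
    bg <- mean(a == 0L & b == 0L)
    expect_lte(abs(dice(a, b) - pixel_accuracy(a, b)), bg + 1e-12)
  }
})

test_that("pixel-prediction bookkeeping matches the published counts", {
  expect_equal(count_pixel_predictions(1, 256), 65536)
  expect_equal(count_pixel_predictions(320, 256), 20971520)   # ~21 million
  expect_equal(count_pixel_predictions(80, 256), 5242880)     # ~5 million
  expect_error(count_pixel_predictions(-1), ">= 0")
})

test_that("per-family aggregation is an unweighted mean of image scores", {
  per_image <- tibble::tibble(
    catalog_number = sprintf("c%d", 1:4),
    family = c("A", "A", "B", "B"),
    dice = c(1.0, 0.8, 0.6, 0.6),
    pixel_accuracy = c(1.0, 0.9, 0.7, 0.7)
  )
  agg <- fernmask:::summarize_eval(per_image, size = 256)
  expect_equal(agg$per_family$mean_dice, c(0.9, 0.6))
  expect_equal(agg$per_family$n_images, c(2L, 2L))
  expect_equal(agg$overall$mean_dice, 0.75)
  expect_equal(agg$overall$total_pixel_predictions, 4 * 65536)
})

test_that("evaluate_model scores at model resolution and keeps its invariants", {
  dir <- withr::local_tempdir()
  manifest <- generate_dataset(6, sheet_config(height = 128, width = 96,
                                               seed = 50), dir)
  cfg <- train_config(image_size = 64, encoder_depth = 3, base_channels = 4,
                      seed = 1)
  model <- build_segnet(cfg)
  rep1 <- evaluate_model(model, manifest)
  expect_s3_class(rep1, "mask_eval")
  expect_equal(nrow(rep1$per_image), 6)
  expect_true(all(rep1$per_image$dice >= 0 & rep1$per_image$dice <= 1))
  expect_equal(sum(rep1$per_family$n_images), rep1$overall$n_images)
  expect_equal(rep1$overall$total_pixel_predictions, 6 * 64^2)

  rep2 <- evaluate_model(model, manifest)
  expect_identical(rep1$per_image, rep2$per_image)

  # broken rows are collected, the run continues
  bad <- manifest
  bad$image[2] <- file.path(dir, "missing.png")
  rep3 <- evaluate_model(model, bad)
  expect_equal(nrow(rep3$per_image), 5)
  expect_equal(nrow(rep3$errors), 1)

  expect_error(evaluate_model(model, manifest[0, ]), "empty")

  paths <- write_eval_report(rep1, file.path(dir, "report"))
  expect_true(all(file.exists(paths)))
})

test_that("tidiers and autoplot methods return the expected shapes", {
  dir <- withr::local_tempdir()
  manifest <- generate_dataset(4, sheet_config(height = 96, width = 96,
                                               seed = 60), dir)
  model <- build_segnet(train_config(image_size = 32, encoder_depth = 2,
                                     base_channels = 2, seed = 1))
  rep <- evaluate_model(model, manifest)
  expect_identical(tidy(rep), rep$per_image)
  expect_identical(glance(rep), rep$overall)
  expect_s3_class(autoplot(rep), "ggplot")

  sheets <- lapply(1:6, function(i) small_sheet(i, 64, 64))
  fit <- fit_segnet(NULL, sheets,
                    train_config(image_size = 32, epochs = 2,
                                 encoder_depth = 2, base_channels = 2,
                                 batch_size = 2, seed = 2))
  td <- tidy(fit$history)
  expect_setequal(unique(td$metric), c("train_loss", "val_loss", "val_dice"))
  gl <- glance(fit$history)
  expect_equal(gl$epochs, 2)
  expect_s3_class(autoplot(fit$history), "ggplot")
})
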
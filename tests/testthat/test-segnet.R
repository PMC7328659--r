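test_that("the 400-image split reproduces 320 train / 80 validation", {
  s <- split_dataset(400, 0.2, seed = 1)
  expect_length(s$train, 320)
  expect_length(s$val, 80)
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), 1:400)
})

test_that("splits are deterministic per seed and exhaustive", {
  s1 <- split_dataset(10, 0.2, seed = 3)
  expect_length(s1$train, 8)
  expect_length(s1$val, 2)
  expect_identical(split_dataset(10, 0.2, seed = 3), s1)
  p1 <- split_dataset(100, 0.2, seed = 1)
  p2 <- split_dataset(100, 0.2, seed = 2)
  expect_false(identical(p1, p2))
  expect_error(split_dataset(5, 0.01), "validation size")
  expect_error(split_dataset(1, 0.5), "at least 2")
})

test_that("prepare_sample center-crops to the short side then resizes", {
  img <- random_rgb(910, 680)
  mask <- random_mask(910, 680)
  out <- prepare_sample(img, mask, 256)
  expect_equal(dim(out$image), c(256L, 256L, 3L))
  expect_equal(dim(out$mask), c(256L, 256L))
  expect_true(is_binary_mask(out$mask))

  # a centered block in a square mask stays centered
  sq <- matrix(0L, 100, 100)
  sq[41:60, 41:60] <- 255L
  out2 <- prepare_sample(random_rgb(100, 100), sq, 50)
  expect_true(all(out2$mask[21:30, 21:30] == 255L))
  expect_true(all(out2$mask[1:10, ] == 0L))

  expect_error(prepare_sample(img, random_mask(10, 10)), "differ")
})

test_that("prepared masks stay binary across random geometries", {
  withr::local_seed(31)
  for (i in 1:50) {
    h <- sample(40:160, 1); w <- sample(40:160, 1)
    out <- prepare_sample(random_rgb(h, w), random_mask(h, w), 32)
    expect_true(is_binary_mask(out$mask))
  }
})

test_that("zeroed augmentation probabilities give the identity", {
  img <- random_rgb(64, 64)
  mask <- random_mask(64, 64)
  cfg <- augment_config(hflip_prob = 0, transform_prob = 0)
  out <- augment_pair(img, mask, cfg)
  expect_identical(out$image, img)
  expect_identical(out$mask, mask)
})

test_that("horizontal flip is an involution", {
  img <- random_rgb(32, 48)
  expect_identical(flip_horizontal(flip_horizontal(img)), img)
  m <- random_mask(32, 48)
  expect_identical(flip_horizontal(flip_horizontal(m)), m)
})

test_that("augmentation applies the identical geometry to image and mask", {
  withr::local_seed(19)
  img <- random_rgb(64, 64)
  mask <- random_mask(64, 64, p = 0.3)
  cfg <- augment_config()
  for (i in 1:50) {
    out <- augment_pair(img, mask, cfg)
    expect_true(is_binary_mask(out$mask))
    replay <- rebinarize(apply_augment_geometry(mask, out$params,
                                                method = "nearest"))
    expect_equal(dice(out$mask, replay), 1.0)
  }
})

test_that("the one-cycle schedule hits its endpoints and peak", {
  cfg <- train_config(lr_max = 1e-2, image_size = 64, encoder_depth = 3)
  total <- 100
  oc <- cfg$one_cycle
  expect_equal(one_cycle_lr(0, total, cfg), cfg$lr_max / oc$div_factor)
  w <- round(oc$warmup_fraction * total)
  expect_equal(one_cycle_lr(w, total, cfg), cfg$lr_max)
  expect_equal(one_cycle_lr(total - 1, total, cfg),
               cfg$lr_max / oc$final_div_factor, tolerance = 1e-9)
  lrs <- one_cycle_lr(0:(total - 1), total, cfg)
  expect_equal(which.max(lrs) - 1, w)
  expect_error(one_cycle_lr(total, total, cfg), "step")
  expect_error(one_cycle_lr(-1, total, cfg), "step")
})

test_that("model building is seeded and shape-stable at depths 3 and 4", {
  for (d in c(3, 4)) {
    cfg <- train_config(image_size = 64, encoder_depth = d,
                        base_channels = 4, seed = 5)
    m1 <- build_segnet(cfg)
    m2 <- build_segnet(cfg)
    expect_identical(m1$params, m2$params)
    expect_gt(m1$n_params, 0)
    z <- fernmask:::segnet_forward(m1, matrix(0, 64 * 64, 3))$z
    expect_equal(dim(z), c(64L * 64L, 1L))
    expect_true(all(is.finite(z)))
  }
  expect_error(train_config(image_size = 100, encoder_depth = 3),
               "divisible")
})

test_that("predict_mask always returns a binary size x size raster", {
  cfg <- train_config(image_size = 64, encoder_depth = 3, base_channels = 4,
                      seed = 2)
  model <- build_segnet(cfg)
  withr::local_seed(23)
  geoms <- list(c(910, 680), c(500, 500), c(64, 64), c(100, 300))
  for (i in 1:6) geoms[[4 + i]] <- c(sample(70:200, 1), sample(70:200, 1))
  for (g in geoms) {
    out <- predict_mask(model, random_rgb(g[1], g[2]))
    expect_equal(dim(out), c(64L, 64L))
    expect_true(is_binary_mask(out))
  }
  img <- random_rgb(90, 120)
  expect_identical(predict_mask(model, img), predict_mask(model, img))
})

test_that("a short training run reduces the loss and logs a full history", {
  sheets <- lapply(1:20, function(i) small_sheet(i))
  cfg <- train_config(image_size = 64, epochs = 2, encoder_depth = 3,
                      base_channels = 4, batch_size = 4, seed = 7)
  fit <- fit_segnet(NULL, sheets, cfg)
  h <- fit$history$epochs
  expect_equal(nrow(h), 2)
  expect_lt(h$train_loss[2], h$train_loss[1])
  # the recorded learning-rate trace is exactly the one-cycle schedule
  total <- nrow(fit$history$lr)
  expect_equal(fit$history$lr$lr, one_cycle_lr(0:(total - 1), total, cfg))
  # determinism of the whole run
  fit2 <- fit_segnet(NULL, sheets, cfg)
  expect_identical(fit$model$params, fit2$model$params)
})

test_that("all-background targets drive predictions to empty masks", {
  withr::local_seed(3)
  sheets <- lapply(1:8, function(i) {
    img <- array(as.integer(pmin(pmax(round(rnorm(32 * 32 * 3, 200, 12)), 0), 255)),
                 dim = c(32, 32, 3))
    list(image = img, mask = matrix(0L, 32, 32))
  })
  cfg <- train_config(image_size = 32, epochs = 50, lr_max = 0.05,
                      encoder_depth = 2, base_channels = 4, batch_size = 4,
                      seed = 9)
  fit <- fit_segnet(NULL, sheets, cfg,
                    aug = augment_config(hflip_prob = 0, transform_prob = 0))
  pred <- predict_mask(fit$model, sheets[[1]]$image)
  expect_gte(pixel_accuracy(pred, matrix(0L, 32, 32)), 0.99)
})

test_that("checkpoints are self-describing and restore predictions exactly", {
  cfg <- train_config(image_size = 64, encoder_depth = 3, base_channels = 4,
                      seed = 4)
  model <- build_segnet(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$arch$depth, 3)
  restored <- load_checkpoint(path)
  img <- random_rgb(80, 80)
  expect_identical(predict_mask(restored, img), predict_mask(model, img))
  expect_error(load_checkpoint("nope.rds"), "not found")
})
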
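#' Training configuration
#'
#' Data-handling and optimization settings for the segmentation network.
#' Defaults mirror the published training recipe: 256 x 256 inputs, an
#' 80/20 train/validation split, 22 epochs under the one-cycle
#' learning-rate policy. The one-cycle internals (warmup fraction 0.3,
#' div factor 25, final div factor 2.5e4) and the optimizer settings are
#' documented package choices — the recipe names the policy but not its
#' constants.
#'
#' @param image_size Square input side in pixels (default 256); must be
#'   at least 32 and divisible by `2^encoder_depth`.
#' @param val_fraction Fraction of images held out for validation (default 0.2).
#' @param epochs Training epochs (default 22).
#' @param lr_max Peak learning rate of the one-cycle schedule (default 5e-3).
#' @param one_cycle List with `warmup_fraction`, `div_factor`,
#'   `final_div_factor`.
#' @param batch_size Minibatch size (default 8).
#' @param encoder_depth Number of stride-2 downsampling stages (default 4).
#' @param base_channels Channels of the first encoder stage; doubled at
#'   each downsampling (default 8).
#' @param loss `"bce"` (per-pixel binary cross-entropy, default) or
#'   `"dice"` (soft-Dice).
#' @param seed Root RNG seed governing split, initialization and
#'   augmentation draws (derived streams per consumer).
#' @return An object of class `train_config`.
#' @export
train_config <- function(image_size = 256, val_fraction = 0.2, epochs = 22,
                         lr_max = 5e-3,
                         one_cycle = list(warmup_fraction = 0.3,
                                          div_factor = 25,
                                          final_div_factor = 2.5e4),
                         batch_size = 8, encoder_depth = 4,
                         base_channels = 8, loss = c("bce", "dice"),
                         seed = 1) {
  loss <- match.arg(loss)
  if (image_size < 32 || image_size %% (2^encoder_depth) != 0) {
    stop(sprintf(
      "image_size must be >= 32 and divisible by 2^encoder_depth (= %d)",
      2^encoder_depth), call. = FALSE)
  }
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(image_size = as.integer(image_size),
                 val_fraction = val_fraction, epochs = as.integer(epochs),
                 lr_max = lr_max, one_cycle = one_cycle,
                 batch_size = as.integer(batch_size),
                 encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 loss = loss, seed = as.integer(seed)),
            class = "train_config")
}

derive_seed <- function(seed, purpose) {
  offset <- c(split = 101L, init = 211L, train = 307L, dataset = 401L,
              eval = 503L)[[purpose]]
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

#' Deterministic train/validation split
#'
#' Seeded shuffle of `1:n`; the validation set takes `round(n * val_fraction)`
#' indices, the training set the rest. With the published 400-image set and
#' `val_fraction = 0.2` this yields 320 training and 80 validation images.
#'
#' @param n Number of samples (`>= 2`).
#' @param val_fraction Held-out fraction, strictly in (0, 1).
#' @param seed RNG seed; the same seed always yields the same split.
#' @return List with integer vectors `train` and `val` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(n, val_fraction = 0.2, seed = 1) {
  if (n < 2) stop("need at least 2 samples to split", call. = FALSE)
  n_val <- round(n * val_fraction)
  if (n_val < 1 || n_val >= n) {
    stop(sprintf("val_fraction %.3f gives a validation size of %d (need 1..%d)",
                 val_fraction, n_val, n - 1), call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  list(val = sort(perm[seq_len(n_val)]), train = sort(perm[-seq_len(n_val)]))
}

#' One-cycle learning-rate schedule
#'
#' Cosine warmup from `lr_max / div_factor` to `lr_max` over
#' `warmup_fraction` of the run, then cosine annealing down to
#' `lr_max / final_div_factor`: continuous with a single interior maximum.
#'
#' @param step 0-based step index (vectorized), `0 <= step < total_steps`.
#' @param total_steps Total optimizer steps in the run.
#' @param cfg A [train_config()] (or any list with `lr_max` and `one_cycle`).
#' @return Learning rate(s).
#' @export
one_cycle_lr <- function(step, total_steps, cfg) {
  if (any(step < 0 | step >= total_steps)) {
    stop("step must satisfy 0 <= step < total_steps", call. = FALSE)
  }
  oc <- cfg$one_cycle
  lr0 <- cfg$lr_max / oc$div_factor
  lr_end <- cfg$lr_max / oc$final_div_factor
  w <- max(1, round(oc$warmup_fraction * total_steps))
  up <- function(s) lr0 + (cfg$lr_max - lr0) * (1 - cos(pi * s / w)) / 2
  dn <- function(s) {
    t <- if (total_steps - 1 > w) (s - w) / (total_steps - 1 - w) else 1
    lr_end + (cfg$lr_max - lr_end) * (1 + cos(pi * t)) / 2
  }
  ifelse(step <= w, up(step), dn(step))
}

# --- model ------------------------------------------------------------------

#' Build the encoder-decoder segmentation network
#'
#' A U-Net-style fully convolutional network: a stem 3x3 convolution,
#' `encoder_depth` stride-2 downsampling stages that double the channel
#' count, a mirrored decoder of nearest-neighbor x2 upsampling stages with
#' skip concatenation at each resolution, and a final 1x1 convolution to a
#' one-channel per-pixel score map the same size as the input. Weights are
#' He-initialized from the seeded RNG stream, so two builds from the same
#' config are identical; loading external pretrained encoder weights is not
#' required by any part of the workflow.
#'
#' @param cfg A [train_config()].
#' @return An object of class `fern_segnet`.
#' @export
build_segnet <- function(cfg) {
  stopifnot(inherits(cfg, "train_config"))
  d <- cfg$encoder_depth; cbase <- cfg$base_channels
  params <- withr::with_seed(derive_seed(cfg$seed, "init"), {
    p <- list(
      stem = list(w = he_init(9L * 3L, cbase), b = numeric(cbase)),
      down = vector("list", d), up = vector("list", d),
      head = list(w = he_init(cbase, 1L), b = numeric(1L))
    )
    for (i in seq_len(d)) {
      cin <- cbase * 2^(i - 1L); cout <- cbase * 2^i
      p$down[[i]] <- list(w = he_init(9L * cin, cout), b = numeric(cout))
    }
    for (i in seq_len(d)) {
      cin <- cbase * 2^i + cbase * 2^(i - 1L)   # upsampled + skip
      cout <- cbase * 2^(i - 1L)
      p$up[[i]] <- list(w = he_init(9L * cin, cout), b = numeric(cout))
    }
    p
  })
  n_par <- sum(unlist(rapply(params, length, how = "unlist")))
  structure(list(params = params, cfg = cfg,
                 arch = list(depth = d, base_channels = cbase,
                             image_size = cfg$image_size),
                 n_params = n_par),
            class = "fern_segnet")
}

#' @export
print.fern_segnet <- function(x, ...) {
  cat(sprintf(
    "Encoder-decoder segmentation network: depth %d, base channels %d, %d x %d input, %s parameters\n",
    x$arch$depth, x$arch$base_channels, x$arch$image_size,
    x$arch$image_size, format(x$n_params, big.mark = ",")))
  invisible(x)
}

# sides at each resolution level 0..d
net_sides <- function(model) {
  model$arch$image_size / 2^(0:model$arch$depth)
}

# forward pass; x is (size^2, 3) in [0, 1]. keep = TRUE retains the caches
# needed for the backward pass.
segnet_forward <- function(model, x, keep = FALSE) {
  d <- model$arch$depth
  s <- net_sides(model)
  p <- model$params
  cache <- list(acts = vector("list", d + 1L), p_stem = NULL,
                p_down = vector("list", d), p_up = vector("list", d),
                cats = vector("list", d))
  g0 <- conv_geom(s[1], s[1], 3L, 1L)
  cv <- conv_fwd(x, p$stem$w, p$stem$b, g0)
  a <- relu_fwd(cv$out)
  if (keep) { cache$p_stem <- cv$p; cache$acts[[1]] <- a }
  enc <- vector("list", d + 1L)
  enc[[1]] <- a
  for (i in seq_len(d)) {
    gi <- conv_geom(s[i], s[i], 3L, 2L)
    cv <- conv_fwd(enc[[i]], p$down[[i]]$w, p$down[[i]]$b, gi)
    enc[[i + 1L]] <- relu_fwd(cv$out)
    if (keep) { cache$p_down[[i]] <- cv$p; cache$acts[[i + 1L]] <- enc[[i + 1L]] }
  }
  u <- enc[[d + 1L]]
  dec <- vector("list", d)
  for (i in rev(seq_len(d))) {
    upx <- upsample2_fwd(u, s[i + 1L], s[i + 1L])
    cat_ <- cbind(upx, enc[[i]])
    gi <- conv_geom(s[i], s[i], 3L, 1L)
    cv <- conv_fwd(cat_, p$up[[i]]$w, p$up[[i]]$b, gi)
    u <- relu_fwd(cv$out)
    if (keep) { cache$p_up[[i]] <- cv$p; cache$cats[[i]] <- cat_; dec[[i]] <- u }
  }
  gh <- conv_geom(s[1], s[1], 1L, 1L)
  z <- conv_fwd(u, p$head$w, p$head$b, gh)$out
  if (keep) { cache$dec <- dec; cache$enc <- enc }
  list(z = z, cache = if (keep) cache else NULL)
}

relu_bwd_from_act <- function(grad, act) {
  grad[act <= 0] <- 0
  grad
}

segnet_backward <- function(model, cache, dz) {
  d <- model$arch$depth
  s <- net_sides(model)
  p <- model$params
  cb <- model$arch$base_channels
  grads <- grads_zero_like(p)
  gh <- conv_geom(s[1], s[1], 1L, 1L)
  bw <- conv_bwd(dz, cache$dec[[1]], p$head$w, gh, cin = cb, need_dx = TRUE)
  grads$head$w <- bw$dw; grads$head$b <- bw$db
  du <- bw$dx
  denc <- vector("list", d + 1L)   # gradients flowing into encoder acts
  for (i in seq_len(d)) {
    du <- relu_bwd_from_act(du, cache$dec[[i]])
    gi <- conv_geom(s[i], s[i], 3L, 1L)
    cin <- cb * 2^i + cb * 2^(i - 1L)
    bw <- conv_bwd(du, cache$p_up[[i]], p$up[[i]]$w, gi, cin = cin,
                   need_dx = TRUE)
    grads$up[[i]]$w <- bw$dw; grads$up[[i]]$b <- bw$db
    c_up <- cb * 2^i
    d_upx <- bw$dx[, seq_len(c_up), drop = FALSE]
    denc[[i]] <- bw$dx[, -seq_len(c_up), drop = FALSE]
    du <- upsample2_bwd(d_upx, s[i + 1L], s[i + 1L])
  }
  denc[[d + 1L]] <- du   # gradient into the bottleneck activation
  dcur <- denc[[d + 1L]]
  for (i in rev(seq_len(d))) {
    dcur <- relu_bwd_from_act(dcur, cache$acts[[i + 1L]])
    gi <- conv_geom(s[i], s[i], 3L, 2L)
    cin <- cb * 2^(i - 1L)
    bw <- conv_bwd(dcur, cache$p_down[[i]], p$down[[i]]$w, gi, cin = cin,
                   need_dx = TRUE)
    grads$down[[i]]$w <- bw$dw; grads$down[[i]]$b <- bw$db
    dcur <- bw$dx + denc[[i]]
  }
  dcur <- relu_bwd_from_act(dcur, cache$acts[[1]])
  g0 <- conv_geom(s[1], s[1], 3L, 1L)
  bw <- conv_bwd(dcur, cache$p_stem, p$stem$w, g0, cin = 3L, need_dx = FALSE)
  grads$stem$w <- bw$dw; grads$stem$b <- bw$db
  grads
}

# network input layout: (H*W, 3) matrix, per-image per-channel
# standardization (zero mean, unit variance). Without it the all-positive,
# bright-sheet-dominated inputs condition the loss surface so badly that
# the net collapses to the background class.
flatten_image <- function(img) {
  d <- dim(img)
  x <- matrix(as.numeric(img) / 255, d[1] * d[2], 3L)
  for (ch in 1:3) {
    mu <- mean(x[, ch]); sg <- stats::sd(x[, ch])
    x[, ch] <- (x[, ch] - mu) / max(sg, 1e-4)
  }
  x
}

loss_fns <- function(loss) {
  if (loss == "dice") list(f = dice_loss, g = dice_loss_grad)
  else list(f = bce_with_logits, g = bce_with_logits_grad)
}

#' Train the segmentation network
#'
#' Optimizes the per-pixel loss on (image, mask) pairs with Adam under the
#' one-cycle learning-rate schedule. Samples are passed through the
#' crop/resize geometry of [prepare_sample()] once, then augmented afresh
#' each epoch with [augment_pair()]. The run is deterministic for a fixed
#' `cfg$seed` (one root seed, derived streams for split, initialization and
#' augmentation) up to floating-point reduction order.
#'
#' @param model A [build_segnet()] model, or `NULL` to build one from `cfg`.
#' @param dataset A list of samples, each a list with `image` (RGB array)
#'   and `mask` (binary matrix of the same height/width).
#' @param cfg A [train_config()].
#' @param aug An [augment_config()]; pass
#'   `augment_config(hflip_prob = 0, transform_prob = 0)` to disable
#'   augmentation.
#' @param verbose Print a one-line summary per epoch.
#' @return List with `model` (trained) and `history` (class
#'   `segnet_history`: per-epoch training loss, validation loss and
#'   validation Dice, plus the per-step learning-rate trace).
#' @export
fit_segnet <- function(model = NULL, dataset, cfg, aug = augment_config(),
                       verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (length(dataset) < 2) stop("dataset must contain at least 2 samples",
                                call. = FALSE)
  if (is.null(model)) model <- build_segnet(cfg)
  if (model$arch$image_size != cfg$image_size) {
    stop("model and config disagree on image_size", call. = FALSE)
  }
  size <- cfg$image_size
  prepped <- lapply(dataset, function(s) {
    pr <- prepare_sample(s$image, s$mask, size)
    list(image = pr$image, mask = pr$mask)
  })
  split <- split_dataset(length(dataset), cfg$val_fraction,
                         derive_seed(cfg$seed, "split"))
  tr <- split$train; va <- split$val
  if (length(tr) == 0 || length(va) == 0) {
    stop("empty train or validation partition", call. = FALSE)
  }
  lfn <- loss_fns(cfg$loss)
  n_batches <- ceiling(length(tr) / cfg$batch_size)
  total_steps <- cfg$epochs * n_batches
  state <- adam_init(model$params)
  lr_trace <- numeric(total_steps)
  hist <- vector("list", cfg$epochs)
  step <- 0L
  withr::with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$epochs)) {
      order_ <- sample(tr)
      batch_losses <- numeric(n_batches)
      for (b in seq_len(n_batches)) {
        ids <- order_[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size,
                                                           length(tr))]
        acc <- grads_zero_like(model$params)
        bl <- 0
        for (id in ids) {
          s <- prepped[[id]]
          agu <- augment_pair(s$image, s$mask, aug)
          x <- flatten_image(agu$image)
          y <- as.numeric(agu$mask) / 255
          fw <- segnet_forward(model, x, keep = TRUE)
          bl <- bl + lfn$f(fw$z, y)
          dz <- matrix(lfn$g(fw$z, y), ncol = 1L)
          acc <- grads_add(acc, segnet_backward(model, fw$cache, dz))
        }
        acc <- grads_scale(acc, 1 / length(ids))
        batch_losses[b] <- bl / length(ids)
        lr <- one_cycle_lr(step, total_steps, cfg)
        step <- step + 1L
        lr_trace[step] <- lr
        upd <- adam_step(model$params, acc, state, lr, t = step)
        model$params <- upd$p
        state <- upd$s
      }
      val <- evaluate_prepped(model, prepped[va], lfn)
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(batch_losses),
        val_loss = val$loss, val_dice = val$dice
      )
      if (verbose) {
        message(sprintf("epoch %2d  train loss %.4f  val loss %.4f  val dice %.4f",
                        epoch, mean(batch_losses), val$loss, val$dice))
      }
    }
  })
  history <- structure(list(
    epochs = dplyr::bind_rows(hist),
    lr = tibble::tibble(step = seq_len(total_steps) - 1L, lr = lr_trace),
    split = split
  ), class = "segnet_history")
  list(model = model, history = history)
}

# mean loss and mean Dice over already-prepared samples
evaluate_prepped <- function(model, samples, lfn) {
  losses <- numeric(length(samples))
  dices <- numeric(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    x <- flatten_image(s$image)
    y <- as.numeric(s$mask) / 255
    z <- segnet_forward(model, x)$z
    losses[i] <- lfn$f(z, y)
    pred <- matrix(0L, nrow(s$mask), ncol(s$mask))
    pred[matrix(z > 0, nrow(s$mask))] <- 255L
    dices[i] <- dice(pred, s$mask)
  }
  list(loss = mean(losses), dice = mean(dices))
}

#' Predict a binary mask for an image
#'
#' Applies the same center-crop/resize geometry as training, runs the
#' network, and thresholds the per-pixel score at probability 0.5. The
#' output is always `image_size x image_size` regardless of the input
#' geometry.
#'
#' @param model A `fern_segnet`.
#' @param img An RGB raster array of any size.
#' @return A binary mask matrix of side `model$cfg$image_size`.
#' @export
predict_mask <- function(model, img) {
  stopifnot(inherits(model, "fern_segnet"))
  size <- model$arch$image_size
  pr <- prepare_sample(img, NULL, size)
  z <- segnet_forward(model, flatten_image(pr$image))$z
  out <- matrix(0L, size, size)
  out[matrix(z > 0, size)] <- 255L
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single serialized parameter file plus a JSON sidecar
#' (`<path>.json`) carrying the full training and architecture
#' configuration, so a checkpoint is self-describing.
#'
#' @param model A `fern_segnet`.
#' @param path Checkpoint file path.
#' @return `path` invisibly (`save_checkpoint`); the model
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fern_segnet"))
  saveRDS(list(params = model$params, cfg = unclass(model$cfg),
               arch = model$arch, n_params = model$n_params), path)
  jsonlite::write_json(list(config = unclass(model$cfg), arch = model$arch,
                            n_params = model$n_params),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("checkpoint not found: '%s'", path), call. = FALSE)
  }
  raw <- readRDS(path)
  structure(list(params = raw$params,
                 cfg = structure(raw$cfg, class = "train_config"),
                 arch = raw$arch, n_params = raw$n_params),
            class = "fern_segnet")
}
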
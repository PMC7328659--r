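# Seeded generator of synthetic digitized herbarium sheets with
# pixel-perfect ground truth. The scenes emulate the visual structure and
# noise sources of real sheet photographs — an off-white aging mounting
# sheet, a dark frond silhouette with complex margins, a specimen label,
# a color bar, a ruler, a barcode, stamp marks and dust/stain debris —
# so that every pipeline stage is testable without downloading data.
#
# Painting goes through a mutable canvas environment (three channel
# planes + plant/element index sets) so that drawing hundreds of strokes
# never copies the full raster.

#' Synthetic sheet configuration
#'
#' Defaults produce a 910 x 680 sheet (a 1/10-scale herbarium sheet,
#' aspect ratio preserved so the square-crop path is exercised) with three
#' fronds of branching pinnae, all non-plant elements enabled, and a
#' moderate debris load. The plant and sheet color ranges are disjoint in
#' luma by at least `luma_margin` gray levels, which guarantees Otsu
#' separability on clean scenes; a config violating that margin errors.
#' Plant limbs are blade-like (roughly 8-26 px wide at the default scale)
#' while dark element strokes (barcode bars, ruler ticks, label text,
#' stamp ring) are at most 2 px, so a 5 x 5 despeckle removes the latter
#' but preserves the silhouette, and the silhouette survives the 5x
#' downscaling of the network's crop/resize path.
#'
#' @param height,width Sheet size in pixels (each `>= 64`).
#' @param sheet_color Off-white base RGB of the mounting paper.
#' @param sheet_noise Per-pixel Gaussian noise amplitude on the paper.
#' @param yellowing Aging-gradient strength in `[0, 1]` (reduces blue/green
#'   toward the sheet edges).
#' @param plant_color_low,plant_color_high Dark green/brown RGB interval
#'   the plant tissue is drawn from.
#' @param luma_margin Required luma gap (gray levels) between the darkest
#'   sheet pixel and the brightest plant pixel.
#' @param frond_count Number of fronds.
#' @param pinna_pairs Pinna pairs per frond.
#' @param branch_depth 1 = pinnae only; `>= 2` adds second-order pinnules.
#' @param elements Named logical flags: `label`, `color_bar`, `ruler`,
#'   `barcode`, `stamp`, `debris`.
#' @param debris_density Debris specks per megapixel.
#' @param seed RNG seed; generation is fully deterministic per seed.
#' @return An object of class `sheet_config`.
#' @export
sheet_config <- function(height = 910, width = 680,
                         sheet_color = c(245, 242, 228), sheet_noise = 4,
                         yellowing = 0.25,
                         plant_color_low = c(45, 60, 30),
                         plant_color_high = c(85, 105, 60),
                         luma_margin = 40,
                         frond_count = 3, pinna_pairs = 12, branch_depth = 2,
                         elements = c(label = TRUE, color_bar = TRUE,
                                      ruler = TRUE, barcode = TRUE,
                                      stamp = TRUE, debris = TRUE),
                         debris_density = 250, seed = 1) {
  if (height < 64 || width < 64) {
    stop("sheet dimensions must be at least 64 x 64", call. = FALSE)
  }
  cfg <- structure(list(
    height = as.integer(height), width = as.integer(width),
    sheet_color = sheet_color, sheet_noise = sheet_noise,
    yellowing = yellowing,
    plant_color_low = plant_color_low, plant_color_high = plant_color_high,
    luma_margin = luma_margin,
    frond_count = as.integer(frond_count),
    pinna_pairs = as.integer(pinna_pairs),
    branch_depth = as.integer(branch_depth),
    elements = elements, debris_density = debris_density,
    seed = as.integer(seed)
  ), class = "sheet_config")
  luma <- function(rgb) sum(c(0.299, 0.587, 0.114) * rgb)
  sheet_min <- luma(sheet_color) - 4 * sheet_noise - 45 * yellowing
  plant_max <- luma(plant_color_high) + 12   # + per-pixel jitter headroom
  if (sheet_min - plant_max < luma_margin) {
    stop(sprintf(
      "plant and sheet luma ranges are separated by %.0f < margin %.0f gray levels",
      sheet_min - plant_max, luma_margin), call. = FALSE)
  }
  cfg
}

# invented taxonomy: exercises family-level grouping without implying any
# real specimen data
fake_taxonomy <- function() {
  list(
    families = c("Plumofilicaceae", "Umbrapteridaceae", "Virgulifrondaceae",
                 "Nanofoliaceae", "Crassipinnaceae", "Arcuatifiliceae",
                 "Sparsipinnulaceae", "Latifrondaceae"),
    genera = c("Plumofilix", "Umbrapteris", "Virgulifrons", "Nanofolium",
               "Crassipinna", "Arcuatifilix", "Sparsipinnula", "Latifrons"),
    epithets = c("angusta", "communis", "decipiens", "elegans", "gracilis",
                 "humilis", "insularis", "maculata", "nitida", "obscura",
                 "pallida", "recurva", "scandens", "tenuis", "vulgaris")
  )
}

# linear pixel indices of a thick, linearly tapered segment
segment_indices <- function(h, w, x0, y0, x1, y1, w0, w1) {
  rmax <- max(w0, w1) / 2 + 1
  cmin <- max(1L, floor(min(x0, x1) - rmax))
  cmax <- min(w, ceiling(max(x0, x1) + rmax))
  rmin <- max(1L, floor(min(y0, y1) - rmax))
  rmax2 <- min(h, ceiling(max(y0, y1) + rmax))
  if (cmin > cmax || rmin > rmax2) return(integer(0))
  cs <- cmin:cmax; rs <- rmin:rmax2
  px <- rep(cs, each = length(rs)); py <- rep.int(rs, length(cs))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx * dx + dy * dy
  t <- if (len2 == 0) numeric(length(px)) else
    pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
  qx <- x0 + t * dx; qy <- y0 + t * dy
  d2 <- (px - qx)^2 + (py - qy)^2
  half <- (w0 + (w1 - w0) * t) / 2
  hit <- d2 <= half^2
  (px[hit] - 1L) * h + py[hit]
}

# linear indices of one frond (rachis + tapered pinnae + optional pinnules).
# Fronds are mounted side by side in horizontal bands, as collectors lay
# multiple fronds on one sheet; this also keeps silhouettes from crossing.
frond_indices <- function(h, w, cfg, scale, band = c(0.25, 0.75)) {
  idx <- vector("list", 256L); ni <- 0L
  add <- function(v) { ni <<- ni + 1L; idx[[ni]] <<- v }
  x <- runif(1, band[1] * w, band[2] * w)
  y <- runif(1, 0.70 * h, 0.92 * h)
  ang <- -pi / 2 + runif(1, -0.25, 0.25)    # mostly upward
  len <- runif(1, 0.50, 0.72) * min(h, w)
  nseg <- 22L
  step <- len / nseg
  pts <- matrix(0, nseg + 1L, 2L)
  pts[1, ] <- c(x, y)
  angs <- numeric(nseg)
  for (i in seq_len(nseg)) {
    ang <- ang + rnorm(1, 0, 0.05)
    angs[i] <- ang
    pts[i + 1L, ] <- pts[i, ] + step * c(cos(ang), sin(ang))
  }
  rachis_w0 <- 14 * scale; rachis_w1 <- 9 * scale
  for (i in seq_len(nseg)) {
    ww <- rachis_w0 + (rachis_w1 - rachis_w0) * (i - 1) / nseg
    add(segment_indices(h, w, pts[i, 1], pts[i, 2],
                        pts[i + 1L, 1], pts[i + 1L, 2], ww, ww))
  }
  n_pairs <- cfg$pinna_pairs
  attach_t <- seq(0.15, 0.97, length.out = 2L * n_pairs)
  pinna_max <- 0.24 * len
  for (j in seq_len(2L * n_pairs)) {
    ti <- attach_t[j]
    seg <- pmin(pmax(ceiling(ti * nseg), 1L), nseg)
    base <- pts[seg, ] + (ti * nseg - (seg - 1)) * (pts[seg + 1L, ] - pts[seg, ])
    local_ang <- angs[seg]
    plen <- pinna_max * (1 - 0.78 * ti) * runif(1, 0.85, 1.1)
    for (s in if (j %% 2 == 0) 1 else -1) {          # alternate sides
      pang <- local_ang + s * runif(1, 1.05, 1.35)   # ~60-77 deg off rachis
      tip <- base + plen * c(cos(pang), sin(pang))
      add(segment_indices(h, w, base[1], base[2], tip[1], tip[2],
                          26 * scale, 8 * scale))
      if (cfg$branch_depth >= 2L && plen > 16 * scale) {
        n_pnl <- max(2L, floor(plen / (14 * scale)))
        gap_same_side <- 2 * 0.82 * len / (2 * n_pairs - 1)
        for (q in seq_len(n_pnl)) {
          tq <- q / (n_pnl + 1)
          pb <- base + tq * (tip - base)
          # pinnules are stubby marginal teeth, kept well short of the
          # neighboring pinna so silhouette gaps stay wider than the
          # despeckle window
          qlen <- min(0.28 * plen * (1 - 0.6 * tq), 0.35 * gap_same_side)
          ss <- if (q %% 2 == 0) 1 else -1     # alternate sides
          qang <- pang + ss * runif(1, 1.35, 1.55)  # near-perpendicular
          qt <- pb + qlen * c(cos(qang), sin(qang))
          add(segment_indices(h, w, pb[1], pb[2], qt[1], qt[2],
                              12 * scale, 8 * scale))
        }
      }
    }
  }
  unique(unlist(idx[seq_len(ni)]))
}

# mutable canvas: channel planes + element index accumulator
new_canvas <- function(r, g, b) {
  cv <- new.env(parent = emptyenv())
  cv$r <- r; cv$g <- g; cv$b <- b
  cv$h <- nrow(r); cv$w <- ncol(r)
  cv$element_idx <- list()
  cv
}

canvas_paint <- function(cv, idx, rgb, element = TRUE) {
  if (length(idx) == 0) return(invisible(cv))
  cv$r[idx] <- rgb[1]; cv$g[idx] <- rgb[2]; cv$b[idx] <- rgb[3]
  if (element) cv$element_idx[[length(cv$element_idx) + 1L]] <- idx
  invisible(cv)
}

rect_indices <- function(cv, r0, r1, c0, c1) {
  r0 <- max(1L, round(r0)); r1 <- min(cv$h, round(r1))
  c0 <- max(1L, round(c0)); c1 <- min(cv$w, round(c1))
  if (r0 > r1 || c0 > c1) return(integer(0))
  as.vector(outer(r0:r1, (c0:c1 - 1L) * cv$h, `+`))
}

# non-plant elements: label box, color bar, ruler, barcode, stamp.
# Light fills pollute nothing (they stay above the Otsu threshold); dark
# strokes are kept <= 2 px so the despeckle stage can remove them.
draw_elements <- function(cv, cfg) {
  h <- cv$h; w <- cv$w
  el <- cfg$elements
  dark <- c(40, 40, 45)
  if (isTRUE(el[["label"]])) {
    lw <- round(0.30 * w); lh <- round(0.16 * h)
    c0 <- w - lw - round(0.03 * w); r0 <- h - lh - round(0.03 * h)
    canvas_paint(cv, rect_indices(cv, r0, r0 + lh, c0, c0 + lw), c(252, 250, 242))
    canvas_paint(cv, rect_indices(cv, r0, r0 + lh, c0, c0 + 1L), dark)
    canvas_paint(cv, rect_indices(cv, r0, r0 + lh, c0 + lw - 1L, c0 + lw), dark)
    canvas_paint(cv, rect_indices(cv, r0, r0 + 1L, c0, c0 + lw), dark)
    canvas_paint(cv, rect_indices(cv, r0 + lh - 1L, r0 + lh, c0, c0 + lw), dark)
    n_lines <- sample(3:5, 1)
    for (i in seq_len(n_lines)) {
      lr <- r0 + round(lh * (0.2 + 0.6 * (i - 1) / max(1, n_lines - 1)))
      llen <- round(lw * runif(1, 0.4, 0.8))
      canvas_paint(cv, rect_indices(cv, lr, lr + 1L, c0 + 8L, c0 + 8L + llen), dark)
    }
  }
  if (isTRUE(el[["color_bar"]])) {
    pal <- rbind(c(235, 180, 180), c(235, 215, 170), c(225, 235, 175),
                 c(180, 230, 190), c(175, 220, 235), c(185, 190, 235),
                 c(225, 185, 230), c(230, 230, 230))
    sq <- max(10L, round(0.03 * h)); c0 <- round(0.25 * w); r0 <- round(0.015 * h)
    for (i in seq_len(nrow(pal))) {
      cc0 <- c0 + (i - 1L) * (sq + 2L)
      canvas_paint(cv, rect_indices(cv, r0, r0 + sq, cc0, cc0 + sq), pal[i, ])
      canvas_paint(cv, rect_indices(cv, r0, r0 + sq, cc0 + sq, cc0 + sq + 1L),
                   c(70, 70, 70))
    }
  }
  if (isTRUE(el[["ruler"]])) {
    rw <- max(9L, round(0.018 * w)); c0 <- round(0.012 * w)
    canvas_paint(cv, rect_indices(cv, 0.05 * h, 0.95 * h, c0, c0 + rw),
                 c(232, 230, 224))
    for (r in seq(round(0.05 * h), round(0.95 * h), by = max(6L, round(h / 90)))) {
      canvas_paint(cv, rect_indices(cv, r, r + 1L, c0, c0 + round(rw * 0.6)),
                   c(30, 30, 30))
    }
  }
  if (isTRUE(el[["barcode"]])) {
    bw <- round(0.13 * w); bh <- round(0.045 * h)
    c0 <- w - bw - round(0.03 * w); r0 <- round(0.02 * h)
    canvas_paint(cv, rect_indices(cv, r0, r0 + bh, c0, c0 + bw), c(250, 250, 250))
    x <- c0 + 3L
    while (x < c0 + bw - 3L) {
      sw <- sample(1:2, 1)
      if (runif(1) < 0.55) {
        canvas_paint(cv, rect_indices(cv, r0 + 3L, r0 + bh - 3L, x, x + sw - 1L),
                     c(15, 15, 15))
      }
      x <- x + sw + sample(1:2, 1)
    }
  }
  if (isTRUE(el[["stamp"]])) {
    rad <- max(12L, round(0.03 * h))
    cx <- round(runif(1, 0.08, 0.18) * w); cy <- round(runif(1, 0.82, 0.92) * h)
    cs <- pmax(1L, cx - rad - 2L):pmin(w, cx + rad + 2L)
    rs <- pmax(1L, cy - rad - 2L):pmin(h, cy + rad + 2L)
    px <- rep(cs, each = length(rs)); py <- rep.int(rs, length(cs))
    d <- sqrt((px - cx)^2 + (py - cy)^2)
    ring <- abs(d - rad) <= 0.8
    canvas_paint(cv, (px[ring] - 1L) * h + py[ring], c(120, 40, 60))
  }
  invisible(cv)
}

# dust/stain specks: painted after truth capture, never part of it
draw_debris <- function(cv, cfg) {
  h <- cv$h; w <- cv$w
  n <- rpois(1, cfg$debris_density * h * w / 1e6)
  for (i in seq_len(n)) {
    cx <- runif(1, 2, w - 1); cy <- runif(1, 2, h - 1)
    rad <- sample(0:1, 1)                       # single pixels and r=1 discs
    shade <- runif(1, 40, 120)
    col <- shade * c(1, runif(1, 0.85, 1), runif(1, 0.7, 0.95))
    cs <- max(1L, floor(cx - rad)):min(w, ceiling(cx + rad))
    rs <- max(1L, floor(cy - rad)):min(h, ceiling(cy + rad))
    px <- rep(cs, each = length(rs)); py <- rep.int(rs, length(cs))
    keep <- (px - cx)^2 + (py - cy)^2 <= (rad + 0.5)^2
    canvas_paint(cv, (px[keep] - 1L) * h + py[keep], col, element = FALSE)
  }
  invisible(cv)
}

#' Generate one synthetic herbarium sheet
#'
#' Deterministic for a fixed `cfg$seed`. The plant silhouette is recorded
#' as the ground-truth mask while it is painted; non-plant elements
#' (label, color bar, ruler, barcode, stamp) overwrite the image — and are
#' removed from the truth where they overlap the plant — and debris is
#' painted last, after truth capture, so it pollutes the image but never
#' the truth. That debris is exactly the disparity the despeckle stage
#' exists to remove.
#'
#' @param cfg A [sheet_config()].
#' @return An object of class `synthetic_specimen`: list with `image`
#'   (RGB raster array), `truth` (binary mask), and `record` (one-row
#'   tibble with catalog number and invented taxonomy).
#' @export
generate_sheet <- function(cfg = sheet_config()) {
  stopifnot(inherits(cfg, "sheet_config"))
  h <- cfg$height; w <- cfg$width
  scale <- min(h, w) / 680
  withr::with_seed(cfg$seed, {
    # mounting sheet: base color + gray noise + radial yellowing gradient
    noise <- matrix(rnorm(h * w, 0, cfg$sheet_noise), h, w)
    gy <- (row(noise) / h - 0.5)^2 + (col(noise) / w - 0.5)^2
    grad <- cfg$yellowing * pmin(1, 2.2 * gy)
    cv <- new_canvas(cfg$sheet_color[1] + noise - 5 * grad,
                     cfg$sheet_color[2] + noise - 14 * grad,
                     cfg$sheet_color[3] + noise - 42 * grad)
    # plant silhouette, truth captured as it is painted
    nf <- cfg$frond_count
    plant_idx <- unique(unlist(lapply(seq_len(nf), function(f) {
      lo <- 0.12 + 0.76 * (f - 1) / nf
      hi <- 0.12 + 0.76 * (f - 0.35) / nf
      frond_indices(h, w, cfg, scale, band = c(lo, hi))
    })))
    base_col <- runif(3, cfg$plant_color_low, cfg$plant_color_high)
    jit <- rnorm(length(plant_idx), 0, 4)
    cv$r[plant_idx] <- pmax(0, base_col[1] + jit)
    cv$g[plant_idx] <- pmax(0, base_col[2] + jit)
    cv$b[plant_idx] <- pmax(0, base_col[3] + jit)
    # non-plant elements overwrite the image and are excluded from truth
    draw_elements(cv, cfg)
    element_idx <- unique(unlist(cv$element_idx))
    truth_idx <- setdiff(plant_idx, element_idx)
    if (isTRUE(cfg$elements[["debris"]])) draw_debris(cv, cfg)
    img <- array(0L, dim = c(h, w, 3L))
    clamp8 <- function(m) {
      m <- round(m); m[m < 0] <- 0; m[m > 255] <- 255
      storage.mode(m) <- "integer"
      m
    }
    img[, , 1] <- clamp8(cv$r); img[, , 2] <- clamp8(cv$g); img[, , 3] <- clamp8(cv$b)
    truth <- matrix(0L, h, w)
    truth[truth_idx] <- 255L
    tax <- fake_taxonomy()
    fam_i <- sample(length(tax$families), 1)
    record <- tibble::tibble(
      catalog_number = sprintf("SYN%07d", cfg$seed %% 10000000L),
      family = tax$families[fam_i],
      genus = tax$genera[fam_i],
      species = paste(tax$genera[fam_i], sample(tax$epithets, 1))
    )
    structure(list(image = img, truth = truth, record = record, config = cfg),
              class = "synthetic_specimen")
  })
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  cat(sprintf(
    "Synthetic herbarium sheet %d x %d px, %s (%s), plant fraction %.3f\n",
    nrow(x$truth), ncol(x$truth), x$record$species, x$record$family,
    mean(x$truth == 255L)))
  invisible(x)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` sheet PNGs, `n` ground-truth mask PNGs and a `metadata.csv`
#' manifest (header `catalog_number,family,genus,species,image,mask`)
#' mirroring the metadata deposit that accompanies real digitized
#' collections. Per-item seeds are `cfg$seed + index`, so the whole tree is
#' reproducible from the root seed.
#'
#' @param n Number of specimens (`>= 1`).
#' @param cfg A [sheet_config()]; per-item configs differ only in seed.
#' @param out_dir Output directory (created if needed).
#' @return The manifest as a tibble, with `image`/`mask` holding absolute
#'   paths; written as `metadata.csv` (paths relative to `out_dir`).
#' @export
generate_dataset <- function(n, cfg = sheet_config(), out_dir) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop(sprintf("cannot create output directory '%s'", out_dir), call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i
    sp <- generate_sheet(cfg_i)
    stem <- sprintf("sheet_%04d", i)
    img_rel <- paste0(stem, ".png"); mask_rel <- paste0(stem, "_mask.png")
    write_image_png(sp$image, file.path(out_dir, img_rel))
    write_mask(sp$truth, file.path(out_dir, mask_rel))
    rows[[i]] <- dplyr::mutate(sp$record, image = img_rel, mask = mask_rel)
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  dplyr::mutate(manifest,
                image = file.path(normalizePath(out_dir), .data$image),
                mask = file.path(normalizePath(out_dir), .data$mask))
}

#' Read a dataset manifest CSV
#'
#' Resolves relative `image`/`mask` paths against the manifest's own
#' directory.
#'
#' @param path Path to a manifest CSV with columns
#'   `catalog_number,family,genus,species,image,mask` (extra columns pass
#'   through).
#' @return A tibble with absolute `image`/`mask` paths.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: '%s'", path), call. = FALSE)
  }
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("image", "mask")
  if (!all(need %in% names(m))) {
    stop("manifest must have `image` and `mask` columns", call. = FALSE)
  }
  base <- normalizePath(dirname(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  dplyr::mutate(m, image = fix(.data$image), mask = fix(.data$mask))
}
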
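# shared fixtures and independent oracles, built in code at test time

random_mask <- function(h, w, p = 0.4) {
  m <- matrix(0L, h, w)
  m[matrix(runif(h * w) < p, h)] <- 255L
  m
}

random_rgb <- function(h, w) {
  img <- array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
  storage.mode(img) <- "integer"
  img
}

# exhaustive-scan Otsu oracle: between-class variance at every threshold
brute_otsu <- function(counts) {
  total <- sum(counts)
  v <- 0:255
  best <- -1; best_t <- 0L
  for (t in 0:255) {
    lo <- 1:(t + 1)
    w0 <- sum(counts[lo]); w1 <- total - w0
    s <- if (w0 == 0 || w1 == 0) 0 else {
      mu0 <- sum(counts[lo] * v[lo]) / w0
      mu1 <- (sum(counts * v) - sum(counts[lo] * v[lo])) / w1
      (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    }
    if (s > best + 1e-12) { best <- s; best_t <- t }
  }
  best_t
}

# per-pixel brute-force median filter + binarize oracle (symmetric
# reflection at the borders, matching the documented despeckle contract)
brute_median_mask <- function(mask, k) {
  r <- (k - 1) %/% 2
  h <- nrow(mask); w <- ncol(mask)
  refl <- function(i, n) ifelse(i < 1, 1 - i, ifelse(i > n, 2 * n + 1 - i, i))
  out <- matrix(0L, h, w)
  for (i in 1:h) {
    for (j in 1:w) {
      ri <- refl((i - r):(i + r), h)
      ci <- refl((j - r):(j + r), w)
      if (stats::median(mask[ri, ci]) > 127) out[i, j] <- 255L
    }
  }
  out
}

# small, fast synthetic sheets for training smoke tests
small_sheet <- function(seed, h = 128, w = 96) {
  sp <- generate_sheet(sheet_config(height = h, width = w, seed = seed))
  list(image = sp$image, mask = sp$truth)
}

quiet <- function(expr) suppressMessages(expr)
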
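# Minimal CNN primitives in base R matrix algebra.
#
# A feature map at resolution H x W with C channels is stored as an
# (H*W) x C matrix whose pixel index is the column-major linearization of
# the H x W raster (index = (col-1)*H + row). Convolutions are computed by
# im2col patch extraction followed by one BLAS matrix multiply; gradients
# flow back through the same index maps (rowsum scatter-add). Geometry
# index maps depend only on (H, W, k, stride) and are memoized.

.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(h, w, k, stride) {
  key <- paste(h, w, k, stride, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (h + 2L * pad - k) %/% stride + 1L
  wo <- (w + 2L * pad - k) %/% stride + 1L
  npix <- ho * wo
  oi <- rep(seq_len(ho), times = wo)          # output row, column-major
  oj <- rep(seq_len(wo), each = ho)           # output col
  base_r <- (oi - 1L) * stride                # top-left of window in padded
  base_c <- (oj - 1L) * stride
  idx <- matrix(0L, npix, k * k)
  q <- 0L
  for (dj in seq_len(k)) {
    for (di in seq_len(k)) {
      q <- q + 1L
      idx[, q] <- (base_c + dj - 1L) * hp + (base_r + di)
    }
  }
  interior <- as.vector(outer((pad + seq_len(h)),
                              (pad + seq_len(w) - 1L) * hp, `+`))
  geom <- list(h = h, w = w, k = k, stride = stride, pad = pad,
               hp = hp, wp = wp, ho = ho, wo = wo, npix = npix,
               idx_vec = as.vector(idx), interior = interior)
  .geom_cache[[key]] <- geom
  geom
}

im2col <- function(x, geom) {
  cc <- ncol(x)
  if (geom$pad == 0L && geom$k == 1L && geom$stride == 1L) return(x)
  padded <- matrix(0, geom$hp * geom$wp, cc)
  padded[geom$interior, ] <- x
  p <- padded[geom$idx_vec, , drop = FALSE]
  dim(p) <- c(geom$npix, geom$k * geom$k * cc)
  p
}

conv_fwd <- function(x, wmat, bias, geom) {
  p <- im2col(x, geom)
  out <- p %*% wmat
  out <- out + rep(bias, each = nrow(out))
  list(out = out, p = p)
}

# dout: (npix_out, Cout). Returns dW, db and (optionally) dx.
conv_bwd <- function(dout, p, wmat, geom, cin, need_dx = TRUE) {
  dw <- crossprod(p, dout)
  db <- colSums(dout)
  dx <- NULL
  if (need_dx) {
    dp <- dout %*% t(wmat)
    if (geom$pad == 0L && geom$k == 1L && geom$stride == 1L) {
      dx <- dp
    } else {
      dim(dp) <- c(geom$npix * geom$k * geom$k, cin)
      g <- rowsum(dp, geom$idx_vec)
      dpad <- matrix(0, geom$hp * geom$wp, cin)
      dpad[as.integer(rownames(g)), ] <- g
      dx <- dpad[geom$interior, , drop = FALSE]
    }
  }
  list(dw = dw, db = db, dx = dx)
}

upsample_geom <- function(h, w) {
  key <- paste("up", h, w, sep = "_")
  hit <- .geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  oi <- rep(seq_len(2L * h), times = 2L * w)
  oj <- rep(seq_len(2L * w), each = 2L * h)
  src <- (ceiling(oj / 2) - 1L) * h + ceiling(oi / 2)
  .geom_cache[[key]] <- src
  src
}

upsample2_fwd <- function(x, h, w) {
  x[upsample_geom(h, w), , drop = FALSE]
}

upsample2_bwd <- function(dout, h, w) {
  rowsum(dout, upsample_geom(h, w))   # groups 1..h*w, numerically ordered
}

relu_fwd <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable binary cross-entropy with logits; y in {0,1}
bce_with_logits <- function(z, y) {
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

bce_with_logits_grad <- function(z, y) {
  (sigmoid(z) - y) / length(z)
}

# soft-Dice loss on sigmoid probabilities (smoothing 1)
dice_loss <- function(z, y) {
  p <- sigmoid(z)
  1 - (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
}

dice_loss_grad <- function(z, y) {
  p <- sigmoid(z)
  num <- 2 * sum(p * y) + 1
  den <- sum(p) + sum(y) + 1
  dp <- (num / den^2) - (2 * y / den)
  dp * p * (1 - p)
}

he_init <- function(nrow, ncol) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / nrow)), nrow, ncol)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.99, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      m <- beta1 * s$m + (1 - beta1) * g
      v <- beta2 * s$v + (1 - beta2) * g^2
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), s = list(m = m, v = v))
    }
  }
  walk(params, grads, state)
}

grads_zero_like <- function(params) {
  rapply(params, function(p) p * 0, how = "replace")
}

grads_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
    a
  } else {
    a + b
  }
}

grads_scale <- function(a, s) {
  rapply(a, function(p) p * s, how = "replace")
}
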
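test_that("rebinarize uses strict > cutoff semantics and is idempotent", {
  m <- matrix(c(127L, 128L), 1, 2)
  out <- rebinarize(m, cutoff = 127)
  expect_equal(out, matrix(c(0L, 255L), 1, 2))

  withr::local_seed(2)
  bin <- random_mask(10, 10)
  expect_identical(rebinarize(bin), bin)
  expect_identical(rebinarize(rebinarize(bin)), rebinarize(bin))

  ramp <- matrix(0:255, 16, 16)
  out2 <- rebinarize(ramp, 127)
  expect_equal(sum(out2 == 255L), sum(ramp > 127))
  expect_error(rebinarize(ramp, 255), "cutoff")
})

test_that("despeckle removes minority specks and preserves constants", {
  speck <- matrix(0L, 9, 9)
  speck[5, 5] <- 255L
  expect_true(all(despeckle(speck, 3) == 0L))

  expect_true(all(despeckle(matrix(255L, 7, 7), 5) == 255L))

  block <- matrix(0L, 21, 21)
  block[7:15, 7:15] <- 255L
  out <- despeckle(block, 3)
  expect_true(all(out[8:14, 8:14] == 255L))   # interior untouched
})

test_that("despeckle equals the brute-force median-filter oracle", {
  withr::local_seed(8)
  for (rep in 1:4) {
    m <- random_mask(20, 24, p = runif(1, 0.2, 0.6))
    for (k in c(3, 5, 7)) {
      expect_identical(despeckle(m, k), brute_median_mask(m, k))
    }
  }
})

test_that("despeckle validates kernels and never reaches past kernel radius", {
  m <- random_mask(15, 15)
  expect_error(despeckle(m, 4), "odd")
  expect_error(despeckle(m, 17), "exceeds")
  expect_error(despeckle(matrix(c(0L, 128L), 1, 2), 3), "not binary")

  withr::local_seed(21)
  for (k in c(3, 5)) {
    m2 <- matrix(0L, 30, 30)
    m2[10:20, 10:20] <- 255L
    out <- despeckle(m2, k)
    expect_true(is_binary_mask(out))
    # no new foreground farther than k %/% 2 from existing foreground
    r <- k %/% 2
    reach <- matrix(0L, 30, 30)
    reach[pmax(1, 10 - r):pmin(30, 20 + r), pmax(1, 10 - r):pmin(30, 20 + r)] <- 255L
    expect_true(all(out[reach == 0L] == 0L))
  }
})

test_that("blur_sweep returns one candidate per kernel, no automatic pick", {
  m <- matrix(0L, 40, 40)
  m[10:30, 10:30] <- 255L     # large blob
  m[3, 3] <- 255L             # 1-px speck
  sweep <- blur_sweep(m, c(5, 11, 21))
  expect_length(sweep$candidates, 3)
  for (cand in sweep$candidates) {
    expect_equal(cand[3, 3], 0L)            # speck gone everywhere
    expect_true(all(cand[15:25, 15:25] == 255L))  # blob core present
  }
  expect_error(blur_sweep(m, integer(0)), "at least one")
})

test_that("sweeping an already-clean bulky mask is nearly the identity", {
  # blobs whose boundary curvature is large relative to the kernels, so the
  # only deviation is the corner rounding inherent to an edge median
  withr::local_seed(9)
  for (i in 1:5) {
    m <- matrix(0L, 220, 220)
    hgt <- sample(140:180, 1); wdt <- sample(100:140, 1)
    r0 <- sample(10:30, 1); c0 <- sample(10:30, 1)
    m[r0:(r0 + hgt), c0:(c0 + wdt)] <- 255L
    sweep <- blur_sweep(m)
    for (cand in sweep$candidates) {
      expect_gte(dice(cand, m), 0.99)
    }
  }
})
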
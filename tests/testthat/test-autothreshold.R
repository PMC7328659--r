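test_that("histograms count pixel values exactly", {
  h <- gray_histogram(matrix(c(0L, 0L, 255L, 255L), 2, 2))
  expect_equal(h$counts[1], 2L)
  expect_equal(h$counts[256], 2L)
  expect_equal(sum(h$counts), 4L)
  expect_equal(h$total, 4L)

  h2 <- gray_histogram(matrix(7L, 3, 3))
  expect_equal(h2$counts[8], 9L)
  expect_equal(h2$total, 9L)

  withr::local_seed(5)
  img <- matrix(sample(0:255, 256, replace = TRUE), 16, 16)
  h3 <- gray_histogram(img)
  tally <- vapply(0:255, function(v) sum(img == v), integer(1))
  expect_equal(h3$counts, tally)
})

test_that("a two-delta histogram forces the partition and ties break low", {
  counts <- integer(256)
  counts[10 + 1] <- 50L
  counts[200 + 1] <- 50L
  h <- structure(list(counts = counts, total = 100L), class = "gray_histogram")
  res <- otsu_threshold(h)
  expect_equal(res$threshold, 10L)
  expect_false(res$degenerate)
})

test_that("constant images are flagged degenerate, empty histograms error", {
  res <- otsu_threshold(matrix(42L, 5, 5))
  expect_equal(res$threshold, 42L)
  expect_true(res$degenerate)
  empty <- structure(list(counts = integer(256), total = 0L),
                     class = "gray_histogram")
  expect_error(otsu_threshold(empty), "empty")
})

test_that("the threshold equals the exhaustive between-class-variance argmax", {
  withr::local_seed(11)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 1024, replace = TRUE,
                         prob = runif(256)), 32, 32)
    h <- gray_histogram(img)
    expect_equal(otsu_threshold(h)$threshold, brute_otsu(h$counts))
  }
})

test_that("the Otsu threshold depends only on the histogram and shifts with the image", {
  withr::local_seed(13)
  img <- matrix(sample(40:180, 600, replace = TRUE), 20, 30)
  t1 <- otsu_threshold(gray_histogram(img))$threshold
  expect_equal(otsu_threshold(gray_histogram(matrix(img, 30, 20)))$threshold, t1)
  # +c on every pixel (no clipping) shifts the threshold by exactly c
  expect_equal(otsu_threshold(gray_histogram(img + 50L))$threshold, t1 + 50L)
})

test_that("thresholding yields complementary foreground/background masks", {
  pair <- threshold_to_pair(matrix(c(0L, 200L), 1, 2), 10)
  expect_equal(pair$foreground, matrix(c(255L, 0L), 1, 2))
  expect_equal(pair$background, matrix(c(0L, 255L), 1, 2))

  g <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
  all_white <- threshold_to_pair(g, 255)
  expect_true(all(all_white$foreground == 255L))
  expect_true(all(all_white$background == 0L))

  for (t in c(0, 17, 128, 254)) {
    pr <- threshold_to_pair(g, t)
    expect_true(all(bitwXor(pr$foreground, pr$background) == 255L))
  }
  expect_error(threshold_to_pair(g, 300), "\\[0, 255\\]")
})

test_that("auto_mask equals the composed step-by-step pipeline", {
  sp <- generate_sheet(sheet_config(height = 128, width = 96, seed = 3))
  am <- auto_mask(sp$image)
  g <- to_grayscale(sp$image)
  res <- otsu_threshold(gray_histogram(g))
  pair <- threshold_to_pair(g, res$threshold)
  expect_identical(am$pair$foreground, pair$foreground)
  expect_identical(am$otsu$threshold, res$threshold)
})

test_that("a featureless white sheet is flagged degenerate, not an error", {
  img <- array(255L, dim = c(32, 32, 3))
  am <- auto_mask(img)
  expect_true(am$otsu$degenerate)
})
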
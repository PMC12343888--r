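test_that("max projection matches a brute-force per-pixel maximum", {
  set.seed(21)
  a <- array(runif(3 * 4 * 2 * 8 * 8, 0, 100), c(3, 4, 2, 8, 8))
  s <- image_stack(a)
  p <- max_project(s)
  expect_identical(dim(p$data)[2], 1L)
  for (t in 1:3) for (ch in 1:2) for (y in 1:8) for (x in 1:8)
    expect_identical(p$data[t, 1, ch, y, x], max(a[t, , ch, y, x]))
})

test_that("max projection is idempotent and invariant to z-slice order", {
  set.seed(22)
  a <- array(runif(1 * 3 * 1 * 6 * 6), c(1, 3, 1, 6, 6))
  s <- image_stack(a)
  p1 <- max_project(s)
  expect_identical(max_project(p1)$data, p1$data)
  perm <- image_stack(a[, c(3, 1, 2), , , , drop = FALSE])
  expect_identical(max_project(perm)$data, p1$data)
})

test_that("background estimation recovers the majority level of a bimodal image", {
  img <- matrix(50, 64, 64)
  img[20:40, 20:40] <- 200
  bg <- estimate_background(img)
  expect_identical(as.numeric(bg), 50)
  expect_false(attr(bg, "degenerate"))
  expect_true(attr(bg, "threshold") > 50 && attr(bg, "threshold") < 200)
})

test_that("background estimation of a constant image is degenerate but usable", {
  bg <- estimate_background(matrix(7, 16, 16))
  expect_identical(as.numeric(bg), 7)
  expect_true(attr(bg, "degenerate"))
})

test_that("background estimation tolerates moderate noise", {
  set.seed(23)
  img <- matrix(rnorm(64 * 64, 100, 5), 64, 64)
  img[10:30, 10:30] <- img[10:30, 10:30] + 400
  expect_lt(abs(as.numeric(estimate_background(img)) - 100), 2)
})

test_that("normalization is exactly divisive and rejects bad backgrounds", {
  img <- matrix(1:12 * 10, 3, 4)
  expect_identical(normalize_to_background(img, 10), img / 10)
  expect_identical(normalize_to_background(2 * img, 10),
                   2 * normalize_to_background(img, 10))
  expect_error(normalize_to_background(img, 0), "positive")
  expect_error(normalize_to_background(img, -3), "positive")
})

test_that("median denoising removes isolated outliers and preserves plateaus", {
  img <- matrix(10, 21, 21)
  img[11, 11] <- 1000            # isolated hot pixel
  img[5:15, 3:5] <- 80           # 3-px-wide bar
  out <- median_denoise(img, 3)
  expect_identical(out[11, 11], 10)
  expect_identical(out[10, 4], 80)           # bar interior intact
  expect_true(all(out %in% c(10, 80)))       # values from the input level set
  expect_identical(median_denoise(matrix(5, 8, 8), 3), matrix(5, 8, 8))
  expect_error(median_denoise(img, 4), "odd")
})

test_that("median denoising equals a brute-force windowed median", {
  set.seed(31)
  img <- matrix(rnorm(20 * 15), 20, 15)
  out <- median_denoise(img, 3)
  for (y in c(1, 2, 10, 20)) for (x in c(1, 7, 15)) {
    ys <- pmin(pmax((y - 1):(y + 1), 1), 20)
    xs <- pmin(pmax((x - 1):(x + 1), 1), 15)
    expect_equal(out[y, x], median(as.vector(img[ys, xs])))
  }
})

test_that("box filters agree with brute-force window statistics at edges and interior", {
  set.seed(24)
  img <- matrix(rnorm(15 * 12), 15, 12)
  k <- 5
  bm <- box_mean(img, k)
  bs <- box_sd(img, k)
  for (y in c(1, 2, 8, 15)) for (x in c(1, 6, 12)) {
    ys <- max(1, y - 2):min(15, y + 2)
    xs <- max(1, x - 2):min(12, x + 2)
    w <- img[ys, xs]
    expect_equal(bm[y, x], mean(w))
    # box_sd is the population standard deviation of the window
    expect_equal(bs[y, x], sqrt(mean((w - mean(w))^2)))
  }
})

test_that("line profiles reproduce a linear ramp analytically", {
  img <- matrix(rep(0:31, each = 32), 32, 32)   # value = x (0-based column)
  lp <- line_profile(img, c(10, 2), c(10, 30))
  expect_equal(lp$values, 2 + lp$positions_px)
  expect_identical(lp$positions_px[1], 0)
  expect_true(all(diff(lp$positions_px) > 0))
  # width averaging across a constant-in-y image changes nothing
  lp3 <- line_profile(img, c(10, 2), c(10, 30), width_px = 3)
  expect_equal(lp3$values, lp$values)
  expect_error(line_profile(img, c(5, 5), c(5, 5)), "distinct")
  expect_error(line_profile(img, c(-1, 0), c(5, 5)), "outside")
})
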
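test_that("grayscale conversion uses BT.601 luminance and is range-safe", {
  white <- array(255, c(4, 5, 3))
  expect_true(all(to_grayscale(white) == 255))

  red <- array(0, c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(to_grayscale(red)[1, 1], 76)  # round(0.299 * 255)

  g <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_identical(to_grayscale(g), g)

  set.seed(11)
  arr <- array(runif(3 * 12 * 9, 0, 255), c(12, 9, 3))
  gs <- to_grayscale(arr)
  expect_true(all(gs >= 0 & gs <= 255))
  # matches an independent per-pixel computation
  expect_equal(gs[3, 7],
               round(0.299 * arr[3, 7, 1] + 0.587 * arr[3, 7, 2] + 0.114 * arr[3, 7, 3]))
})

test_that("inversion maps v to 255 - v and is an involution", {
  expect_equal(invert_image(matrix(0, 1, 1))[1, 1], 255)
  expect_equal(invert_image(matrix(255, 1, 1))[1, 1], 0)
  set.seed(2)
  img <- matrix(sample(0:255, 60, replace = TRUE), 6, 10)
  expect_identical(invert_image(invert_image(img)), img)
})

test_that("binarize is strict and monotone non-increasing in the threshold", {
  img <- matrix(c(10, 200, 10, 200), 2, 2)
  m <- binarize(img, 100)
  expect_identical(m, matrix(as.integer(img == 200), 2, 2))
  expect_true(all(binarize(img, 255) == 0L))
  expect_error(binarize(img, 300), "0, 255")

  set.seed(33)
  for (k in 1:100) {
    img <- matrix(runif(32 * 32, 0, 255), 32, 32)
    t1 <- runif(1, 0, 255); t2 <- runif(1, t1, 255)
    f1 <- binarize(img, t1); f2 <- binarize(img, t2)
    expect_true(all(f1[f2 == 1L] == 1L))  # foreground(t2) subset of foreground(t1)
  }
})

test_that("auto threshold equals the exhaustive Otsu search", {
  bimodal <- matrix(c(rep(50, 50), rep(200, 50)), 10, 10)
  t <- auto_threshold(bimodal)
  expect_gt(t, 49); expect_lt(t, 200)

  set.seed(7)
  for (k in 1:20) {
    mix <- matrix(pmin(255, pmax(0, c(rnorm(300, 60, 20), rnorm(100, 190, 15)))),
                  20, 20)
    expect_identical(auto_threshold(mix), otsu_brute_force(mix))
  }
  expect_error(auto_threshold(matrix(42, 5, 5)), "distinct")
})

test_that("CIELAB conversion reproduces reference values at the sRGB corners", {
  # frozen reference values (IEC sRGB, D65), cross-checked against an
  # independent colour library
  corners <- rbind(
    white   = c(255, 255, 255, 100.0000,   0.0000,    0.0000),
    black   = c(0, 0, 0,         0.0000,   0.0000,    0.0000),
    red     = c(255, 0, 0,      53.2406,  80.0923,   67.2028),
    green   = c(0, 255, 0,      87.7351, -86.1830,   83.1797),
    blue    = c(0, 0, 255,      32.2957,  79.1856, -107.8573),
    yellow  = c(255, 255, 0,    97.1395, -21.5547,   94.4781),
    cyan    = c(0, 255, 255,    91.1133, -48.0906,  -14.1263),
    magenta = c(255, 0, 255,    60.3235,  98.2331,  -60.8210))
  arr <- array(0, c(nrow(corners), 1, 3))
  for (k in 1:3) arr[, 1, k] <- corners[, k]
  lab <- to_cielab(arr)
  expect_equal(as.numeric(lab$L), unname(corners[, 4]), tolerance = 0.1)
  expect_equal(as.numeric(lab$a), unname(corners[, 5]), tolerance = 0.1)
  expect_equal(as.numeric(lab$b), unname(corners[, 6]), tolerance = 0.1)
  expect_lt(abs(lab$a[1, 1]), 0.5)
  expect_lt(abs(lab$b[1, 1]), 0.5)

  # saturated yellow sits far above dark red on the b* axis
  two <- array(c(255, 100, 255, 20, 0, 40), c(2, 1, 3))
  labs <- to_cielab(two)
  expect_gt(labs$b[1, 1], labs$b[2, 1])

  # base R convertColor as an independent (slightly different) cross-check
  set.seed(5)
  rgb <- matrix(sample(0:255, 30, replace = TRUE), 10, 3)
  arr <- array(0, c(10, 1, 3)); for (k in 1:3) arr[, 1, k] <- rgb[, k]
  ours <- to_cielab(arr)
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  expect_equal(as.numeric(ours$L), unname(ref[, 1]), tolerance = 0.6)
})

test_that("scale-bar removal blanks bars but leaves seeds and bare images alone", {
  # bright solid bar along the bottom border + real seed blobs
  set.seed(21)
  sc <- generate_scene(20, marker_fraction = 1, radius_mean_px = 12,
                       canvas = c(400, 400), rng_seed = 17)
  img <- render_fluorescence_pair(sc, noise_sd = 2)$fluorescent
  img[395:400, 80:279] <- 230  # 200 x 6 solid bar along the bottom border
  cleaned <- remove_scale_bar(img)
  seg <- segment_seeds(cleaned, seg_params())
  expect_equal(seg$n_seeds, 20)

  # no bar-like component: image unchanged
  plain <- render_fluorescence_pair(sc, noise_sd = 2)$fluorescent
  expect_identical(remove_scale_bar(plain), plain)

  # explicit exclusion rectangle: exactly those pixels set to modal intensity
  img2 <- matrix(10, 20, 20); img2[4:8, 3:12] <- 200
  out <- remove_scale_bar(img2, exclusion_rect = c(5, 5, 3, 12))
  expect_true(all(out[5, 3:12] == 10))
  expect_true(all(out[c(4, 6:8), 3:12] == 200))
})
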
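test_that("connected components use 8-connectivity and match the flood-fill oracle", {
  m <- matrix(0L, 20, 20)
  m[2:6, 2:6] <- 1L; m[10:14, 12:16] <- 1L
  res <- label_components(m)
  expect_equal(res$n_labels, 2L)
  expect_equal(res$regions$area_px, c(25L, 25L))
  expect_equal(res$regions$centroid_r, c(4, 12))
  expect_equal(res$regions$centroid_c, c(4, 14))

  # squares touching only at one diagonal corner are one region
  d <- matrix(0L, 10, 10)
  d[2:4, 2:4] <- 1L; d[5:7, 5:7] <- 1L
  expect_equal(label_components(d)$n_labels, 1L)

  set.seed(101)
  for (k in 1:50) {
    m <- random_mask(24, 24, p = runif(1, 0.2, 0.6))
    expect_true(same_partition(label_components(m)$labels, flood_fill_labels(m)))
  }
})

test_that("radial threshold derivation reproduces the printed ratio/threshold pairings", {
  # median seed area pi * 20^2 (equivalent radius 20 px, the benchmark scale)
  regions <- data.frame(area_px = rep(pi * 400, 5))
  expect_equal(derive_radial_threshold(regions, 0.45), 9.0)
  expect_equal(derive_radial_threshold(regions, 0.50), 10.0)
  expect_equal(derive_radial_threshold(regions, 1e-9), 2e-8, tolerance = 1e-6)
  expect_error(derive_radial_threshold(regions[0, , drop = FALSE], 0.4),
               "lower the intensity threshold")
})

test_that("noise filter keeps exactly the regions at or above the radial threshold", {
  regions <- data.frame(area_px = c(400, 50, 3))
  regions$eq_radius <- sqrt(regions$area_px / pi)
  out <- filter_noise(regions, 9)
  expect_equal(out$area_px, 400)
  expect_equal(nrow(filter_noise(regions, 0)), 3L)

  set.seed(9)
  for (k in 1:20) {
    regions <- data.frame(area_px = sample(1:2000, 30))
    regions$eq_radius <- sqrt(regions$area_px / pi)
    t <- runif(1, 0, 20)
    out <- filter_noise(regions, t)
    expect_identical(out, regions[regions$eq_radius >= t, , drop = FALSE])
  }
})

test_that("morphological opening removes speckle, preserves disks, is idempotent", {
  m <- matrix(0L, 15, 15); m[8, 8] <- 1L
  expect_true(all(morphological_clean(m) == 0L))

  disk <- disk_mask(40, 40, 20, 20, 15)
  opened <- morphological_clean(disk)
  expect_lt(abs(sum(opened) - sum(disk)) / sum(disk), 0.05)

  set.seed(4)
  r <- random_mask(30, 30, 0.5)
  once <- morphological_clean(r)
  expect_identical(morphological_clean(once), once)
})

test_that("chamfer transform approximates Euclidean distance within 8%", {
  m <- matrix(0L, 10, 10); m[5, 2:9] <- 1L
  d <- chamfer_distance(m)
  expect_true(all(d[m == 0L] == 0))
  expect_true(all(d[5, 2:9] == 1))

  set.seed(77)
  for (k in 1:10) {
    m <- morphological_clean(random_mask(48, 48, runif(1, 0.3, 0.6)))
    if (all(m == 0L)) next
    d <- chamfer_distance(m)
    ref <- brute_force_dist(m)
    fg <- m == 1L
    expect_lt(max(abs(d[fg] - ref[fg]) / ref[fg]), 0.08)
  }

  # any foreground pixel 8-adjacent to background is within sqrt(2) of it
  disk <- disk_mask(50, 50, 25, 25, 18)
  d <- chamfer_distance(disk)
  edge <- disk == 1L & brute_force_dist(disk) <= sqrt(2)
  expect_true(all(d[edge] <= sqrt(2) + 1e-9))

  expect_error(chamfer_distance(matrix(1L, 4, 4)), "background")
})

test_that("marker cores are the distance-level sets of the mask", {
  disk <- disk_mask(60, 60, 30, 30, 20)
  mk <- make_markers(disk, 9)
  expect_equal(mk$n_labels, 1L)
  # level set at 9 of a radius-20 disk: a concentric disk of radius ~11
  expect_gt(mk$regions$area_px, pi * 9^2)
  expect_lt(mk$regions$area_px, pi * 13^2)
  expect_equal(mk$regions$centroid_r, 30, tolerance = 0.6)

  # threshold 0: markers are the mask components themselves
  m <- matrix(0L, 20, 20); m[3:6, 3:6] <- 1L; m[12:15, 10:13] <- 1L
  mk0 <- make_markers(m, 0)
  expect_true(same_partition(mk0$labels, label_components(m)$labels))

  # two disks overlapping by 20% of radius: the neck (Euclidean half-width
  # 0.436 r, read up to ~4.5% high by the 3-4 chamfer) falls below 0.5 r
  # while both cores (distance ~r at the centres) survive
  two <- disk_mask(60, 100, 30, 30, 20) | disk_mask(60, 100, 30, 66, 20)
  two <- matrix(as.integer(two), 60, 100)
  expect_equal(make_markers(two, 0.5 * 20)$n_labels, 2L)

  expect_error(make_markers(disk, 50), "lower the radial threshold")
})

test_that("watershed partitions the foreground with one region per marker", {
  blob <- disk_mask(40, 40, 20, 20, 12)
  mk <- matrix(0L, 40, 40); mk[20, 20] <- 1L
  d <- chamfer_distance(blob)
  out <- watershed_split(d, blob, mk)
  expect_true(all((out > 0L) == (blob == 1L)))
  expect_equal(unique(out[out > 0L]), 1L)

  # two overlapping disks, centres 1.5 radii apart, one marker per centre
  r <- 14
  two <- disk_mask(50, 70, 25, 25, r) | disk_mask(50, 70, 25, 25 + 1.5 * r, r)
  two <- matrix(as.integer(two), 50, 70)
  mk <- matrix(0L, 50, 70); mk[25, 25] <- 1L; mk[25, 25 + 1.5 * r] <- 2L
  d <- chamfer_distance(two)
  out <- watershed_split(d, two, mk)
  expect_true(all((out > 0L) == (two == 1L)))
  expect_setequal(unique(out[out > 0L]), c(1L, 2L))
  expect_equal(out[25, 25], 1L)
  expect_equal(out[25, 25 + 1.5 * r], 2L)

  # n markers -> exactly n labels, n = 1..5
  big <- matrix(1L, 30, 60); big[1, ] <- 0L  # keep one background row
  for (n in 1:5) {
    mk <- matrix(0L, 30, 60)
    for (i in seq_len(n)) mk[15, 10 * i] <- i
    out <- watershed_split(chamfer_distance(big), big, mk)
    expect_equal(sort(unique(out[out > 0L])), seq_len(n))
  }

  expect_error(watershed_split(d, two, matrix(0L, 50, 70)), "at least one marker")
})

test_that("contours enclose exactly their region's pixels", {
  sq <- matrix(0L, 8, 8); sq[3:5, 4:6] <- 1L
  ct <- extract_contours(sq)
  expect_length(ct, 1L)
  poly <- ct[[1]]
  # closed, axis-aligned crack boundary of a 3x3 square encloses area 9
  expect_identical(poly[1, ], poly[nrow(poly), ])
  x <- poly[, 2]; y <- poly[, 1]
  area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  expect_equal(area, 9)

  # every pixel of a label lies inside that label's polygon (random maps)
  set.seed(55)
  for (k in 1:20) {
    m <- random_mask(18, 18, runif(1, 0.25, 0.5))
    lab <- label_components(m)$labels
    n <- max(lab)
    if (n == 0L) next
    cts <- extract_contours(lab)
    expect_length(cts, n)
    px <- which(lab > 0L, arr.ind = TRUE)
    for (i in seq_len(nrow(px))) {
      l <- lab[px[i, 1], px[i, 2]]
      expect_true(point_in_polygon(px[i, 1], px[i, 2], cts[[as.character(l)]]))
    }
  }

  # on hole-free touching regions (watershed output) the correspondence is
  # exact in both directions: inside its own polygon, outside all others
  r <- 10
  two <- disk_mask(40, 60, 20, 20, r) | disk_mask(40, 60, 20, 20 + 1.5 * r, r)
  two <- matrix(as.integer(two), 40, 60)
  mk <- matrix(0L, 40, 60); mk[20, 20] <- 1L; mk[20, 35] <- 2L
  lab <- watershed_split(chamfer_distance(two), two, mk)
  cts <- extract_contours(lab)
  px <- which(lab > 0L, arr.ind = TRUE)
  for (i in seq_len(nrow(px))) {
    l <- lab[px[i, 1], px[i, 2]]
    for (cl in names(cts)) {
      expect_equal(point_in_polygon(px[i, 1], px[i, 2], cts[[cl]]),
                   cl == as.character(l))
    }
  }
})

test_that("the composed pipeline recovers ground-truth counts", {
  sc <- generate_scene(50, marker_fraction = 1, overlap_fraction = 0, rng_seed = 8)
  img <- render_fluorescence_pair(sc, noise_sd = 3)$fluorescent
  seg <- segment_seeds(img, seg_params())
  expect_equal(seg$n_seeds, 50)
  expect_equal(length(seg$contours), 50)

  blank <- matrix(12, 100, 100)
  expect_warning(res <- segment_seeds(blank), "0 seeds")
  expect_equal(res$n_seeds, 0L)
})

test_that("seed counts are invariant under integer translation of the scene", {
  set.seed(60)
  shifts <- cbind(sample(-8:8, 20, replace = TRUE), sample(-8:8, 20, replace = TRUE))
  for (k in 1:20) {
    sc <- generate_scene(12, marker_fraction = 1, radius_mean_px = 12,
                         canvas = c(300, 300), rng_seed = 400 + k)
    img <- render_fluorescence_pair(sc, noise_sd = 2)$fluorescent
    n0 <- segment_seeds(img)$n_seeds
    n1 <- segment_seeds(translate_image(img, shifts[k, 1], shifts[k, 2]))$n_seeds
    expect_equal(n1, n0)
  }
})
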
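make_fixture_dir <- function(ids = c("lineA", "lineB", "lineC"),
                             n = c(40, 44, 36), marker = c(30, 33, 27),
                             seeds = c(301, 302, 303)) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  for (i in seq_along(ids)) {
    sc <- generate_scene(n[i], radius_mean_px = 15, rng_seed = seeds[i])
    sc <- force_marker_count(sc, marker[i])
    write_scene_fixtures(sc, dir, sample_id = ids[i])
  }
  dir
}

test_that("a fluorescence run reproduces ground truth end to end", {
  dir <- make_fixture_dir(ids = "lineA", n = 40, marker = 30, seeds = 301)
  overlay_dir <- file.path(dir, "overlays")
  rec <- run_fluorescence(file.path(dir, "lineA_BF.png"),
                          file.path(dir, "lineA_FL.png"),
                          overlay_dir = overlay_dir)
  expect_s3_class(rec, "sample_record")
  expect_equal(rec$sample_id, "lineA")
  expect_equal(rec$n_total, 40L)
  expect_equal(rec$n_transgenic, 30L)
  expect_equal(rec$chi2, 0)
  expect_equal(rec$p_value, 1)
  expect_equal(rec$call, "single_locus_consistent")
  expect_true(file.exists(file.path(overlay_dir, "lineA_BF_overlay.png")))
  expect_true(file.exists(file.path(overlay_dir, "lineA_FL_overlay.png")))

  expect_error(run_fluorescence(file.path(dir, "lineA_BF.png"), "missing.png"),
               "cannot read")
})

test_that("a colorimetric run reproduces ground truth end to end", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(60, radius_mean_px = 15, rng_seed = 777)
  sc <- force_marker_count(sc, 45)
  write_scene_fixtures(sc, dir, sample_id = "ruby1", mode = "colorimetric")
  rec <- run_colorimetric(file.path(dir, "ruby1_RGB.png"))
  expect_equal(rec$n_total, 60L)
  expect_equal(rec$n_transgenic, 45L)
  expect_equal(rec$chi2, 0)
  expect_equal(rec$p_value, 1)

  # a 30/30 split is decisively rejected under the 3:1 null
  sc2 <- generate_scene(60, radius_mean_px = 15, rng_seed = 778)
  sc2 <- force_marker_count(sc2, 30)
  write_scene_fixtures(sc2, dir, sample_id = "ruby2", mode = "colorimetric")
  rec2 <- run_colorimetric(file.path(dir, "ruby2_RGB.png"))
  expect_equal(rec2$n_total, 60L)
  expect_equal(rec2$n_transgenic, 30L)
  expect_equal(rec2$chi2, 20, tolerance = 1e-10)  # 225/45 + 225/15
  expect_equal(rec2$call, "rejected")
  expect_equal(rec2$direction, "deficit_transgenic")
})

test_that("batch processing pairs files, exports CSV and isolates failures", {
  dir <- make_fixture_dir()
  csv <- file.path(dir, "out.csv")
  df <- run_batch(dir, mode = "fluorescence", out_csv = csv, quiet = TRUE)
  expect_equal(nrow(df), 3L)
  expect_equal(sort(df$sample_id), c("lineA", "lineB", "lineC"))
  expect_equal(df$n_total[order(df$sample_id)], c(40L, 44L, 36L))
  expect_equal(df$n_transgenic[order(df$sample_id)], c(30L, 33L, 27L))
  expect_equal(nrow(attr(df, "failures")), 0L)
  expect_true(file.exists(csv))
  expect_equal(length(readLines(csv)), 4L)  # header + 3 rows

  # CSV round trip reproduces every field exactly
  back <- read_records_csv(csv)
  expect_equal(nrow(back), 3L)
  for (col in names(df)) expect_identical(back[[col]], df[[col]], label = col)

  # order independence: a shuffled manifest permutes rows, changes no values
  manifest <- data.frame(sample_id = c("lineB", "lineC", "lineA"),
                         brightfield = file.path(dir, c("lineB_BF.png", "lineC_BF.png", "lineA_BF.png")),
                         fluorescent = file.path(dir, c("lineB_FL.png", "lineC_FL.png", "lineA_FL.png")))
  df2 <- run_batch(manifest, mode = "fluorescence", quiet = TRUE)
  expect_equal(df2[order(df2$sample_id), ], df[order(df$sample_id), ],
               ignore_attr = TRUE)

  # re-running with a fixed configuration is bit-identical
  csv2 <- file.path(dir, "out2.csv")
  run_batch(dir, mode = "fluorescence", out_csv = csv2, quiet = TRUE)
  expect_identical(readLines(csv), readLines(csv2))

  # one unreadable sample: two rows, one logged failure
  manifest$fluorescent[2] <- file.path(dir, "nope.png")
  df3 <- run_batch(manifest, mode = "fluorescence", quiet = TRUE)
  expect_equal(nrow(df3), 2L)
  fails <- attr(df3, "failures")
  expect_equal(fails$sample_id, "lineC")
  expect_match(fails$error, "cannot read")

  expect_error(run_batch(data.frame(sample_id = character()),
                         mode = "fluorescence", quiet = TRUE), "empty manifest")
})

test_that("manual count adjustment recomputes the test and flags the record", {
  dir <- make_fixture_dir(ids = "lineA", n = 40, marker = 30, seeds = 301)
  rec <- run_fluorescence(file.path(dir, "lineA_BF.png"),
                          file.path(dir, "lineA_FL.png"))

  adj <- adjust_counts(rec, corrected_total = 41)
  expect_true(adj$manually_adjusted)
  expect_equal(adj$n_total, 41L)
  expect_equal(adj$n_wildtype, 11L)
  # exact Pearson statistic for (30, 11) under 3:1
  expect_equal(adj$chi2, (4 * 30 - 3 * 41)^2 / (3 * 41), tolerance = 1e-12)
  expect_equal(adj$call, "single_locus_consistent")

  expect_identical(adjust_counts(rec), rec)  # no corrections: unchanged
  expect_error(adjust_counts(rec, corrected_transgenic = 200), "exceeds")
})
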
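# Batch processing, sample records, CSV export, overlays.

# 3x5 bitmap digits for stamping seed ids onto overlays
.digit_font <- local({
  rows <- c("111101101101111", "010110010010111", "111001111100111",
            "111001111001111", "101101111001001", "111100111001111",
            "111100111101111", "111001001001001", "111101111101111",
            "111101111001111")
  lapply(rows, function(s) matrix(as.integer(strsplit(s, "")[[1]]) == 1L,
                                  nrow = 5, byrow = TRUE))
})

stamp_number <- function(img_rgb, number, row, col, rgb = c(0, 255, 255)) {
  digits <- as.integer(strsplit(as.character(number), "")[[1]])
  H <- dim(img_rgb)[1]; W <- dim(img_rgb)[2]
  c0 <- round(col) - 2 * length(digits)
  r0 <- round(row) - 2
  for (d in seq_along(digits)) {
    pat <- .digit_font[[digits[d] + 1L]]
    idx <- which(pat, arr.ind = TRUE)
    rr <- r0 + idx[, 1] - 1L
    cc <- c0 + (d - 1L) * 4L + idx[, 2] - 1L
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    for (k in 1:3) img_rgb[cbind(rr[ok], cc[ok], k)] <- rgb[k]
  }
  img_rgb
}

boundary_pixels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- function(dr, dc) {
    out <- matrix(-1L, nr, nc)
    out[max(1, 1 + dr):min(nr, nr + dr), max(1, 1 + dc):min(nc, nc + dc)] <-
      labels[max(1, 1 - dr):min(nr, nr - dr), max(1, 1 - dc):min(nc, nc - dc)]
    out
  }
  b <- labels > 0L & (labels != pad(1, 0) | labels != pad(-1, 0) |
                      labels != pad(0, 1) | labels != pad(0, -1))
  which(b)
}

#' Write a verification overlay
#'
#' Writes a PNG copy of the input with each detected seed outlined and its
#' numeric label stamped at the centroid.
#'
#' @param img The original image (grayscale matrix or RGB array, 0-255).
#' @param seg A `seed_segmentation` (or the `segmentation` element of a
#'   `color_classification`).
#' @param path Output PNG path.
#' @param outline RGB outline colour; regions listed in `highlight` use
#'   `highlight_col` instead (used to mark RUBY seeds).
#' @param highlight Optional integer labels to outline in `highlight_col`.
#' @param highlight_col RGB colour for highlighted regions.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, seg, path, outline = c(255, 40, 40),
                          highlight = integer(), highlight_col = c(40, 90, 255)) {
  if (is_rgb(img)) rgbim <- img else rgbim <- array(rep(img, 3), c(dim(img), 3))
  lab <- seg$labels
  bidx <- boundary_pixels(lab)
  if (length(bidx) > 0) {
    hi <- lab[bidx] %in% highlight
    n <- length(lab)
    for (k in 1:3) {
      rgbim[bidx + (k - 1) * n][!hi] <- outline[k]
      rgbim[bidx + (k - 1) * n][hi] <- highlight_col[k]
    }
  }
  if (nrow(seg$regions) > 0) {
    for (i in seq_len(nrow(seg$regions))) {
      r <- seg$regions[i, ]
      rgbim <- stamp_number(rgbim, r$label, r$centroid_r, r$centroid_c)
    }
  }
  write_raster(rgbim, path)
  invisible(path)
}

new_record <- function(sample_id, mode, counts, stat, bf_intensity, fl_intensity,
                       radial_threshold, radial_ratio, warnings) {
  structure(list(
    sample_id = sample_id, mode = mode,
    n_total = if (is.null(counts)) NA_integer_ else counts$n_total,
    n_transgenic = if (is.null(counts)) NA_integer_ else counts$n_transgenic,
    n_wildtype = if (is.null(counts)) NA_integer_ else counts$n_wildtype,
    chi2 = if (is.null(stat)) NA_real_ else stat$chi2_statistic,
    p_value = if (is.null(stat)) NA_real_ else stat$p_value,
    call = if (is.null(stat)) NA_character_ else stat$call,
    direction = if (is.null(stat)) NA_character_ else stat$direction,
    expected_fraction = if (is.null(stat)) NA_real_ else stat$expected_fraction,
    alpha = if (is.null(stat)) NA_real_ else stat$alpha,
    bf_intensity = bf_intensity, fl_intensity = fl_intensity,
    radial_threshold = radial_threshold, radial_ratio = radial_ratio,
    manually_adjusted = FALSE,
    warnings = warnings), class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("Sample %s [%s]: %s total, %s transgenic, %s wild-type\n",
              x$sample_id, x$mode, x$n_total, x$n_transgenic, x$n_wildtype))
  if (!is.na(x$chi2)) {
    cat(sprintf("  chi2 = %.4g, p = %.4g -> %s\n", x$chi2, x$p_value, x$call))
  }
  if (x$manually_adjusted) cat("  (counts manually adjusted)\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

collect_warnings <- function(expr) {
  w <- character()
  val <- withCallingHandlers(expr, warning = function(cnd) {
    w <<- c(w, conditionMessage(cnd))
    invokeRestart("muffleWarning")
  })
  list(value = val, warnings = w)
}

segregation_or_null <- function(counts, expected_fraction, alpha) {
  if (counts$n_total == 0L) return(NULL)
  chi_squared_segregation(counts, expected_fraction, alpha)
}

#' Analyse one brightfield/fluorescent image pair
#'
#' Runs the full fluorescence-mode analysis: the brightfield frame is
#' converted to grayscale, inverted, cleared of scale bars and segmented to
#' count all seeds; the fluorescent frame is converted to grayscale, cleared
#' of scale bars and segmented to count marker-positive seeds; the two counts
#' are combined and tested against the Mendelian null.
#'
#' @param brightfield_path,fluorescent_path Image files of identical pixel
#'   dimensions (the two frames of one field of seeds).
#' @param bf_params,fl_params [seg_params()] for each channel; brightfield and
#'   fluorescent frames usually need different intensity thresholds.
#' @param sample_id Sample label (defaults to the brightfield file name).
#' @param expected_fraction,alpha Passed to [chi_squared_segregation()].
#' @param exclusion_rect Optional scale-bar rectangle, `c(row1,row2,col1,col2)`.
#' @param overlay_dir If non-`NULL`, verification overlays are written there.
#' @return A `sample_record` with the counts, test results, resolved
#'   parameters and any warnings.
#' @export
run_fluorescence <- function(brightfield_path, fluorescent_path,
                             bf_params = seg_params(), fl_params = seg_params(),
                             sample_id = NULL, expected_fraction = 0.75,
                             alpha = 0.05, exclusion_rect = NULL,
                             overlay_dir = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("_BF$", "", tools::file_path_sans_ext(basename(brightfield_path)))
  }
  bf_raw <- read_raster(brightfield_path)
  fl_raw <- read_raster(fluorescent_path)
  if (!identical(dim(to_grayscale(bf_raw)), dim(to_grayscale(fl_raw)))) {
    stop("brightfield and fluorescent images have different dimensions",
         call. = FALSE)
  }
  res <- collect_warnings({
    bf <- remove_scale_bar(invert_image(to_grayscale(bf_raw)), exclusion_rect)
    fl <- remove_scale_bar(to_grayscale(fl_raw), exclusion_rect)
    list(bf = segment_seeds(bf, bf_params), fl = segment_seeds(fl, fl_params))
  })
  segs <- res$value
  counts <- combine_counts(segs$bf$n_seeds, segs$fl$n_seeds)
  stat <- segregation_or_null(counts, expected_fraction, alpha)
  warns <- res$warnings
  if (is.null(stat)) warns <- c(warns, "no seeds detected; statistics skipped")

  if (!is.null(overlay_dir)) {
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
    write_overlay(bf_raw, segs$bf, file.path(overlay_dir, paste0(sample_id, "_BF_overlay.png")))
    write_overlay(fl_raw, segs$fl, file.path(overlay_dir, paste0(sample_id, "_FL_overlay.png")))
  }
  rec <- new_record(sample_id, "fluorescence", counts, stat,
                    bf_intensity = segs$bf$intensity_threshold %||% NA_real_,
                    fl_intensity = segs$fl$intensity_threshold %||% NA_real_,
                    radial_threshold = segs$bf$radial_threshold,
                    radial_ratio = bf_params$radial_ratio %||% NA_real_,
                    warnings = warns)
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analyse one colorimetric (RUBY-mode) image
#'
#' @param rgb_path RGB image file with a predominantly white background.
#' @param params A [color_params()] object.
#' @param sample_id Sample label (defaults to the file name).
#' @param expected_fraction,alpha Passed to [chi_squared_segregation()].
#' @param overlay_dir If non-`NULL`, a verification overlay is written there
#'   with RUBY seeds outlined in a second colour.
#' @return A `sample_record`.
#' @export
run_colorimetric <- function(rgb_path, params = color_params(),
                             sample_id = NULL, expected_fraction = 0.75,
                             alpha = 0.05, overlay_dir = NULL) {
  if (is.null(sample_id)) {
    sample_id <- sub("_RGB$", "", tools::file_path_sans_ext(basename(rgb_path)))
  }
  img <- read_raster(rgb_path)
  res <- collect_warnings(classify_colorimetric(img, params))
  cls <- res$value
  counts <- combine_counts(cls$n_total, cls$n_ruby)
  stat <- segregation_or_null(counts, expected_fraction, alpha)
  warns <- res$warnings
  if (is.null(stat)) warns <- c(warns, "no seeds detected; statistics skipped")

  if (!is.null(overlay_dir) && !is.null(cls$segmentation)) {
    dir.create(overlay_dir, recursive = TRUE, showWarnings = FALSE)
    write_overlay(img, cls$segmentation,
                  file.path(overlay_dir, paste0(sample_id, "_overlay.png")),
                  highlight = cls$ruby_labels)
  }
  new_record(sample_id, "colorimetric", counts, stat,
             bf_intensity = cls$L_threshold, fl_intensity = cls$b_threshold,
             radial_threshold = if (is.null(cls$segmentation)) NA_real_ else
               cls$segmentation$radial_threshold,
             radial_ratio = params$seg$radial_ratio %||% NA_real_,
             warnings = warns)
}

#' Manually adjust the counts of a sample record
#'
#' Replaces the automated counts with reviewer-corrected values and recomputes
#' the chi-squared test; the record is flagged `manually_adjusted`.
#'
#' @param record A `sample_record`.
#' @param corrected_total,corrected_transgenic Replacement counts; `NULL`
#'   keeps the automated value.
#' @return The updated `sample_record`.
#' @export
adjust_counts <- function(record, corrected_total = NULL,
                          corrected_transgenic = NULL) {
  stopifnot(inherits(record, "sample_record"))
  if (is.null(corrected_total) && is.null(corrected_transgenic)) return(record)
  nt <- corrected_total %||% record$n_total
  nm <- corrected_transgenic %||% record$n_transgenic
  counts <- seed_counts(nt, nm)  # validates non-negative, transgenic <= total
  stat <- segregation_or_null(counts, record$expected_fraction %||% 0.75,
                              if (is.na(record$alpha)) 0.05 else record$alpha)
  record$n_total <- counts$n_total
  record$n_transgenic <- counts$n_transgenic
  record$n_wildtype <- counts$n_wildtype
  record$chi2 <- if (is.null(stat)) NA_real_ else stat$chi2_statistic
  record$p_value <- if (is.null(stat)) NA_real_ else stat$p_value
  record$call <- if (is.null(stat)) NA_character_ else stat$call
  record$direction <- if (is.null(stat)) NA_character_ else stat$direction
  record$expected_fraction <- if (is.null(stat)) record$expected_fraction else
    stat$expected_fraction
  record$manually_adjusted <- TRUE
  record
}

record_to_row <- function(rec) {
  data.frame(sample_id = rec$sample_id, mode = rec$mode,
             n_total = rec$n_total, n_transgenic = rec$n_transgenic,
             n_wildtype = rec$n_wildtype, chi2 = rec$chi2,
             p_value = rec$p_value, call = rec$call, direction = rec$direction,
             bf_intensity = as.numeric(rec$bf_intensity),
             fl_intensity = as.numeric(rec$fl_intensity),
             radial_threshold = rec$radial_threshold,
             radial_ratio = rec$radial_ratio,
             manually_adjusted = rec$manually_adjusted,
             warnings = paste(rec$warnings, collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Tabulate sample records
#'
#' @param records A list of `sample_record` objects (or a single one).
#' @return One data frame row per record.
#' @export
records_to_df <- function(records) {
  if (inherits(records, "sample_record")) records <- list(records)
  do.call(rbind, lapply(records, record_to_row))
}

# full-precision CSV: doubles are serialised with %.17g so that reading the
# file back reproduces every value bit-for-bit
#' Write sample records to CSV
#'
#' @param df Data frame from [records_to_df()] (or [run_batch()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.17g", out[[col]]))
    }
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a records CSV written by [write_records_csv()]
#'
#' @param path CSV path.
#' @return Data frame with the same columns and values.
#' @export
read_records_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(sample_id = "character", warnings = "character"))
  for (col in c("chi2", "p_value", "bf_intensity", "fl_intensity",
                "radial_threshold", "radial_ratio")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$warnings[is.na(df$warnings)] <- ""
  df
}

pair_directory <- function(dir, mode) {
  files <- list.files(dir, full.names = TRUE)
  base <- tools::file_path_sans_ext(basename(files))
  if (mode == "fluorescence") {
    bf <- files[grepl("_BF$", base)]
    ids <- sub("_BF$", "", tools::file_path_sans_ext(basename(bf)))
    fl <- vapply(seq_along(bf), function(i) {
      hit <- files[grepl(paste0("^", ids[i], "_FL$"),
                         tools::file_path_sans_ext(basename(files)))]
      if (length(hit) == 0L) NA_character_ else hit[1]
    }, "")
    data.frame(sample_id = ids, brightfield = bf, fluorescent = fl,
               stringsAsFactors = FALSE)
  } else {
    rgb <- files[grepl("_RGB$", base)]
    data.frame(sample_id = sub("_RGB$", "", tools::file_path_sans_ext(basename(rgb))),
               rgb = rgb, stringsAsFactors = FALSE)
  }
}

#' Batch-process a set of samples
#'
#' Processes every sample of a manifest (or of a directory following the
#' `<id>_BF.*` / `<id>_FL.*` - or `<id>_RGB.*` - naming convention) and
#' returns one record row per sample. A failing sample is logged and skipped
#' without aborting the batch; failures are reported in the `"failures"`
#' attribute of the result.
#'
#' @param input A directory path, a manifest CSV path, or a manifest data
#'   frame. Fluorescence manifests need columns `sample_id`, `brightfield`,
#'   `fluorescent`; colorimetric manifests `sample_id`, `rgb`.
#' @param mode `"fluorescence"` or `"colorimetric"`.
#' @param bf_params,fl_params,color_params Parameters passed through to the
#'   per-sample runners.
#' @param expected_fraction,alpha Passed to the segregation test.
#' @param out_csv If non-`NULL`, the records are written there with
#'   [write_records_csv()].
#' @param overlay_dir Passed through to the runners.
#' @param quiet Suppress per-sample progress lines.
#' @return Data frame of records (see [records_to_df()]), with attribute
#'   `failures`: a data frame of `sample_id` and `error` for failed samples.
#' @export
run_batch <- function(input, mode = c("fluorescence", "colorimetric"),
                      bf_params = seg_params(), fl_params = seg_params(),
                      color_params = seedscreen::color_params(),
                      expected_fraction = 0.75, alpha = 0.05,
                      out_csv = NULL, overlay_dir = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  manifest <- if (is.data.frame(input)) {
    input
  } else if (dir.exists(input)) {
    pair_directory(input, mode)
  } else if (file.exists(input)) {
    read.csv(input, stringsAsFactors = FALSE)
  } else {
    stop("input is neither a directory, a manifest file nor a data frame",
         call. = FALSE)
  }
  if (nrow(manifest) == 0L) stop("empty manifest: nothing to process", call. = FALSE)
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample_id in manifest", call. = FALSE)
  }

  recs <- list()
  fails <- data.frame(sample_id = character(), error = character(),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      if (mode == "fluorescence") {
        run_fluorescence(manifest$brightfield[i], manifest$fluorescent[i],
                         bf_params, fl_params, sample_id = sid,
                         expected_fraction = expected_fraction, alpha = alpha,
                         overlay_dir = overlay_dir)
      } else {
        run_colorimetric(manifest$rgb[i], color_params, sample_id = sid,
                         expected_fraction = expected_fraction, alpha = alpha,
                         overlay_dir = overlay_dir)
      }
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      fails <- rbind(fails, data.frame(sample_id = sid,
                                       error = conditionMessage(rec),
                                       stringsAsFactors = FALSE))
      if (!quiet) message(sprintf("[%s] FAILED: %s", sid, conditionMessage(rec)))
    } else {
      recs[[length(recs) + 1L]] <- rec
      if (!quiet) {
        message(sprintf("[%s] %s: %d/%d seeds, p = %.3g (%.2fs)%s",
                        sid, mode, rec$n_transgenic, rec$n_total,
                        rec$p_value, proc.time()[["elapsed"]] - t0,
                        if (length(rec$warnings)) paste0(" [", length(rec$warnings),
                                                         " warning(s)]") else ""))
      }
    }
  }
  df <- if (length(recs) > 0) records_to_df(recs) else NULL
  if (!is.null(out_csv) && !is.null(df)) write_records_csv(df, out_csv)
  if (!quiet && nrow(fails) > 0) {
    message(nrow(fails), " of ", nrow(manifest), " sample(s) failed")
  }
  attr(df, "failures") <- fails
  df
}
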
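#' Segmentation parameters
#'
#' Bundles the tunable parameters of the seed-detection pipeline.
#' `radial_threshold` (in pixels) and `radial_ratio` are mutually exclusive:
#' the ratio expresses the threshold as a fraction of the median detected
#' seed's equivalent radius `sqrt(area / pi)`, which makes it scale-free
#' across seed sizes and magnifications. When neither is given the ratio
#' defaults to 0.4.
#'
#' @param intensity_threshold Real in `[0, 255]`, or `"auto"` for Otsu.
#' @param radial_threshold Fixed radial threshold in pixels (`>= 0`), or `NULL`.
#' @param radial_ratio Radial threshold as a fraction of the median seed's
#'   equivalent radius, in `(0, 1)`, or `NULL`.
#' @param min_area Optional extra minimum region area in pixels^2; when `NULL`
#'   the noise floor is `pi * radial_threshold^2`, implied by the radial filter.
#' @return Object of class `seg_params`.
#' @export
seg_params <- function(intensity_threshold = "auto", radial_threshold = NULL,
                       radial_ratio = NULL, min_area = NULL) {
  if (!identical(intensity_threshold, "auto")) {
    stopifnot(is.numeric(intensity_threshold), length(intensity_threshold) == 1L,
              intensity_threshold >= 0, intensity_threshold <= 255)
  }
  if (!is.null(radial_threshold) && !is.null(radial_ratio)) {
    stop("set at most one of radial_threshold and radial_ratio", call. = FALSE)
  }
  if (!is.null(radial_threshold)) {
    stopifnot(is.numeric(radial_threshold), radial_threshold >= 0)
  }
  if (!is.null(radial_ratio)) {
    stopifnot(is.numeric(radial_ratio), radial_ratio > 0, radial_ratio < 1)
  }
  if (is.null(radial_threshold) && is.null(radial_ratio)) radial_ratio <- 0.4
  if (!is.null(min_area)) stopifnot(is.numeric(min_area), min_area >= 0)
  structure(list(intensity_threshold = intensity_threshold,
                 radial_threshold = radial_threshold,
                 radial_ratio = radial_ratio,
                 min_area = min_area),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat("Segmentation parameters\n")
  cat("  intensity threshold:", format(x$intensity_threshold), "\n")
  if (!is.null(x$radial_threshold)) {
    cat("  radial threshold:   ", x$radial_threshold, "px\n")
  } else {
    cat("  radial ratio:       ", x$radial_ratio, "(threshold derived per image)\n")
  }
  if (!is.null(x$min_area)) cat("  min region area:    ", x$min_area, "px^2\n")
  invisible(x)
}

# per-label region statistics from a label map
region_stats <- function(labels, n, intensity = NULL) {
  if (n == 0L) {
    return(data.frame(label = integer(), area_px = integer(),
                      centroid_r = numeric(), centroid_c = numeric(),
                      eq_radius = numeric(), mean_intensity = numeric()))
  }
  idx <- which(labels > 0L)
  l <- labels[idx]
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- tabulate(l, nbins = n)
  cr <- rowsum(as.numeric(rows), l)[, 1] / area
  cc <- rowsum(as.numeric(cols), l)[, 1] / area
  mi <- if (is.null(intensity)) rep(NA_real_, n) else
    rowsum(as.numeric(intensity[idx]), l)[, 1] / area
  data.frame(label = seq_len(n), area_px = area,
             centroid_r = as.numeric(cr), centroid_c = as.numeric(cc),
             eq_radius = sqrt(area / pi), mean_intensity = mi)
}

#' Label connected components of a binary mask
#'
#' 8-connectivity: diagonally touching foreground pixels belong to the same
#' component, so antialiased seed boundaries are never fragmented. Labels are
#' consecutive integers `1..n` in raster-scan order of first encounter.
#'
#' @param mask Integer 0/1 matrix.
#' @param intensity Optional grayscale image of the same shape; per-region
#'   mean intensity is computed from it.
#' @return List with `labels` (integer matrix), `n_labels`, and `regions`, a
#'   data frame with one row per component: `label`, `area_px`, `centroid_r`,
#'   `centroid_c`, `eq_radius` (`sqrt(area/pi)`), `mean_intensity`.
#' @export
label_components <- function(mask, intensity = NULL) {
  stopifnot(is.matrix(mask))
  lab <- label_components_cpp(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)))
  n <- attr(lab, "n_labels")
  list(labels = lab, n_labels = n, regions = region_stats(lab, n, intensity))
}

#' Derive the radial threshold from detected seed sizes
#'
#' The adaptive rule `t = ratio * r_med`, where `r_med = sqrt(median(area)/pi)`
#' is the equivalent radius of the median-area detected region. Using the
#' median makes the threshold robust to merged clumps and debris, and lets one
#' ratio transfer across species with different seed sizes.
#'
#' @param regions Region data frame from [label_components()].
#' @param ratio Radial threshold ratio in `(0, 1)`.
#' @return The radial threshold in pixels.
#' @export
derive_radial_threshold <- function(regions, ratio) {
  stopifnot(is.numeric(ratio), ratio > 0, ratio < 1)
  if (nrow(regions) == 0L) {
    stop("no regions detected; lower the intensity threshold", call. = FALSE)
  }
  ratio * sqrt(median(regions$area_px) / pi)
}

#' Remove small regions below the radial threshold
#'
#' Keeps exactly the regions whose equivalent radius `sqrt(area/pi)` is at
#' least `radial_threshold`; dirt and other small artifacts fall below it.
#'
#' @param regions Region data frame.
#' @param radial_threshold Radial threshold in pixels (`>= 0`).
#' @return The surviving rows, in their original order.
#' @export
filter_noise <- function(regions, radial_threshold) {
  stopifnot(is.numeric(radial_threshold), radial_threshold >= 0)
  regions[regions$eq_radius >= radial_threshold, , drop = FALSE]
}

#' Morphological opening of a binary mask
#'
#' One opening (erosion then dilation) with a 3x3 structuring element removes
#' isolated pixels and pixel-scale protrusions while leaving convex seed
#' regions essentially unchanged; opening is idempotent.
#'
#' @param mask Integer 0/1 matrix.
#' @return Cleaned 0/1 integer matrix.
#' @export
morphological_clean <- function(mask) {
  stopifnot(is.matrix(mask))
  kern <- EBImage::makeBrush(3, shape = "disc")
  out <- EBImage::opening(mask * 1, kern)  # symmetric kernel: no transpose needed
  matrix(as.integer(out > 0.5), nrow(mask), ncol(mask))
}

#' Chamfer distance transform
#'
#' Two-pass chamfer propagation with local weights 3 (edge) and 4 (diagonal),
#' normalised by 3, approximating the Euclidean distance from each foreground
#' pixel to the nearest background pixel. Background pixels are exactly 0.
#'
#' @param mask Integer 0/1 matrix with at least one background pixel.
#' @return Numeric matrix of distances (pixels).
#' @export
chamfer_distance <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (all(m == 1L)) stop("mask has no background pixel; distance is undefined",
                         call. = FALSE)
  chamfer_cpp(m)
}

#' Build watershed markers from the distance transform
#'
#' Marker cores are the 8-connected components of the set of foreground pixels
#' whose chamfer distance is at least `radial_threshold`. Thresholding the
#' distance map erodes each region inward by `radial_threshold` pixels, so the
#' thin neck between two slightly overlapping seeds drops out and each seed
#' contributes its own core.
#'
#' @param mask Integer 0/1 matrix.
#' @param radial_threshold Distance level in pixels (`>= 0`).
#' @param dist Optional precomputed [chamfer_distance()] of `mask`.
#' @return List with `labels` (marker label map), `n_labels`, `regions`.
#' @export
make_markers <- function(mask, radial_threshold, dist = NULL) {
  stopifnot(is.numeric(radial_threshold), radial_threshold >= 0)
  if (is.null(dist)) dist <- chamfer_distance(mask)
  core <- matrix(as.integer(mask != 0 & dist >= radial_threshold),
                 nrow(mask), ncol(mask))
  mk <- label_components(core)
  if (mk$n_labels == 0L) {
    stop("no watershed markers survive the radial threshold; ",
         "lower the radial threshold (or ratio)", call. = FALSE)
  }
  mk
}

#' Marker-seeded watershed split
#'
#' Floods the negated distance map from the marker cores: basins grow outward
#' from each core, highest distance first, until every foreground pixel of the
#' mask is claimed. The result is a partition of the mask foreground into
#' exactly one region per marker; boundaries fall along the distance-map
#' ridges between touching seeds.
#'
#' @param dist Distance map from [chamfer_distance()].
#' @param mask Integer 0/1 matrix.
#' @param markers Marker label map (positive labels inside the mask foreground).
#' @return Integer label map partitioning the foreground by marker label.
#' @export
watershed_split <- function(dist, mask, markers) {
  stopifnot(is.matrix(dist), is.matrix(mask), is.matrix(markers))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(markers > 0)) stop("watershed requires at least one marker", call. = FALSE)
  if (any(markers > 0 & m == 0L)) {
    stop("markers must lie inside the mask foreground", call. = FALSE)
  }
  out <- watershed_cpp(dist, m, matrix(as.integer(markers), nrow(markers), ncol(markers)))
  # hard guarantees: partition of the foreground, one region per marker
  stopifnot(all((out > 0L) == (m == 1L)),
            identical(sort(unique(out[out > 0L])), sort(unique(markers[markers > 0L]))))
  out
}

# -- contour extraction ------------------------------------------------------
# Crack-boundary tracing: the contour follows pixel edges (corners at
# half-integer coordinates), so every pixel centre of the region lies strictly
# inside its polygon. At a diagonal pinch corner the successor edge bordering
# the *other* pixel is taken, which merges 8-connected diagonals into one loop.
trace_region <- function(rows, cols) {
  # work in a padded local bounding box
  r0 <- min(rows) - 1L; c0 <- min(cols) - 1L
  lr <- rows - r0; lc <- cols - c0
  nr <- max(lr) + 1L; nc <- max(lc) + 1L
  member <- matrix(FALSE, nr, nc)
  member[cbind(lr, lc)] <- TRUE
  pixid <- matrix(0L, nr, nc)
  pixid[cbind(lr, lc)] <- seq_along(lr)

  shift <- function(dr, dc) {
    out <- matrix(FALSE, nr, nc)
    out[max(1, 1 + dr):min(nr, nr + dr), max(1, 1 + dc):min(nc, nc + dc)] <-
      member[max(1, 1 - dr):min(nr, nr - dr), max(1, 1 - dc):min(nc, nc - dc)]
    out
  }
  at <- cbind(lr, lc)
  # neighbour (r+dr, c+dc) lies outside the region
  expo <- function(dr, dc) !shift(-dr, -dc)[at]
  top <- expo(-1, 0); rgt <- expo(0, 1); bot <- expo(1, 0); lft <- expo(0, -1)

  # directed boundary edges, clockwise on screen around each pixel
  er0 <- c(lr[top] - .5, lr[rgt] - .5, lr[bot] + .5, lr[lft] + .5)
  ec0 <- c(lc[top] - .5, lc[rgt] + .5, lc[bot] + .5, lc[lft] - .5)
  er1 <- c(lr[top] - .5, lr[rgt] + .5, lr[bot] + .5, lr[lft] - .5)
  ec1 <- c(lc[top] + .5, lc[rgt] + .5, lc[bot] - .5, lc[lft] - .5)
  epix <- c(which(top), which(rgt), which(bot), which(lft))
  m <- length(epix)
  key <- function(r, c) paste0(r * 2, ":", c * 2)
  starts <- split(seq_len(m), vapply(seq_len(m), function(i) key(er0[i], ec0[i]), ""))
  used <- logical(m)
  loops <- list()
  for (s in seq_len(m)) {
    if (used[s]) next
    path_r <- er0[s]; path_c <- ec0[s]
    cur <- s
    repeat {
      used[cur] <- TRUE
      path_r <- c(path_r, er1[cur]); path_c <- c(path_c, ec1[cur])
      cand <- starts[[key(er1[cur], ec1[cur])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      nxt <- if (length(cand) > 1L) {
        other <- cand[epix[cand] != epix[cur]]
        if (length(other) > 0L) other[1] else cand[1]
      } else cand[1]
      cur <- nxt
    }
    loops[[length(loops) + 1L]] <- cbind(row = path_r + r0, col = path_c + c0)
  }
  # outer boundary = loop with the largest enclosed area
  if (length(loops) == 1L) return(loops[[1]])
  areas <- vapply(loops, function(p) {
    x <- p[, 2]; y <- p[, 1]
    abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  }, 0)
  loops[[which.max(areas)]]
}

#' Extract region contours
#'
#' Traces one closed polygon per label along the pixel-grid edges of the
#' region (vertices at half-integer coordinates), so the polygon encloses
#' every pixel of its label and no pixel of any other label. Used to draw the
#' verification overlays.
#'
#' @param labels Integer label map (0 = background).
#' @return Named list of polygons (matrices with columns `row`, `col`, first
#'   vertex repeated at the end), one per positive label.
#' @export
extract_contours <- function(labels) {
  stopifnot(is.matrix(labels))
  idx <- which(labels > 0L)
  if (length(idx) == 0L) return(list())
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  l <- labels[idx]
  byl <- split(seq_along(l), l)
  out <- lapply(byl, function(k) trace_region(rows[k], cols[k]))
  names(out) <- names(byl)
  out
}

# shared back half of the pipeline: cleaned binary mask -> split seed regions
segment_mask <- function(mask, intensity, params, warnings = character()) {
  empty <- function(msg) {
    warning(msg, call. = FALSE)
    structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                   regions = region_stats(matrix(0L, 1, 1), 0L),
                   contours = list(), n_seeds = 0L,
                   radial_threshold = NA_real_, params = params,
                   warnings = c(warnings, msg)),
              class = "seed_segmentation")
  }
  mask <- morphological_clean(mask)
  comp <- label_components(mask, intensity)
  if (comp$n_labels == 0L) return(empty("no regions detected: 0 seeds"))

  rt <- if (!is.null(params$radial_threshold)) params$radial_threshold else
    derive_radial_threshold(comp$regions, params$radial_ratio)
  keep <- filter_noise(comp$regions, rt)
  if (!is.null(params$min_area)) keep <- keep[keep$area_px >= params$min_area, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop("all regions fall below the radial threshold (", signif(rt, 4),
         " px); lower the radial threshold or intensity threshold", call. = FALSE)
  }
  drop <- setdiff(comp$regions$label, keep$label)
  if (length(drop) > 0L) mask[comp$labels %in% drop] <- 0L

  dist <- chamfer_distance(mask)
  mk <- make_markers(mask, rt, dist = dist)

  # a region whose interior never reaches the radial threshold has no core;
  # it is below the noise floor the threshold defines and is dropped
  has_marker <- unique(comp$labels[mk$labels > 0L])
  orphan <- setdiff(keep$label, has_marker)
  if (length(orphan) > 0L) {
    msg <- paste0(length(orphan), " region(s) without a marker core dropped ",
                  "(max distance below radial threshold)")
    warning(msg, call. = FALSE)
    warnings <- c(warnings, msg)
    mask[comp$labels %in% orphan] <- 0L
  }

  final <- watershed_split(dist, mask, mk$labels)
  n <- max(0L, max(final))
  regions <- region_stats(final, n, intensity)
  structure(list(labels = final, regions = regions,
                 contours = extract_contours(final),
                 n_seeds = nrow(regions), radial_threshold = rt,
                 params = params, warnings = warnings),
            class = "seed_segmentation")
}

#' Detect and count seeds in a preprocessed grayscale image
#'
#' The full fluorescence-mode detection stack: intensity thresholding
#' ([binarize()], threshold from [auto_threshold()] when `"auto"`), a 3x3
#' morphological opening, 8-connected component labelling, the median-area
#' adaptive radial threshold, small-region noise filtering, the chamfer
#' distance transform, marker extraction, marker-seeded watershed splitting of
#' touching seeds, and contour extraction.
#'
#' The input is expected with seeds bright on a dark background: an inverted
#' brightfield frame (see [invert_image()]) or a raw fluorescence frame.
#'
#' @param img Grayscale matrix, 0-255.
#' @param params A [seg_params()] object.
#' @return Object of class `seed_segmentation`: list with `labels` (final
#'   label map), `regions` (per-seed data frame), `contours`, `n_seeds`,
#'   `radial_threshold` (the resolved value in pixels), `params`, `warnings`.
#' @export
segment_seeds <- function(img, params = seg_params()) {
  check_gray(img)
  stopifnot(inherits(params, "seg_params"))
  warnings <- character()
  thr <- params$intensity_threshold
  if (identical(thr, "auto")) {
    thr <- tryCatch(auto_threshold(img), error = function(e) NULL)
    if (is.null(thr)) {
      msg <- "constant image: no threshold separates seeds from background; 0 seeds"
      warning(msg, call. = FALSE)
      return(structure(list(labels = matrix(0L, nrow(img), ncol(img)),
                            regions = region_stats(matrix(0L, 1, 1), 0L),
                            contours = list(), n_seeds = 0L,
                            radial_threshold = NA_real_, params = params,
                            warnings = msg),
                       class = "seed_segmentation"))
    }
  }
  res <- segment_mask(binarize(img, thr), img, params, warnings)
  res$intensity_threshold <- thr
  res
}

#' @export
print.seed_segmentation <- function(x, ...) {
  cat("Seed segmentation:", x$n_seeds, "seeds\n")
  if (!is.na(x$radial_threshold)) {
    cat("  radial threshold:", signif(x$radial_threshold, 4), "px")
    if (is.null(x$params$radial_threshold)) {
      cat(" (ratio", x$params$radial_ratio, "x median equivalent radius)")
    }
    cat("\n")
  }
  if (!is.null(x$intensity_threshold)) {
    cat("  intensity threshold:", x$intensity_threshold, "\n")
  }
  if (x$n_seeds > 0L) {
    cat("  area (px^2): median", round(median(x$regions$area_px)),
        " range", paste(range(x$regions$area_px), collapse = "-"), "\n")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
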
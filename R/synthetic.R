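# Ground-truth scene generation. Scenes emulate a single layer of ~50-200
# Arabidopsis-like seeds poured onto a white weigh boat and photographed on a
# stereomicroscope: elliptical seeds (aspect 1.2-1.8, equivalent radius ~20 px
# at benchmark magnification), lognormal brightness, optional deliberately
# touching/overlapping pairs, Gaussian sensor noise, optional scale bar.

with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic seed scene with known ground truth
#'
#' Places `n_seeds` ellipses on a canvas by rejection sampling. A fraction of
#' the seeds is placed in deliberately touching/overlapping pairs (centre
#' distance uniform in 1.2-1.8 x `radius_mean_px`); all remaining seeds are
#' kept disjoint. Seed classes (`marker` vs `wildtype`) are independent draws
#' at `marker_fraction`. Fully reproducible from `rng_seed`.
#'
#' @param n_seeds Number of seeds (`>= 0`).
#' @param marker_fraction Probability a seed carries the transgenic marker.
#' @param overlap_fraction Fraction of seeds participating in touching pairs
#'   (rounded to whole pairs).
#' @param radius_mean_px Mean equivalent radius in pixels.
#' @param radius_cv Coefficient of variation of the (lognormal) radius.
#' @param canvas `c(height, width)` in pixels, or `NULL` to size automatically
#'   for the requested seed count.
#' @param scale_bar `TRUE` to add a solid scale bar (25% of width x 6 px,
#'   bottom-left), or an explicit `c(row1, row2, col1, col2)` rectangle.
#' @param brightness_preset `"default"`, `"dim"` (faint marker signal, as from
#'   a weak fluorophore/short exposure) or `"bright"` (near-saturating signal).
#' @param rng_seed Integer seed.
#' @return Object of class `synthetic_scene`: `seeds` data frame (`id`, `row`,
#'   `col`, semi-axes `a` >= `b`, `orientation`, `class`, `brightness`,
#'   `pair_id`), `canvas`, `overlap_pairs`, `scale_bar`, `rng_seed`.
#' @export
generate_scene <- function(n_seeds, marker_fraction = 0.75, overlap_fraction = 0,
                           radius_mean_px = 20, radius_cv = 0.15, canvas = NULL,
                           scale_bar = FALSE, brightness_preset = "default",
                           rng_seed = 1) {
  stopifnot(n_seeds >= 0, n_seeds == round(n_seeds),
            marker_fraction >= 0, marker_fraction <= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            radius_mean_px > 0, radius_cv >= 0)
  if (is.null(canvas)) {
    side <- ceiling(sqrt(max(n_seeds, 16) * 22) * radius_mean_px)
    canvas <- c(side, side)
  }
  canvas <- as.integer(canvas)
  bar <- NULL
  if (isTRUE(scale_bar)) {
    bar <- c(canvas[1] - 24L, canvas[1] - 19L, 12L, 12L + as.integer(0.25 * canvas[2]))
  } else if (is.numeric(scale_bar) && length(scale_bar) == 4L) {
    bar <- as.integer(scale_bar)
  }

  bmean <- switch(brightness_preset,
                  default = 200, dim = 70, bright = 245,
                  stop("unknown brightness_preset", call. = FALSE))

  scene <- with_rng_seed(rng_seed, {
    n <- as.integer(n_seeds)
    if (n == 0L) {
      seeds <- data.frame(id = integer(), row = numeric(), col = numeric(),
                          a = numeric(), b = numeric(), orientation = numeric(),
                          class = character(), brightness = numeric(),
                          pair_id = integer())
    } else {
      sdlog <- sqrt(log(1 + radius_cv^2))
      r <- rlnorm(n, meanlog = log(radius_mean_px) - sdlog^2 / 2, sdlog = sdlog)
      aspect <- runif(n, 1.2, 1.8)
      a <- r * sqrt(aspect); b <- r / sqrt(aspect)
      theta <- runif(n, 0, pi)
      cls <- ifelse(rbinom(n, 1, marker_fraction) == 1L, "marker", "wildtype")
      bright <- pmin(250, rlnorm(n, meanlog = log(bmean) - 0.005, sdlog = 0.1))

      n_pairs <- floor(round(n * overlap_fraction) / 2)
      pair_id <- rep(NA_integer_, n)
      if (n_pairs > 0) pair_id[seq_len(2 * n_pairs)] <- rep(seq_len(n_pairs), each = 2)

      row <- col <- rep(NA_real_, n)
      margin <- a + 4
      sep_ok <- function(i, rr, cc, skip = 0L) {
        placed <- which(!is.na(row))
        placed <- setdiff(placed, c(i, skip))
        if (length(placed) == 0L) return(TRUE)
        d2 <- (row[placed] - rr)^2 + (col[placed] - cc)^2
        all(d2 >= (1.1 * (a[placed] + a[i]))^2)
      }
      place_single <- function(i, clear = 0) {
        if (2 * (margin[i] + clear) >= canvas[1] ||
            2 * (margin[i] + clear) >= canvas[2]) return(FALSE)
        for (try in 1:4000) {
          rr <- runif(1, margin[i] + clear, canvas[1] - margin[i] - clear)
          cc <- runif(1, margin[i] + clear, canvas[2] - margin[i] - clear)
          if (!is.null(bar) &&
              rr > bar[1] - margin[i] - 6 && rr < bar[2] + margin[i] + 6 &&
              cc > bar[3] - margin[i] - 6 && cc < bar[4] + margin[i] + 6) next
          if (sep_ok(i, rr, cc)) { row[i] <<- rr; col[i] <<- cc; return(TRUE) }
        }
        FALSE
      }
      for (p in seq_len(n_pairs)) {
        i <- 2L * p - 1L; j <- 2L * p
        d <- runif(1, 1.2, 1.8) * radius_mean_px
        ok <- FALSE
        for (try in 1:200) {
          if (!place_single(i, clear = d + a[j])) break
          ang <- runif(1, 0, 2 * pi)
          rr <- row[i] + d * sin(ang); cc <- col[i] + d * cos(ang)
          if (rr > margin[j] && rr < canvas[1] - margin[j] &&
              cc > margin[j] && cc < canvas[2] - margin[j] &&
              sep_ok(j, rr, cc, skip = i)) {
            row[j] <- rr; col[j] <- cc; ok <- TRUE; break
          }
          row[i] <- NA_real_; col[i] <- NA_real_
        }
        if (!ok) stop("canvas too small to place overlapping pair ", p, call. = FALSE)
      }
      for (i in seq_len(n)) {
        if (!is.na(row[i])) next
        if (!place_single(i)) stop("canvas too small to place ", n, " seeds",
                                   call. = FALSE)
      }
      seeds <- data.frame(id = seq_len(n), row = row, col = col, a = a, b = b,
                          orientation = theta, class = cls, brightness = bright,
                          pair_id = pair_id)
    }
    structure(list(seeds = seeds, canvas = canvas,
                   overlap_pairs = if (n == 0L) 0L else
                     as.integer(floor(round(n * overlap_fraction) / 2)),
                   scale_bar = bar, rng_seed = rng_seed),
              class = "synthetic_scene")
  })
  scene
}

#' @export
print.synthetic_scene <- function(x, ...) {
  n <- nrow(x$seeds)
  cat("Synthetic scene:", n, "seeds on a", x$canvas[1], "x", x$canvas[2], "canvas\n")
  if (n > 0L) {
    cat("  marker:", sum(x$seeds$class == "marker"),
        " wild-type:", sum(x$seeds$class == "wildtype"), "\n")
  }
  cat("  overlapping pairs:", x$overlap_pairs,
      " scale bar:", if (is.null(x$scale_bar)) "no" else "yes",
      " rng seed:", x$rng_seed, "\n")
  invisible(x)
}

# antialiased coverage compositing of one ellipse onto matrix channels
# (values is a vector: one value per channel)
paint_ellipse <- function(channels, seed, values) {
  H <- nrow(channels[[1]]); W <- ncol(channels[[1]])
  ext <- max(seed$a, seed$b) + 2
  r1 <- max(1L, floor(seed$row - ext)); r2 <- min(H, ceiling(seed$row + ext))
  c1 <- max(1L, floor(seed$col - ext)); c2 <- min(W, ceiling(seed$col + ext))
  if (r1 > r2 || c1 > c2) return(channels)
  rr <- r1:r2; cc <- c1:c2
  dr <- matrix(rr - seed$row, length(rr), length(cc))
  dc <- matrix(cc - seed$col, length(rr), length(cc), byrow = TRUE)
  ct <- cos(seed$orientation); st <- sin(seed$orientation)
  x <- dc * ct + dr * st
  y <- -dc * st + dr * ct
  q <- sqrt((x / seed$a)^2 + (y / seed$b)^2)
  cov <- pmin(1, pmax(0, (1 - q) * seed$b + 0.5))  # ~1 px soft edge
  for (k in seq_along(channels)) {
    channels[[k]][rr, cc] <- channels[[k]][rr, cc] * (1 - cov) + values[k] * cov
  }
  channels
}

finish_image <- function(m, noise_sd) {
  if (noise_sd > 0) m <- m + matrix(rnorm(length(m), 0, noise_sd), nrow(m))
  matrix(round(pmin(255, pmax(0, m))), nrow(m), ncol(m))
}

#' Render the brightfield/fluorescence image pair of a scene
#'
#' Brightfield: all seeds dark on a light background (the raw microscope
#' convention; invert before segmenting). Fluorescent: only marker-class
#' seeds, bright on a dark background. Edges are antialiased, Gaussian pixel
#' noise is added, and the scene's scale bar (if any) is drawn dark on the
#' brightfield frame and bright on the fluorescent frame. Rendering is
#' byte-identical across calls for a given scene.
#'
#' @param scene A [generate_scene()] object.
#' @param noise_sd Gaussian pixel noise standard deviation (0-255 scale).
#' @param bg_level Brightfield background intensity.
#' @return List with `brightfield` and `fluorescent` grayscale matrices.
#' @export
render_fluorescence_pair <- function(scene, noise_sd = 3, bg_level = 220) {
  stopifnot(inherits(scene, "synthetic_scene"))
  H <- scene$canvas[1]; W <- scene$canvas[2]
  bf <- matrix(bg_level, H, W)
  fl <- matrix(8, H, W)
  for (i in seq_len(nrow(scene$seeds))) {
    s <- scene$seeds[i, ]
    bf <- paint_ellipse(list(bf), s, 255 - s$brightness)[[1]]
    if (s$class == "marker") fl <- paint_ellipse(list(fl), s, s$brightness)[[1]]
  }
  if (!is.null(scene$scale_bar)) {
    b <- scene$scale_bar
    bf[b[1]:b[2], b[3]:b[4]] <- 25
    fl[b[1]:b[2], b[3]:b[4]] <- 230
  }
  with_rng_seed((scene$rng_seed + 104729L) %% 2147483647L, {
    list(brightfield = finish_image(bf, noise_sd),
         fluorescent = finish_image(fl, noise_sd))
  })
}

# per-class base colors: brown-yellow wild-type seed coat, dark betalain-red
# RUBY (CIELAB: wt L* ~54, b* ~51; ruby L* ~28, b* ~23)
.wt_rgb <- c(170, 120, 35)
.ruby_rgb <- c(130, 25, 35)

#' Render the colorimetric (RUBY-mode) image of a scene
#'
#' White background; wild-type seeds in saturated yellow hues, marker (RUBY)
#' seeds in dark red hues, with per-seed hue jitter. The two palettes are
#' separated by well over 20 CIELAB b* units, as yellow and betalain-red
#' seeds are.
#'
#' @param scene A [generate_scene()] object.
#' @param noise_sd Gaussian pixel noise standard deviation per channel.
#' @return RGB array (`height x width x 3`), 0-255.
#' @export
render_colorimetric <- function(scene, noise_sd = 2) {
  stopifnot(inherits(scene, "synthetic_scene"))
  H <- scene$canvas[1]; W <- scene$canvas[2]
  ch <- list(matrix(250, H, W), matrix(250, H, W), matrix(250, H, W))
  n <- nrow(scene$seeds)
  with_rng_seed((scene$rng_seed + 224737L) %% 2147483647L, {
    if (n > 0L) {
      jit <- matrix(runif(3 * n, -12, 12), n, 3)
      for (i in seq_len(n)) {
        s <- scene$seeds[i, ]
        base <- if (s$class == "marker") .ruby_rgb else .wt_rgb
        ch <- paint_ellipse(ch, s, pmin(255, pmax(0, base + jit[i, ])))
      }
    }
    out <- array(0, dim = c(H, W, 3))
    for (k in 1:3) out[, , k] <- finish_image(ch[[k]], noise_sd)
    out
  })
}

#' Write a scene's images and ground-truth table to disk
#'
#' Materializes standard PNG fixtures plus a truth CSV (`seed id`, centre,
#' semi-axes, class) for a scene, using the `<id>_BF.png` / `<id>_FL.png`
#' pairing convention understood by [run_batch()] (fluorescence mode) or
#' `<id>_RGB.png` (colorimetric mode).
#'
#' @param scene A [generate_scene()] object.
#' @param dir Output directory (created if needed).
#' @param sample_id Sample identifier used in file names.
#' @param mode `"fluorescence"` or `"colorimetric"`.
#' @param noise_sd Passed to the renderer.
#' @return Invisibly, the paths written.
#' @export
write_scene_fixtures <- function(scene, dir, sample_id = paste0("scene", scene$rng_seed),
                                 mode = c("fluorescence", "colorimetric"),
                                 noise_sd = 3) {
  mode <- match.arg(mode)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  if (mode == "fluorescence") {
    pair <- render_fluorescence_pair(scene, noise_sd = noise_sd)
    paths["bf"] <- file.path(dir, paste0(sample_id, "_BF.png"))
    paths["fl"] <- file.path(dir, paste0(sample_id, "_FL.png"))
    write_raster(pair$brightfield, paths["bf"])
    write_raster(pair$fluorescent, paths["fl"])
  } else {
    img <- render_colorimetric(scene, noise_sd = noise_sd)
    paths["rgb"] <- file.path(dir, paste0(sample_id, "_RGB.png"))
    write_raster(img, paths["rgb"])
  }
  paths["truth"] <- file.path(dir, paste0(sample_id, "_truth.csv"))
  write.csv(scene$seeds, paths["truth"], row.names = FALSE)
  invisible(paths)
}
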
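# generic Otsu on arbitrary real values, binned into 256 equal-width bins.
# Returns the threshold (bin upper edge) and eta, the fraction of the total
# variance explained by the split (the bimodality guard statistic).
otsu_values <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0L || diff(range(v)) == 0) {
    stop("cannot auto-threshold a constant plane", call. = FALSE)
  }
  rng <- range(v)
  bin <- pmin(255L, as.integer(floor((v - rng[1]) / diff(rng) * 256)))
  h <- tabulate(bin + 1L, nbins = 256L)
  n <- length(v)
  mids <- rng[1] + (0:255 + 0.5) / 256 * diff(rng)
  w0 <- cumsum(as.numeric(h)); m0 <- cumsum(as.numeric(h) * mids)
  mu <- m0[256]; w1 <- n - w0
  num <- (mu * w0 - m0 * n)^2
  den <- w0 * w1
  sb <- ifelse(den > 0, num / den / n^2, -Inf)        # between-class variance
  k <- which.max(sb)
  tot <- sum(h * (mids - mu / n)^2) / n               # total variance
  mu0 <- m0[k] / w0[k]
  mu1 <- (mu - m0[k]) / w1[k]
  list(threshold = rng[1] + k / 256 * diff(rng), eta = sb[k] / tot,
       gap = mu1 - mu0)
}

#' Colorimetric classification parameters
#'
#' @param L_threshold Lightness threshold in `[0, 100]` separating seeds
#'   (darker) from the white background, or `"auto"` for Otsu on the L* plane.
#' @param b_threshold CIELAB b* threshold separating red RUBY seeds (low b*)
#'   from yellow wild-type seeds (high b*), or `"auto"` for Otsu on the seed
#'   pixels' b* values (guarded by a bimodality check).
#' @param seg A [seg_params()] object; its radial settings drive the noise
#'   filter and watershed exactly as in fluorescence mode (its intensity
#'   threshold is ignored - `L_threshold` plays that role).
#' @return Object of class `color_params`.
#' @export
color_params <- function(L_threshold = "auto", b_threshold = "auto",
                         seg = seg_params()) {
  if (!identical(L_threshold, "auto")) {
    stopifnot(is.numeric(L_threshold), L_threshold >= 0, L_threshold <= 100)
  }
  if (!identical(b_threshold, "auto")) stopifnot(is.numeric(b_threshold))
  stopifnot(inherits(seg, "seg_params"))
  structure(list(L_threshold = L_threshold, b_threshold = b_threshold, seg = seg),
            class = "color_params")
}

#' Segment and classify seeds in a colorimetric (RUBY-mode) image
#'
#' The image is converted to CIELAB. Seeds are darker than the white
#' background, so the seed mask is `L* < L_threshold`; the radial threshold,
#' noise filter and marker-seeded watershed are then applied to that mask
#' exactly as in fluorescence mode. Each final seed region is classified RUBY
#' iff its mean b* is below `b_threshold` (red pigment sits far below yellow
#' on the blue-yellow axis); the region mean makes the call robust to
#' specular highlights.
#'
#' With `b_threshold = "auto"`, Otsu runs on the seed pixels' b* histogram but
#' is only accepted if the split explains at least half of the b* variance
#' (`eta >= 0.5`); a single-class seed population fails that bimodality guard
#' and an explicit `b_threshold` is demanded instead.
#'
#' @param img RGB array, 0-255, predominantly white background.
#' @param params A [color_params()] object.
#' @return Object of class `color_classification`: `segmentation` (the
#'   all-seed `seed_segmentation`), `regions` (per-seed data frame with
#'   `mean_b` and `class`), `ruby_labels`, counts `n_total` / `n_ruby`, and
#'   the resolved `L_threshold` / `b_threshold`.
#' @export
classify_colorimetric <- function(img, params = color_params()) {
  if (!is_rgb(img)) stop("colorimetric mode requires an RGB image", call. = FALSE)
  stopifnot(inherits(params, "color_params"))
  lab <- to_cielab(img)

  empty <- function(msg) {
    warning(msg, call. = FALSE)
    structure(list(segmentation = NULL,
                   regions = cbind(region_stats(matrix(0L, 1, 1), 0L),
                                   mean_b = numeric(), class = character()),
                   ruby_labels = integer(), n_total = 0L, n_ruby = 0L,
                   L_threshold = NA_real_, b_threshold = NA_real_,
                   warnings = msg),
              class = "color_classification")
  }

  Lt <- params$L_threshold
  if (identical(Lt, "auto")) {
    if (diff(range(lab$L)) == 0) {
      if (mean(lab$L) >= 90) {
        return(empty("blank white image: 0 seeds"))
      }
      stop("L* plane is constant; cannot auto-threshold", call. = FALSE)
    }
    Lt <- otsu_values(lab$L)$threshold
  }

  # seeds are dark on white: foreground = L* below threshold
  mask <- matrix(as.integer(lab$L < Lt), nrow(lab$L), ncol(lab$L))
  if (!any(mask == 1L)) return(empty("no pixels below the L* threshold: 0 seeds"))
  seg <- segment_mask(mask, lab$L, params$seg)
  if (seg$n_seeds == 0L) {
    return(empty("no seed regions after segmentation: 0 seeds"))
  }

  seedpix <- seg$labels > 0L
  # the ~1 px antialiased rim blends seed colour toward the white background;
  # the b* histogram uses interior pixels so the rim cannot smear the modes
  interior <- seedpix & chamfer_distance(matrix(as.integer(seedpix),
                                                nrow(seedpix))) >= 2
  if (sum(interior) < 100L) interior <- seedpix
  bt <- params$b_threshold
  if (identical(bt, "auto")) {
    ot <- otsu_values(lab$b[interior])
    # two guards against fabricating a split on a single-class population:
    # the split must explain most of the b* variance AND the two class means
    # must be at least 10 b* units apart (red betalain sits well over 20
    # units below yellow seed coat; natural within-class spread does not)
    if (ot$eta < 0.5 || ot$gap < 10) {
      stop("b* histogram of seed pixels is not bimodal (eta = ",
           signif(ot$eta, 3), ", class-mean gap = ", signif(ot$gap, 3),
           " b* units); supply an explicit b_threshold", call. = FALSE)
    }
    bt <- ot$threshold
  }

  idx <- which(seedpix)
  mean_b <- rowsum(lab$b[idx], seg$labels[idx])[, 1] /
    tabulate(seg$labels[idx], nbins = seg$n_seeds)
  regions <- seg$regions
  regions$mean_b <- as.numeric(mean_b[regions$label])
  regions$class <- ifelse(regions$mean_b < bt, "ruby", "wildtype")
  ruby <- regions$label[regions$class == "ruby"]

  structure(list(segmentation = seg, regions = regions,
                 ruby_labels = as.integer(ruby),
                 n_total = seg$n_seeds, n_ruby = length(ruby),
                 L_threshold = Lt, b_threshold = bt,
                 warnings = seg$warnings),
            class = "color_classification")
}

#' @export
print.color_classification <- function(x, ...) {
  cat("Colorimetric seed classification\n")
  cat(sprintf("  %d seeds: %d RUBY (red), %d wild-type (yellow)\n",
              x$n_total, x$n_ruby, x$n_total - x$n_ruby))
  cat(sprintf("  L* threshold %.2f, b* threshold %.2f\n",
              x$L_threshold, x$b_threshold))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
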
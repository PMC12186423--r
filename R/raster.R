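# Images are plain R objects on the 0-255 scale:
#   grayscale -> numeric matrix, [row, col]
#   RGB       -> numeric array, [row, col, channel]
# Row 1 is the top image row. Binary masks are integer 0/1 matrices.

is_rgb <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L
is_gray <- function(img) is.matrix(img) && is.numeric(img)

check_gray <- function(img) {
  if (!is_gray(img)) stop("expected a grayscale image (numeric matrix)", call. = FALSE)
  invisible(img)
}

#' Read a raster image
#'
#' Reads an 8-bit PNG, TIFF or JPEG file and returns it on the 0-255 scale:
#' a numeric matrix for grayscale input, or a `height x width x 3` array for
#' RGB input. Images with an alpha channel are returned without it; inputs
#' with more than 8 bits per channel are linearly rescaled to 0-255 with a
#' warning.
#'
#' @param path Path to a PNG/TIFF/JPEG file.
#' @return Numeric matrix (grayscale) or array (RGB), values in `[0, 255]`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (max(dat) > 1 + 1e-9) {
    warning("input exceeds 8-bit range; rescaling linearly to 0-255")
    dat <- dat / max(dat)
  }
  if (length(dim(dat)) == 2L) return(round(t(dat) * 255))
  nch <- dim(dat)[3]
  if (nch >= 3L) {
    out <- aperm(dat[, , 1:3, drop = FALSE], c(2, 1, 3))
    return(round(out * 255))
  }
  round(t(dat[, , 1]) * 255) # single-channel stored as 3-d
}

#' Write an image to a file
#'
#' @param img Grayscale matrix or RGB array on the 0-255 scale.
#' @param path Output path; format follows the file extension (.png, .tif, .jpg).
#' @return `path`, invisibly.
#' @export
write_raster <- function(img, path) {
  v <- pmin(pmax(img / 255, 0), 1)
  obj <- if (is_rgb(img)) {
    EBImage::Image(aperm(v, c(2, 1, 3)), colormode = "Color")
  } else {
    EBImage::Image(t(v))
  }
  EBImage::writeImage(obj, path)
  invisible(path)
}

#' Convert an RGB image to grayscale
#'
#' Uses the ITU-R BT.601 luminance weights `0.299 R + 0.587 G + 0.114 B`,
#' rounded to the nearest integer. Grayscale input is returned unchanged.
#'
#' @param img RGB array or grayscale matrix, 0-255.
#' @return Grayscale matrix, 0-255.
#' @export
to_grayscale <- function(img) {
  if (is_gray(img)) return(img)
  if (!is_rgb(img)) stop("expected an RGB array or grayscale matrix", call. = FALSE)
  matrix(round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]),
         dim(img)[1], dim(img)[2])
}

#' Invert a grayscale image
#'
#' Maps every pixel value `v` to `255 - v`. Brightfield frames are inverted so
#' that seeds are bright on a dark background, the convention the rest of the
#' segmentation pipeline assumes.
#'
#' @param img Grayscale matrix, 0-255.
#' @return Inverted grayscale matrix.
#' @export
invert_image <- function(img) {
  check_gray(img)
  if (is.integer(img)) 255L - img else 255 - img
}

# modal (most frequent) rounded intensity; used as the in-paint level
modal_intensity <- function(img) {
  tab <- tabulate(as.integer(round(img)) + 1L, nbins = 256L)
  which.max(tab) - 1L
}

#' Remove a scale bar from a grayscale image
#'
#' Microscope scale bars are long, thin, solid and sit against the image
#' border; seeds are none of those things. Any bright connected component
#' touching the border with bounding-box aspect ratio above `aspect_min` and
#' bounding-box fill solidity above `solidity_min` is painted over with the
#' image's modal intensity. An explicit `exclusion_rect` is painted over
#' unconditionally.
#'
#' @param img Grayscale matrix (seeds bright on dark background).
#' @param exclusion_rect Optional `c(row1, row2, col1, col2)` rectangle to
#'   blank out regardless of content.
#' @param aspect_min,solidity_min Detection thresholds for automatic removal.
#' @return The image with any detected bar replaced by background.
#' @export
remove_scale_bar <- function(img, exclusion_rect = NULL,
                             aspect_min = 8, solidity_min = 0.95) {
  check_gray(img)
  bg <- modal_intensity(img)
  if (!is.null(exclusion_rect)) {
    r <- as.integer(exclusion_rect)
    img[r[1]:r[2], r[3]:r[4]] <- bg
  }
  thr <- tryCatch(auto_threshold(img), error = function(e) NULL)
  if (is.null(thr)) return(img)
  lab <- label_components_cpp(binarize(img, thr))
  n <- attr(lab, "n_labels")
  if (n == 0L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  for (l in seq_len(n)) {
    idx <- which(lab == l, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    touches <- rr[1] == 1L || cc[1] == 1L || rr[2] == nr || cc[2] == nc
    if (!touches) next
    h <- rr[2] - rr[1] + 1L; w <- cc[2] - cc[1] + 1L
    aspect <- max(h, w) / min(h, w)
    solidity <- nrow(idx) / (h * w)
    if (aspect > aspect_min && solidity > solidity_min) img[idx] <- bg
  }
  img
}

#' Threshold a grayscale image into a binary mask
#'
#' A pixel is foreground iff its value is strictly greater than
#' `intensity_threshold`, so the foreground set is non-increasing in the
#' threshold and threshold 255 is always empty.
#'
#' @param img Grayscale matrix, 0-255.
#' @param intensity_threshold Real in `[0, 255]`.
#' @return Integer 0/1 matrix, same shape as `img`.
#' @export
binarize <- function(img, intensity_threshold) {
  check_gray(img)
  if (!is.numeric(intensity_threshold) || length(intensity_threshold) != 1L ||
      is.na(intensity_threshold) ||
      intensity_threshold < 0 || intensity_threshold > 255) {
    stop("intensity_threshold must be a single value in [0, 255]", call. = FALSE)
  }
  m <- matrix(0L, nrow(img), ncol(img))
  m[img > intensity_threshold] <- 1L
  m
}

#' Automatic intensity threshold (Otsu's method)
#'
#' Returns the threshold `t` in `0..255` maximizing the between-class variance
#' of the rounded intensity histogram, where the classes are pixels `<= t` and
#' pixels `> t` (matching [binarize()]'s strict comparison). Ties are broken
#' toward the lowest maximizing threshold.
#'
#' @param img Grayscale matrix, 0-255 (values are rounded for the histogram).
#' @return A single threshold value.
#' @export
auto_threshold <- function(img) {
  check_gray(img)
  h <- tabulate(as.integer(round(img)) + 1L, nbins = 256L)
  if (sum(h > 0) < 2L) {
    stop("image has fewer than two distinct intensity values; cannot auto-threshold",
         call. = FALSE)
  }
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(as.numeric(h))           # pixels <= t
  m0 <- cumsum(as.numeric(h) * lev)     # intensity mass <= t
  mu <- m0[256]
  w1 <- n - w0
  # between-class variance; undefined where either class is empty
  num <- (mu * w0 - m0 * n)^2
  den <- as.numeric(w0) * as.numeric(w1)
  sb <- ifelse(den > 0, num / den, -Inf)
  lev[which.max(sb)]                    # which.max takes the first (lowest) maximizer
}

# vectorized IEC sRGB (D65) -> CIE XYZ -> CIELAB
srgb_to_lab <- function(r, g, b) {
  lin <- function(u) ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  R <- lin(r / 255); G <- lin(g / 255); B <- lin(b / 255)
  X <- 0.4124564 * R + 0.3575761 * G + 0.1804375 * B
  Y <- 0.2126729 * R + 0.7151522 * G + 0.0721750 * B
  Z <- 0.0193339 * R + 0.1191920 * G + 0.9503041 * B
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(X / 0.95047); fy <- f(Y); fz <- f(Z / 1.08883)
  list(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Convert an RGB image to CIELAB planes
#'
#' Standard sRGB (D65 white point) to CIELAB conversion: gamma expansion,
#' linear RGB to XYZ, then the CIELAB nonlinearity. White `(255,255,255)` maps
#' to `L* = 100, a* = b* = 0`.
#'
#' @param img RGB array, 0-255.
#' @return Object of class `lab_planes`: list with matrices `L` (0-100), `a`
#'   and `b`, each the shape of the input image.
#' @export
to_cielab <- function(img) {
  if (!is_rgb(img)) stop("expected an RGB array", call. = FALSE)
  lab <- srgb_to_lab(img[, , 1], img[, , 2], img[, , 3])
  d <- dim(img)[1:2]
  out <- list(L = matrix(lab$L, d[1], d[2]),
              a = matrix(lab$a, d[1], d[2]),
              b = matrix(lab$b, d[1], d[2]))
  class(out) <- "lab_planes"
  out
}
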
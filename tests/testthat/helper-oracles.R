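# Independent oracles used across the suite. Deliberately naive: each one
# re-derives the quantity from its definition, by enumeration or brute force,
# without touching the package's implementation path.

# 8-connected labelling by explicit stack-based flood fill
flood_fill_labels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
            mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# two labelings describe the same partition (bijective label correspondence)
same_partition <- function(a, b) {
  if (!all((a > 0L) == (b > 0L))) return(FALSE)
  pairs <- unique(cbind(a[a > 0L], b[b > 0L]))
  anyDuplicated(pairs[, 1]) == 0L && anyDuplicated(pairs[, 2]) == 0L
}

# exact nearest-background Euclidean distance for every foreground pixel
brute_force_dist <- function(mask) {
  fg <- which(mask == 1L, arr.ind = TRUE)
  bg <- which(mask == 0L, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(fg) == 0L) return(out)
  d2 <- outer(fg[, 1], bg[, 1], "-")^2 + outer(fg[, 2], bg[, 2], "-")^2
  out[fg] <- sqrt(apply(d2, 1, min))
  out
}

# exhaustive 256-candidate search of the between-class variance criterion
otsu_brute_force <- function(img) {
  v <- as.integer(round(img))
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (length(g0) == 0L || length(g1) == 0L) next
    sb <- length(g0) * length(g1) * (mean(g0) - mean(g1))^2
    if (sb > best) { best <- sb; bt <- t }   # first strict max = lowest tie
  }
  bt
}

# even-odd ray casting; polygon is a closed matrix with columns row, col
point_in_polygon <- function(pr, pc, poly) {
  y <- poly[, 1]; x <- poly[, 2]
  n <- nrow(poly) - 1L
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((y[i] > pr) != (y[j] > pr) &&
        pc < (x[j] - x[i]) * (pr - y[i]) / (y[j] - y[i]) + x[i]) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

random_mask <- function(nr, nc, p = 0.4) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}

disk_mask <- function(nr, nc, cr, cc, r) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  matrix(as.integer((rr - cr)^2 + (cc_ - cc)^2 <= r^2), nr, nc)
}

# deterministically force exact class counts onto a generated scene
force_marker_count <- function(scene, n_marker) {
  n <- nrow(scene$seeds)
  stopifnot(n_marker <= n)
  scene$seeds$class <- rep("wildtype", n)
  scene$seeds$class[seq_len(n_marker)] <- "marker"
  scene
}

# translate a grayscale image, padding with its modal intensity
translate_image <- function(img, dr, dc) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- as.numeric(names(sort(table(img), decreasing = TRUE))[1])
  out <- matrix(pad, nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1 & src_r <= nr; ok_c <- src_c >= 1 & src_c <= nc
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
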
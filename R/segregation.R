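#' Seed count tally
#'
#' @param n_total Total seeds counted (brightfield or colorimetric all-seed count).
#' @param n_transgenic Marker-positive seeds (fluorescent or RUBY count).
#' @return Object of class `seed_counts` with `n_total`, `n_transgenic`,
#'   `n_wildtype = n_total - n_transgenic`.
#' @export
seed_counts <- function(n_total, n_transgenic) {
  stopifnot(length(n_total) == 1L, length(n_transgenic) == 1L,
            n_total >= 0, n_transgenic >= 0,
            n_total == round(n_total), n_transgenic == round(n_transgenic))
  if (n_transgenic > n_total) {
    stop("marker seed count (", n_transgenic, ") exceeds total seed count (",
         n_total, "); the two channels disagree - re-tune the intensity ",
         "thresholds of one of them", call. = FALSE)
  }
  structure(list(n_total = as.integer(n_total),
                 n_transgenic = as.integer(n_transgenic),
                 n_wildtype = as.integer(n_total - n_transgenic)),
            class = "seed_counts")
}

#' Combine the two channel counts
#'
#' The brightfield (or colorimetric L*) segmentation counts all seeds; the
#' fluorescent (or b*) channel counts the marker-positive subset.
#'
#' @param n_total_from_brightfield All-seed count.
#' @param n_marker Marker-positive seed count.
#' @return A [seed_counts()] object.
#' @export
combine_counts <- function(n_total_from_brightfield, n_marker) {
  seed_counts(n_total_from_brightfield, n_marker)
}

#' @export
print.seed_counts <- function(x, ...) {
  cat("Seed counts: ", x$n_total, " total = ", x$n_transgenic,
      " transgenic + ", x$n_wildtype, " wild-type\n", sep = "")
  invisible(x)
}

#' Expected transgenic seed fraction for k independent loci
#'
#' A selfed T1 plant hemizygous at `k` independent dominant marker loci yields
#' a marker-positive T2 fraction of `1 - (1/4)^k`: 3:1 (0.75) for a single
#' locus, 15:1 (0.9375) for two.
#'
#' @param k_loci Non-negative integer number of independently segregating loci
#'   (vectorized).
#' @return Expected marker-positive fraction(s).
#' @export
expected_transgenic_fraction <- function(k_loci) {
  stopifnot(all(k_loci >= 0), all(k_loci == round(k_loci)))
  1 - 0.25^k_loci
}

#' Classify a line from its segregation p-value
#'
#' The decision rule: a p-value strictly below `alpha` rejects the
#' single-locus null (multiple independently segregating T-DNA loci, or
#' transgene silencing); otherwise the line is consistent with a single locus.
#'
#' @param p_value P-value in `[0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return `"rejected"` or `"single_locus_consistent"`.
#' @export
classify_line <- function(p_value, alpha = 0.05) {
  stopifnot(p_value >= 0, p_value <= 1, alpha > 0, alpha < 1)
  if (p_value < alpha) "rejected" else "single_locus_consistent"
}

#' Chi-squared test of Mendelian segregation
#'
#' Pearson's chi-squared goodness-of-fit test of the observed
#' transgenic/wild-type counts against the expected marker-positive fraction
#' (default 0.75, the 3:1 single-locus null). Two categories, expected counts
#' `(f N, (1-f) N)`, no continuity correction, p-value from the upper tail of
#' the chi-squared distribution with 1 degree of freedom.
#'
#' @param counts A [seed_counts()] object (or the result of [combine_counts()]).
#' @param expected_fraction Null marker-positive fraction in `(0, 1)`.
#' @param alpha Significance level for the call.
#' @return Object of class `segregation_result`: the counts, observed and
#'   expected fractions, `chi2_statistic`, `p_value`, the `call`
#'   (`"single_locus_consistent"` or `"rejected"`), and `direction`
#'   (`"excess_transgenic"`, `"deficit_transgenic"` or `"exact"`). An excess
#'   points toward multiple loci (two independent loci give 15:1); a deficit
#'   can reflect transgene silencing.
#' @export
chi_squared_segregation <- function(counts, expected_fraction = 0.75, alpha = 0.05) {
  stopifnot(inherits(counts, "seed_counts"),
            expected_fraction > 0, expected_fraction < 1)
  if (counts$n_total == 0L) {
    stop("no seeds counted; cannot test segregation", call. = FALSE)
  }
  ct <- suppressWarnings(
    chisq.test(c(counts$n_transgenic, counts$n_wildtype),
               p = c(expected_fraction, 1 - expected_fraction))
  )
  chi2 <- unname(ct$statistic)
  p <- unname(ct$p.value)
  obs <- counts$n_transgenic / counts$n_total
  direction <- if (obs > expected_fraction) "excess_transgenic"
  else if (obs < expected_fraction) "deficit_transgenic"
  else "exact"
  structure(list(counts = counts,
                 observed_fraction = obs,
                 expected_fraction = expected_fraction,
                 chi2_statistic = chi2,
                 p_value = p,
                 alpha = alpha,
                 call = classify_line(p, alpha),
                 direction = direction),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  c0 <- x$counts
  cat("Segregation test (Pearson chi-squared, 1 df)\n")
  cat(sprintf("  counts: %d transgenic / %d wild-type (n = %d)\n",
              c0$n_transgenic, c0$n_wildtype, c0$n_total))
  cat(sprintf("  observed fraction %.4f vs expected %.4f (%s)\n",
              x$observed_fraction, x$expected_fraction, x$direction))
  cat(sprintf("  chi2 = %.4g, p = %.4g\n", x$chi2_statistic, x$p_value))
  verdict <- if (x$call == "rejected") {
    extra <- if (x$direction == "excess_transgenic") {
      " (excess: consistent with multiple loci, e.g. 15:1 for two)"
    } else if (x$direction == "deficit_transgenic") {
      " (deficit: possible transgene silencing)"
    } else ""
    paste0("REJECTED at alpha = ", x$alpha, extra)
  } else {
    paste0("consistent with a single T-DNA locus (p >= ", x$alpha, ")")
  }
  cat("  call:", verdict, "\n")
  invisible(x)
}
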
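#' Pearson correlation between two signal tracks
#'
#' Product-moment correlation over windows with finite values in both
#' tracks (optionally restricted to a mask), with the two-sided t-test
#' p-value on n - 2 degrees of freedom.
#'
#' @param trackA,trackB `signal_track`s on the same grid.
#' @param mask Optional logical vector or [call_enriched()] result
#'   restricting the analysis universe.
#' @return Object of class `h3_correlation` with fields `r`, `n`, `df`,
#'   `p`, `method`; supports [tidy()] and [glance()].
#' @export
track_pearson <- function(trackA, trackB, mask = NULL) {
  check_same_grid(trackA, trackB)
  a <- trackA$value
  b <- trackB$value
  if (!is.null(mask)) {
    if (is.data.frame(mask)) mask <- mask$enriched
    a[!mask] <- NA_real_
    b[!mask] <- NA_real_
  }
  pearson_cor(a, b)
}

#' Pearson correlation of two numeric vectors
#'
#' @param a,b Numeric vectors of equal length; non-finite pairs dropped.
#' @return An `h3_correlation` object.
#' @export
pearson_cor <- function(a, b) {
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) abort("need at least 3 paired finite values")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("zero variance: correlation undefined")
  }
  ct <- cor.test(a, b, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), n = length(a),
                 df = unname(ct$parameter), p = ct$p.value,
                 method = "Pearson product-moment"),
            class = "h3_correlation")
}

#' @export
print.h3_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f (n = %d, df = %d, p %s)\n",
              x$method, x$r, x$n, x$df, format_p(x$p)))
  invisible(x)
}

format_p <- function(p) {
  if (p < 1e-300) "< 1e-300" else sprintf("= %.3g", p)
}

#' Chi-squared test of a 2x2 contingency table
#'
#' Raw Pearson chi-square (no continuity correction), df = 1, upper-tail
#' p-value. Used for enrichment/depletion contrasts such as
#' transcription-factor binding in one repeat class versus the rest.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return Object of class `h3_contingency` with fields `table`, `chi2`,
#'   `df`, `p`; supports [tidy()] and [glance()].
#' @examples
#' chisq_2x2(matrix(c(20, 40, 80, 60), 2))
#' @export
chisq_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0)) abort("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin: chi-squared test undefined")
  }
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  structure(list(table = table, chi2 = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "h3_contingency")
}

#' @export
print.h3_contingency <- function(x, ...) {
  cat(sprintf("Chi-squared = %.1f, df = %d, p %s\n",
              x$chi2, x$df, format_p(x$p)))
  invisible(x)
}

#' Replicate concordance of dissociation-rate tracks
#'
#' Resamples two rate tracks to a common fine resolution (10-bp windows
#' by default), correlates the windows with finite rates in both
#' replicates (i.e. enriched in both), and exports a 2-D histogram of the
#' paired values for density plotting.
#'
#' @param rateA,rateB Rate `signal_track`s on non-overlapping grids over
#'   the same genome.
#' @param resolution Resampling window width in bp, default 10.
#' @param bins Number of histogram bins per axis, default 50.
#' @return List of class `h3_concordance`: `correlation`
#'   (an `h3_correlation`), `density` (tibble `x`, `y`, `count`),
#'   `resolution`.
#' @export
replicate_concordance <- function(rateA, rateB, resolution = 10, bins = 50) {
  a <- resample_track(rateA, width = resolution)
  b <- resample_track(rateB, width = resolution)
  corr <- track_pearson(a, b)
  keep <- is.finite(a$value) & is.finite(b$value)
  av <- a$value[keep]; bv <- b$value[keep]
  brx <- seq(min(av), max(av), length.out = bins + 1)
  bry <- seq(min(bv), max(bv), length.out = bins + 1)
  cx <- cut(av, brx, include.lowest = TRUE, labels = FALSE)
  cy <- cut(bv, bry, include.lowest = TRUE, labels = FALSE)
  dens <- as_tibble(expand.grid(xi = seq_len(bins), yi = seq_len(bins))) |>
    mutate(x = (brx[.data$xi] + brx[.data$xi + 1]) / 2,
           y = (bry[.data$yi] + bry[.data$yi + 1]) / 2,
           count = as.vector(table(factor(cx, seq_len(bins)),
                                   factor(cy, seq_len(bins))))) |>
    select("x", "y", "count")
  structure(list(correlation = corr, density = dens,
                 resolution = resolution),
            class = "h3_concordance")
}

#' @export
print.h3_concordance <- function(x, ...) {
  cat(sprintf("Replicate concordance at %d-bp resolution:\n", x$resolution))
  print(x$correlation)
  invisible(x)
}
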
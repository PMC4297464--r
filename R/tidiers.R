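#' Tidy a correlation result
#'
#' @param x An `h3_correlation`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `n`, `df`, `p.value`, `method`.
#' @method tidy h3_correlation
#' @export
tidy.h3_correlation <- function(x, ...) {
  tibble(estimate = x$r, n = x$n, df = x$df, p.value = x$p,
         method = x$method)
}

#' @rdname tidy.h3_correlation
#' @method glance h3_correlation
#' @export
glance.h3_correlation <- function(x, ...) tidy(x)

#' Tidy a contingency-test result
#'
#' @param x An `h3_contingency`.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`.
#' @method tidy h3_contingency
#' @export
tidy.h3_contingency <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p.value = x$p)
}

#' @rdname tidy.h3_contingency
#' @method glance h3_contingency
#' @export
glance.h3_contingency <- function(x, ...) tidy(x)

#' Tidy a replicate-concordance result
#'
#' @param x An `h3_concordance`.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `n`, `df`, `p.value`,
#'   `resolution`.
#' @method tidy h3_concordance
#' @export
tidy.h3_concordance <- function(x, ...) {
  mutate(tidy(x$correlation), resolution = x$resolution)
}

#' Tidy per-window turnover estimates
#'
#' @param x A `turnover_estimates` tibble.
#' @param ... Unused.
#' @return The estimate table restricted to enriched windows.
#' @method tidy turnover_estimates
#' @export
tidy.turnover_estimates <- function(x, ...) {
  filter(as_tibble(x), .data$enriched)
}

#' Summarise per-window turnover estimates
#'
#' @param x A `turnover_estimates` tibble.
#' @param ... Unused.
#' @return One-row tibble: windows in/out of the analysis universe and
#'   means of the three turnover quantities over enriched windows.
#' @method glance turnover_estimates
#' @export
glance.turnover_estimates <- function(x, ...) {
  e <- filter(as_tibble(x), .data$enriched)
  tibble(n_windows = nrow(x), n_enriched = nrow(e),
         mean_lambda_out = mean(e$lambda_out),
         mean_lambda_raw = mean(e$lambda_raw),
         mean_lambda_equ = mean(e$lambda_equ))
}
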
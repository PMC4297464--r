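#' Plot group-averaged metaprofile curves
#'
#' @param object A `profile_curves` tibble from [mean_profile()].
#' @param ... Unused.
#' @return A ggplot: mean signal against offset from the anchor, one line
#'   per group; negative offsets are upstream of transcription for
#'   oriented profiles.
#' @method autoplot profile_curves
#' @export
autoplot.profile_curves <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$mean,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "offset from anchor (bp)", y = "mean signal",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of the feature-set by track summary matrix
#'
#' @param object A `region_summary` tibble.
#' @param ... Unused.
#' @return A ggplot tile heatmap (red high, blue low), feature sets on
#'   the vertical axis.
#' @method autoplot region_summary
#' @export
autoplot.region_summary <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$track, y = .data$feature_set,
                               fill = .data$mean)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red",
                                  midpoint = mean(object$mean, na.rm = TRUE)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean") +
    ggplot2::theme_minimal()
}

#' Density plot of replicate rate concordance
#'
#' @param object An `h3_concordance` from [replicate_concordance()].
#' @param ... Unused.
#' @return A ggplot 2-D histogram of paired per-window rates, annotated
#'   with the Pearson correlation.
#' @method autoplot h3_concordance
#' @export
autoplot.h3_concordance <- function(object, ...) {
  d <- filter(object$density, .data$count > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = log10(.data$count))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "replicate 1 rate", y = "replicate 2 rate",
      title = sprintf("PCC = %.3f (df = %d)",
                      object$correlation$r, object$correlation$df)) +
    ggplot2::theme_minimal()
}

#' Scatter of estimated versus true decay rates
#'
#' Parameter-recovery diagnostic for the synthetic simulator: per-locus
#' estimated scaled dissociation rate against the generator's true rate,
#' with the logistic curve the estimates should follow.
#'
#' @param estimates A [locus_turnover()] result joined with the truth
#'   table (columns `true_lambda`, `lambda_out`).
#' @param dt Time interval in hours used for the estimates.
#' @return A ggplot.
#' @export
plot_recovery <- function(estimates, dt = 6) {
  ggplot2::ggplot(as_tibble(estimates),
                  ggplot2::aes(x = .data$true_lambda, y = .data$lambda_out)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::stat_function(fun = function(l) 1 / (1 + exp(-l * dt)),
                           colour = "red") +
    ggplot2::labs(x = "true decay rate (1/h)",
                  y = "estimated scaled dissociation rate") +
    ggplot2::theme_minimal()
}
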
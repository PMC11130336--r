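#' Plot a rate-grid scan
#'
#' Log-likelihood and focal-ancestor state probability against the
#' loss/gain rate ratio — the standard evidence display for whether an
#' ancestor possessed the trait across rate regimes.
#'
#' @param object A `rate_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_grid <- function(object, ...) {
  sp <- object$anchor_fit$model$space
  rec <- object$records
  rec$ratio <- rec$loss / rec$gain
  long <- tidyr::pivot_longer(rec, cols = dplyr::all_of(sp$obs_labels),
                              names_to = "state", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ratio, y = .data$probability,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(long, .data$is_mle), size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "loss / gain rate ratio", y = "focal ancestor probability",
      colour = NULL,
      title = "Ancestral state across gain/loss rate regimes",
      subtitle = "point: maximum-likelihood rate pair"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an AIC model comparison
#'
#' @param table Tibble from [aic_table()].
#' @return A ggplot of delta-AIC per model.
#' @export
plot_model_comparison <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(
    x = .data$delta_AIC,
    y = stats::reorder(.data$model, -.data$delta_AIC)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(Delta * AIC), y = NULL,
                  title = "Model comparison (best first)") +
    ggplot2::theme_minimal()
}

#' Plot a confidence region's parameter ranges
#'
#' @param object A `conf_region`.
#' @param ... Unused.
#' @return A ggplot of the per-parameter delta-2 intervals on a log scale.
#' @export
autoplot.conf_region <- function(object, ...) {
  ggplot2::ggplot(object$ranges, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
                            height = 0.25) +
    ggplot2::geom_point(ggplot2::aes(x = .data$mle), size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "rate (events/Myr)", y = NULL,
                  title = paste0("Delta-", object$delta, " likelihood region")) +
    ggplot2::theme_minimal()
}
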
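#' Tidy a fitted hidden-rates model
#'
#' One row per free rate parameter, with the transition each parameter
#' governs spelled out by composite-state labels.
#'
#' @param x An `hrm_fit`.
#' @param ... Unused.
#' @return Tibble `parameter`, `from`, `to`, `estimate` (events/Myr).
#' @export
tidy.hrm_fit <- function(x, ...) {
  M <- x$model$index
  nz <- which(M > 0, arr.ind = TRUE)
  labs <- x$model$space$labels
  tibble::tibble(
    parameter = names(x$theta)[M[nz]],
    from = labs[nz[, 1]],
    to = labs[nz[, 2]],
    estimate = unname(x$theta[M[nz]])
  ) |>
    dplyr::arrange(.data$parameter) |>
    dplyr::distinct()
}

#' One-row summary of a fitted hidden-rates model
#'
#' @param x An `hrm_fit`.
#' @param ... Unused.
#' @return Tibble with `model`, `k`, `loglik`, `AIC`, `AICc`,
#'   `n_restarts`, `converged`, `constrained`.
#' @export
glance.hrm_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name, k = x$k, loglik = x$loglik,
    AIC = x$AIC, AICc = x$AICc,
    n_restarts = nrow(x$restarts),
    converged = any(x$restarts$converged),
    constrained = x$constrained
  )
}

#' Tidy a delta-2 confidence region
#'
#' @param x A `conf_region`.
#' @param ... Unused.
#' @return The per-parameter `ranges` tibble (`parameter`, `mle`, `lower`,
#'   `upper`).
#' @export
tidy.conf_region <- function(x, ...) x$ranges

#' Tidy a transition summary
#'
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return The per-event tibble.
#' @export
tidy.transition_summary <- function(x, ...) x$events

#' One-row summary of a transition count
#' @param x A `transition_summary`.
#' @param ... Unused.
#' @return Tibble `n_gains`, `n_losses`, `n_events`, `n_edges`,
#'   `minimum_counts`.
#' @export
glance.transition_summary <- function(x, ...) {
  tibble::tibble(
    n_gains = x$n_gains, n_losses = x$n_losses,
    n_events = nrow(x$events), n_edges = x$n_edges,
    minimum_counts = x$minimum_counts
  )
}
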
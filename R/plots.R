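#' Plot parameter trajectories across the parametric gauge family
#'
#' One line per model parameter as a function of `eta`, colored by
#' interaction order. Vertical guides mark the trivial (`eta = 0`),
#' equitable (`1/2`), Euclidean (`alpha/(alpha+1)`), and hierarchical
#' (`1`) gauges.
#'
#' @param object An [eta_sweep()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eta_sweep
#' @export
autoplot.eta_sweep <- function(object, ...) {
  spec <- attr(object, "spec")
  guides <- tibble::tibble(
    gauge = c("trivial", "equitable", "euclidean", "hierarchical"),
    eta = c(0, 0.5, spec$alpha / (spec$alpha + 1), 1)
  )
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$eta, y = .data$value,
    group = .data$feature, colour = factor(.data$order)
  )) +
    ggplot2::geom_vline(
      data = guides, ggplot2::aes(xintercept = .data$eta),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(eta), y = "gauge-fixed parameter value",
      colour = "order"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a variance decomposition by interaction order
#'
#' @param object A [variance_decomposition()] result.
#' @param ... Unused.
#' @return A ggplot object (bar chart of variance fractions).
#' @method autoplot variance_table
#' @export
autoplot.variance_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = factor(.data$order), y = .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "interaction order", y = "fraction of landscape variance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot parameter values by interaction order
#'
#' Strip plot of the values of a gauge-fixed parameter vector, one column
#' per interaction order: a quick view of how a gauge distributes weight
#' across orders.
#'
#' @param object A [param_vec()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot param_vec
#' @export
autoplot.param_vec <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$order), y = .data$value
  )) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.7) +
    ggplot2::labs(x = "interaction order", y = "parameter value") +
    ggplot2::theme_minimal()
}

#' Heat map of additive parameters
#'
#' Position-by-character heat map of the order-1 parameters of a model
#' (the usual matrix view of an additive landscape or energy matrix).
#'
#' @param theta A [param_vec()] with order-1 features.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @export
plot_additive_heatmap <- function(theta) {
  spec <- pv_spec(theta)
  idx <- which(spec$order == 1)
  if (base::length(idx) == 0) abort("The model has no additive features.")
  fc <- spec$feature_chars[idx, , drop = FALSE]
  pos <- apply(fc != SG_WILDCARD, 1, which)
  chr <- fc[cbind(seq_along(idx), pos)]
  df <- tibble::tibble(
    position = as.integer(pos),
    character = factor(chr, levels = spec$alphabet),
    value = theta$value[idx]
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$character, fill = .data$value
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "position", y = NULL, fill = expression(theta[lc])) +
    ggplot2::theme_minimal()
}
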
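#' Plot methods
#'
#' `autoplot()` methods for the main result types, in the usual ggplot2
#' idiom: pipe a fitted object straight into a figure.
#'
#' @name srnn-plots
NULL

#' @describeIn srnn-plots synaptic weight matrix as a heatmap (rows are
#'   postsynaptic neurons).
#' @param object the object to plot.
#' @param ... unused.
#' @export
autoplot.rnn_state <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$pre, y = .data$post,
                                 fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "presynaptic neuron", y = "postsynaptic neuron",
                  fill = "J") +
    ggplot2::theme_minimal()
}

#' @describeIn srnn-plots logged session metrics (row-sum normalization,
#'   spectral stability, oracle errors) over learning.
#' @export
autoplot.rnn_session <- function(object, ...) {
  long <- object$log |>
    tidyr::pivot_longer(-c("step", "unstable"), names_to = "metric",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "step", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn srnn-plots occupancy-normalized rate map (line on a ring,
#'   raster on a grid).
#' @export
autoplot.rate_map <- function(object, ...) {
  df <- tidy(object)
  if (object$env$geometry == "grid") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$rate)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_reverse() +
      ggplot2::scale_fill_viridis_c(na.value = "grey80") +
      ggplot2::labs(x = NULL, y = NULL, fill = "rate") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$pos_cm, y = .data$rate)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "position (cm)", y = "rate") +
      ggplot2::theme_minimal()
  }
}

#' Heatmap of a kernel-search error table
#'
#' @param tbl tibble from [kernel_search()].
#' @return A ggplot object faceted by the post->pre sign.
#' @export
plot_kernel_search <- function(tbl) {
  tbl |>
    filter(!.data$delta) |>
    mutate(side = ifelse(.data$sign_minus < 0, "post->pre depression",
                         "post->pre potentiation")) |>
    ggplot2::ggplot(ggplot2::aes(x = factor(.data$tau_plus),
                                 y = factor(.data$tau_minus),
                                 fill = .data$error_clipped)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~side) +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = "tau+ (steps)", y = "tau- (steps)",
                  fill = "min MSE") +
    ggplot2::theme_minimal()
}

#' Stability-sweep summary plot
#'
#' Final maximum real eigenvalue of `J` against the learning gain, with
#' the instability criterion `1 / gamma_b` overlaid.
#'
#' @param sweep tibble from [stability_sweep()].
#' @return A ggplot object.
#' @export
plot_stability_sweep <- function(sweep) {
  crit <- sweep |>
    dplyr::distinct(.data$gamma_b) |>
    mutate(critical = 1 / .data$gamma_b)
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$gamma_b,
                                      y = .data$max_real_eig)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$unstable)) +
    ggplot2::geom_line(data = crit,
                       ggplot2::aes(y = .data$critical),
                       linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "learning gain", y = "max real eigenvalue of J") +
    ggplot2::theme_minimal()
}
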
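#' Dyadic values by contrast side
#'
#' The standard presentation of a categorical or quartile contrast:
#' individual dyad values as jittered points with the side means and their
#' 95% confidence intervals overlaid.
#'
#' @param x A `categorical_contrast` or `quartile_contrast`.
#' @param ylab Axis label for the dyadic values.
#' @return A ggplot object.
#' @export
plot_contrast <- function(x, ylab = "dyadic value") {
  if (inherits(x, "categorical_contrast")) {
    df <- tibble::tibble(
      side = rep(c("different", "same"), c(x$n_different, x$n_same)),
      value = c(x$different_values, x$same_values)
    )
  } else if (inherits(x, "quartile_contrast")) {
    df <- tibble::tibble(
      side = rep(c("low W", "high W"), c(x$n_low, x$n_high)),
      value = c(x$low_values, x$high_values)
    )
  } else {
    abort("`x` must be a categorical_contrast or quartile_contrast.")
  }
  summ <- df |>
    dplyr::group_by(.data$side) |>
    dplyr::summarise(
      mean = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.35, colour = "grey60") +
    ggplot2::geom_pointrange(
      data = summ,
      ggplot2::aes(y = .data$mean,
                   ymin = .data$mean - 1.96 * .data$se,
                   ymax = .data$mean + 1.96 * .data$se),
      colour = "black", linewidth = 0.8
    ) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
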
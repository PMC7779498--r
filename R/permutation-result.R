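# Shared container for permutation-test results.

new_permutation_result <- function(observed, null, p_value, statistic,
                                   scheme, alternative, n_permutations,
                                   seed = NULL, exact = FALSE, extra = list()) {
  structure(
    c(list(
      observed = observed,
      statistic = statistic,
      null = null,
      null_mean = mean(null),
      null_sd = stats::sd(null),
      n_permutations = n_permutations,
      p_value = p_value,
      alternative = alternative,
      scheme = scheme,
      seed = seed,
      exact = exact
    ), extra),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s)\n", x$scheme,
              if (x$exact) "exhaustive" else sprintf("%d permutations", x$n_permutations)))
  cat(sprintf("  %s = %.4g; null mean %.4g (sd %.4g); p = %.4g (%s)\n",
              x$statistic, x$observed, x$null_mean, x$null_sd,
              x$p_value, x$alternative))
  invisible(x)
}

#' One-row summary of a permutation test
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return A tibble with the observed statistic, null mean/sd, p-value,
#'   permutation count, scheme and alternative.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    n_permutations = x$n_permutations,
    p_value = x$p_value,
    alternative = x$alternative,
    scheme = x$scheme
  )
}

#' Null distribution of a permutation test
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot: histogram of the permutation null with the observed
#'   statistic marked.
#' @export
autoplot.permutation_result <- function(object, ...) {
  df <- tibble::tibble(null = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "firebrick",
                        linewidth = 1) +
    ggplot2::labs(
      x = object$statistic, y = "permutations",
      title = sprintf("observed = %.4g, p = %.4g (%s)",
                      object$observed, object$p_value, object$alternative)
    ) +
    ggplot2::theme_minimal()
}
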
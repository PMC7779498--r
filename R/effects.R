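#' Cohen's d with a normal-approximation confidence interval
#'
#' Standardised mean difference `d = (mean(x) - mean(y)) / s_pooled` with
#' the (n-1)-weighted pooled standard deviation, and a confidence interval
#' from the large-sample standard error
#' `SE(d) = sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))`.
#'
#' When the samples are dyadic values the observations are not independent;
#' the CI is computed as if they were (matching the conventional
#' effect-size packages) and the caveat is recorded in the `note` column
#' rather than corrected.
#'
#' Magnitude labels follow the conventional 0.2 / 0.5 / 0.8 bands
#' (negligible / small / medium / large on |d|).
#'
#' @param x,y Numeric samples (first minus second convention).
#' @param ci_level Confidence level.
#' @return A one-row tibble: `d`, `ci_low`, `ci_high`, `n1`, `n2`,
#'   `magnitude`, `ci_level`, `note`.
#' @export
cohens_d <- function(x, y, ci_level = 0.95) {
  ci_level <- check_prob(ci_level, "ci_level")
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) abort("Both samples need at least 2 values.")
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) abort("Pooled standard deviation is zero; d is undefined.")
  d <- (mean(x) - mean(y)) / sqrt(sp2)
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - ci_level) / 2)
  tibble::tibble(
    d = d,
    ci_low = d - z * se,
    ci_high = d + z * se,
    n1 = n1, n2 = n2,
    magnitude = cut(abs(d), c(-Inf, 0.2, 0.5, 0.8, Inf),
                    labels = c("negligible", "small", "medium", "large")),
    ci_level = ci_level,
    note = "CI treats observations as independent (dyadic values are not)"
  )
}
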
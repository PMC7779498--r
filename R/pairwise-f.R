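#' Pairwise between-group F matrix from a fitted DFA
#'
#' For each pair of groups (i, j) the squared Mahalanobis distance between
#' the group means under the pooled within-group covariance of the selected
#' features, `D2_ij`, is converted to the F statistic testing equality of
#' the two centroids:
#'
#' `F_ij = ((N - g - p + 1) / (p * (N - g))) * (n_i * n_j / (n_i + n_j)) * D2_ij`
#'
#' with `N` calls, `g` groups, `p` selected features and group sizes `n_i`.
#' For `g = 2` this is exactly the two-sample Hotelling T-squared F
#' statistic. The (log-transformed) pairwise F is the package's acoustic
#' dissimilarity score: larger values mean more distinct grunts.
#'
#' @param model A non-empty [dfa_stepwise()] fit.
#' @return A [dyad_matrix()] of kind `"pairwise_F"` (zero diagonal).
#' @export
pairwise_f_matrix <- function(model) {
  if (!inherits(model, "stepwise_dfa")) abort("`model` must be a stepwise_dfa fit.")
  if (model$empty) abort("Model selection is empty; no pairwise F is defined.")
  N <- model$N; g <- model$g; p <- model$p
  if (N - g - p + 1 <= 0) {
    abort("N - g - p + 1 must be positive for the pairwise F statistic.")
  }
  Sinv <- tryCatch(chol2inv(chol(model$pooled_cov)),
                   error = function(e) abort(paste(
                     "Singular pooled within-group covariance;",
                     "reduce the number of selected features.")))
  gm <- model$group_means
  n_i <- model$n_i
  scale_f <- (N - g - p + 1) / (p * (N - g))
  f <- matrix(0, g, g, dimnames = list(model$groups, model$groups))
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      d <- gm[i, ] - gm[j, ]
      d2 <- drop(d %*% Sinv %*% d)
      f[i, j] <- f[j, i] <-
        scale_f * (n_i[i] * n_i[j] / (n_i[i] + n_i[j])) * d2
    }
  }
  dyad_matrix(f, ids = model$groups, kind = "pairwise_F")
}

#' Log-transform a pairwise-F matrix into the dissimilarity score
#'
#' Applies the elementwise `ln(1 + F)` transform. The transform is
#' order-preserving, so dyad rankings are unchanged; it tames the long
#' right tail of the F scale before the matrix enters correlation-based
#' tests.
#'
#' @param fmat A [dyad_matrix()] of kind `"pairwise_F"` with all values >= 0.
#' @return A [dyad_matrix()] of kind `"dissimilarity_lnF"`.
#' @export
dissimilarity_from_f <- function(fmat) {
  if (!inherits(fmat, "dyad_matrix") || dyad_kind(fmat) != "pairwise_F") {
    abort("`fmat` must be a dyad_matrix of kind 'pairwise_F'.")
  }
  if (any(fmat < 0)) abort("Negative pairwise F values violate the invariant F >= 0.")
  dyad_matrix(log1p(unclass(fmat)), ids = rownames(fmat),
              kind = "dissimilarity_lnF")
}
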
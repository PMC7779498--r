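#' Classify calls to individuals with a fitted stepwise DFA
#'
#' Linear classification with equal priors: each call is assigned to the
#' group whose mean is closest in Mahalanobis distance under the pooled
#' within-group covariance of the selected features. Leave-one-out
#' validation refits the sufficient statistics (group means and pooled
#' covariance) exactly, excluding the held-out call; individuals
#' contributing a single call are excluded from the held-out set (their
#' call still trains the other folds) and reported.
#'
#' @param model A [dfa_stepwise()] fit with a non-empty selection.
#' @param features The call table to classify (typically the fitting table).
#' @param mode `"resubstitution"` or `"leave_one_out"`.
#' @return A list of class `dfa_classification`: `percent_correct`,
#'   `chance_pct` (= 100/g), `confusion` (tibble: true, predicted, n),
#'   `n_used`, `excluded` (call ids skipped in LOO), `mode`.
#' @export
dfa_classify <- function(model, features,
                         mode = c("resubstitution", "leave_one_out")) {
  mode <- rlang::arg_match(mode)
  if (!inherits(model, "stepwise_dfa")) abort("`model` must be a stepwise_dfa fit.")
  if (model$empty) abort("The model has an empty selection; nothing to classify with.")
  individual <- model$individual
  if (!all(model$selected %in% names(features))) {
    abort("`features` lacks some selected feature columns.")
  }
  X <- as.matrix(features[model$selected])
  grp <- factor(features[[individual]])
  N <- nrow(X)
  g <- nlevels(grp)

  if (mode == "resubstitution") {
    pred <- predict_block(X, grp, X)
    used <- seq_len(N)
  } else {
    counts <- table(grp)
    singletons <- names(counts)[counts < 2L]
    used <- which(!(as.character(grp) %in% singletons))
    pred <- character(N)
    for (r in used) {
      gtr <- droplevels(grp[-r])
      pred[r] <- predict_block(X[-r, , drop = FALSE], gtr,
                               X[r, , drop = FALSE])
    }
    pred <- pred[used]
  }

  truth <- as.character(grp)[used]
  confusion <- dplyr::count(
    tibble::tibble(true = truth, predicted = pred),
    .data$true, .data$predicted, name = "n")
  excluded <- if (mode == "leave_one_out" && length(used) < N) {
    if ("call_id" %in% names(features)) features$call_id[-used]
    else as.character(setdiff(seq_len(N), used))
  } else character(0)

  structure(
    list(
      percent_correct = 100 * mean(pred == truth),
      chance_pct = 100 / g,
      confusion = confusion,
      n_used = length(used),
      excluded = excluded,
      mode = mode
    ),
    class = "dfa_classification"
  )
}

# Equal-prior linear classification: nearest group mean in Mahalanobis
# distance under the pooled within-group covariance of the training data.
predict_block <- function(Xtr, gtr, Xte) {
  gm <- rowsum(Xtr, gtr) / tabulate(gtr, nbins = nlevels(gtr))
  S <- crossprod(Xtr - gm[as.integer(gtr), , drop = FALSE]) /
    (nrow(Xtr) - nlevels(gtr))
  Sinv <- tryCatch(chol2inv(chol(S)),
                   error = function(e) abort(
                     "Singular pooled covariance during classification."))
  # d2[i, k] = (x_i - mu_k)' Sinv (x_i - mu_k), fully vectorised
  A <- Xte %*% Sinv
  d2 <- rowSums(A * Xte) - 2 * tcrossprod(A, gm) +
    rep(rowSums((gm %*% Sinv) * gm), each = nrow(Xte))
  rownames(gm)[max.col(-d2, ties.method = "first")]
}

# Fast leave-one-out correct rate on a balanced table (every class >= 2
# calls, so no level can empty): identical exact refits as
# dfa_classify(), without building the rich result object. Used inside
# the permuted DFA's inner loop.
loo_rate_fast <- function(X, grp) {
  n <- nrow(X)
  labels <- as.character(grp)
  correct <- 0L
  for (r in seq_len(n)) {
    pred <- predict_block(X[-r, , drop = FALSE], grp[-r],
                          X[r, , drop = FALSE])
    if (pred == labels[r]) correct <- correct + 1L
  }
  100 * correct / n
}

#' @export
print.dfa_classification <- function(x, ...) {
  cat(sprintf("DFA classification (%s): %.1f%% correct (chance %.1f%%, n = %d calls)\n",
              x$mode, x$percent_correct, x$chance_pct, x$n_used))
  if (length(x$excluded)) {
    cat(sprintf("  %d single-call individuals excluded from the held-out set\n",
                length(x$excluded)))
  }
  invisible(x)
}
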
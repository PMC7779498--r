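#' Draw a balanced subset of calls
#'
#' Samples exactly `calls_per_class` calls per individual without
#' replacement, removing the imbalance in call contributions before a DFA.
#' Uses the current RNG state, so wrap in [withr::with_seed()] (or pass a
#' seed to [pdfa()]) for reproducibility.
#'
#' @param features A call-level feature table.
#' @param calls_per_class Calls to keep per individual; every individual
#'   must have at least this many.
#' @param individual Name of the grouping column.
#' @return The reduced feature table (`g * calls_per_class` rows).
#' @export
balanced_subset <- function(features, calls_per_class,
                            individual = "individual") {
  calls_per_class <- check_count(calls_per_class, "calls_per_class")
  counts <- table(features[[individual]])
  short <- names(counts)[counts < calls_per_class]
  if (length(short)) {
    abort(sprintf("Individual %s has fewer than %d calls.",
                  short[1], calls_per_class))
  }
  idx <- unlist(lapply(split(seq_len(nrow(features)), features[[individual]]),
                       function(ix) sort(sample(ix, calls_per_class))),
                use.names = FALSE)
  features[sort(idx), , drop = FALSE]
}

#' Permuted DFA: individual discriminability with balanced call counts
#'
#' Tests whether calls can be assigned to individuals above chance while
#' controlling for unequal call contributions. The observed statistic is
#' the mean, over `n_subsets` balanced subsets (`calls_per_class` calls per
#' individual), of the leave-one-out correct-classification rate of a
#' stepwise DFA refit on each subset (re-running feature selection inside
#' each subset avoids selection leakage into the null). The null
#' distribution repeats the identical procedure on tables whose individual
#' labels have been permuted across calls. The p-value uses the add-one
#' correction, so its attainable minimum is `1 / (n_permutations + 1)`.
#'
#' A subset on which no feature qualifies for entry scores the chance rate
#' (100/g %); the number of such subsets is reported.
#'
#' @param features A call-level feature table.
#' @param calls_per_class Calls per individual in each balanced subset;
#'   defaults to the minimum observed class size.
#' @param n_subsets Balanced subsets averaged per table.
#' @param n_permutations Label permutations for the null distribution.
#' @param p_in,p_out Stepwise entry/removal probabilities (see
#'   [dfa_stepwise()]).
#' @param individual Name of the grouping column.
#' @param seed Optional integer seed.
#' @return A `permutation_result` whose statistic is the mean correct
#'   classification in percent, with extra fields `chance_pct`,
#'   `subset_rates`, `n_empty_selections`, `calls_per_class`,
#'   `n_calls_used`.
#' @export
pdfa <- function(features, calls_per_class = NULL, n_subsets = 10,
                 n_permutations = 100, p_in = 0.05, p_out = 0.10,
                 individual = "individual", seed = NULL) {
  n_subsets <- check_count(n_subsets, "n_subsets")
  n_permutations <- check_count(n_permutations, "n_permutations")
  # Canonicalise row order so the statistic does not depend on how the
  # table happens to be sorted.
  if ("call_id" %in% names(features)) {
    features <- features[order(features[[individual]], features$call_id), ,
                         drop = FALSE]
  }
  # plain data.frame: row subsetting in the subset/permutation loop is far
  # cheaper than on a tibble
  features <- as.data.frame(features)
  counts <- table(features[[individual]])
  g <- length(counts)
  if (is.null(calls_per_class)) calls_per_class <- min(counts)
  calls_per_class <- check_count(calls_per_class, "calls_per_class")
  if (calls_per_class > min(counts)) {
    abort(sprintf("`calls_per_class` (%d) exceeds the minimum class size (%d, individual %s).",
                  calls_per_class, min(counts), names(which.min(counts))))
  }
  if (calls_per_class < 2L) {
    abort("`calls_per_class` must be >= 2 for leave-one-out validation.")
  }
  chance <- 100 / g
  n_empty <- 0L

  mean_loo_rate <- function(tbl) {
    rates <- vapply(seq_len(n_subsets), function(s) {
      sub <- balanced_subset(tbl, calls_per_class, individual)
      m <- dfa_stepwise(sub, individual = individual,
                        p_in = p_in, p_out = p_out)
      if (m$empty) {
        n_empty <<- n_empty + 1L
        chance
      } else {
        loo_rate_fast(as.matrix(sub[m$selected]),
                      factor(sub[[individual]]))
      }
    }, numeric(1))
    rates
  }

  with_seed_if(seed, {
    subset_rates <- mean_loo_rate(features)
    observed <- mean(subset_rates)
    null <- vapply(seq_len(n_permutations), function(b) {
      perm <- features
      perm[[individual]] <- sample(perm[[individual]])
      mean(mean_loo_rate(perm))
    }, numeric(1))
    p <- perm_pvalue(observed, null, "greater")
    new_permutation_result(
      observed = observed, null = null, p_value = p,
      statistic = "mean LOO correct classification (%)",
      scheme = "label_permutation", alternative = "greater",
      n_permutations = n_permutations, seed = seed,
      extra = list(chance_pct = chance,
                   subset_rates = subset_rates,
                   n_empty_selections = n_empty,
                   calls_per_class = calls_per_class,
                   n_calls_used = g * calls_per_class)
    )
  })
}
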
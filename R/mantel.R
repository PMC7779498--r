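#' Restricted (within-block) label permutation
#'
#' Shuffles labels uniformly at random within each exchangeability block,
#' never across blocks: the multiset of labels inside every block is
#' preserved on every draw. With a single block (or `blocks = NULL`) this
#' is a plain permutation. Uses the current RNG state.
#'
#' @param labels Vector of labels (e.g. party membership per individual).
#' @param blocks Block label per individual (e.g. gang membership), or
#'   `NULL` for a free permutation.
#' @return The permuted label vector.
#' @export
restricted_permute <- function(labels, blocks = NULL) {
  if (is.null(blocks)) return(sample(labels))
  if (length(blocks) != length(labels) || anyNA(blocks)) {
    abort("Every labelled individual needs a block.")
  }
  out <- labels
  for (ix in split(seq_along(labels), blocks)) {
    out[ix] <- labels[ix][sample.int(length(ix))]
  }
  out
}

# Draw a permutation of indices under a scheme (free / within blocks).
scheme_permutation <- function(n, blocks = NULL) {
  if (is.null(blocks)) return(sample.int(n))
  perm <- seq_len(n)
  for (ix in split(seq_len(n), blocks)) {
    perm[ix] <- ix[sample.int(length(ix))]
  }
  perm
}

#' Mantel matrix correlation test
#'
#' Tests the association of two dyadic matrices by the Pearson correlation
#' of their off-diagonal upper-triangle values, with a null distribution
#' built by simultaneous row/column permutation of the second matrix's
#' individuals. Permutations can be free or restricted to exchangeability
#' blocks (individuals only swap within their block). The p-value uses the
#' add-one correction; with `exact = TRUE` the full permutation set is
#' enumerated instead (identity included), which is feasible for small
#' numbers of individuals.
#'
#' @param a,b [dyad_matrix()] objects over the same individuals.
#' @param n_permutations Random permutations (ignored when `exact`).
#' @param blocks Optional named vector or per-individual vector of block
#'   labels (in `a`'s id order) for restricted permutations.
#' @param alternative `"greater"`, `"less"` or `"two.sided"` (on r).
#' @param exact Enumerate all permutations instead of sampling.
#' @param seed Optional seed.
#' @return A `permutation_result` with statistic `"mantel_r"` and extra
#'   field `n_dyads`.
#' @export
mantel_test <- function(a, b, n_permutations = 1000, blocks = NULL,
                        alternative = c("greater", "less", "two.sided"),
                        exact = FALSE, seed = NULL) {
  alternative <- rlang::arg_match(alternative)
  if (!inherits(a, "dyad_matrix") || !inherits(b, "dyad_matrix")) {
    abort("`a` and `b` must be dyad_matrix objects.")
  }
  b <- align_dyad_matrices(a, b)
  if (!is.null(blocks) && !is.null(names(blocks))) {
    blocks <- blocks[rownames(a)]
  }
  n <- nrow(a)
  va <- upper_values(a)
  keep <- is.finite(va)
  vb <- upper_values(b)
  keep <- keep & is.finite(vb)
  if (sd(va[keep]) == 0 || sd(vb[keep]) == 0) {
    abort("A matrix has zero variance across dyads; the correlation is undefined.")
  }
  bm <- unclass(b)
  stat <- function(perm) {
    vbp <- upper_values(bm[perm, perm])
    ok <- keep & is.finite(vbp)   # dyads with missing values drop pairwise
    cor(va[ok], vbp[ok])
  }
  observed <- stat(seq_len(n))

  if (exact) {
    perms <- if (is.null(blocks)) all_permutations(n)
             else all_block_permutations(blocks)
    null <- vapply(perms, stat, numeric(1))
    p <- exact_pvalue(observed, null, alternative)
    n_perm <- length(perms)
  } else {
    n_perm <- check_count(n_permutations, "n_permutations")
    null <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
      stat(scheme_permutation(n, blocks))
    }, numeric(1)))
    p <- perm_pvalue(observed, null, alternative)
  }
  new_permutation_result(
    observed = observed, null = null, p_value = p, statistic = "mantel_r",
    scheme = if (is.null(blocks)) "free" else "within_blocks",
    alternative = alternative, n_permutations = n_perm, seed = seed,
    exact = exact, extra = list(n_dyads = sum(keep))
  )
}

#' Categorical Mantel test of same-level convergence
#'
#' Tests whether dyadic values differ between same-group and
#' different-group dyads at a social level. The observed statistic is the
#' mean over different-group dyads minus the mean over same-group dyads;
#' for a dissimilarity matrix a positive statistic therefore indicates
#' convergence (same-group calls more similar), while for a relatedness
#' matrix convergence corresponds to a negative statistic (use
#' `alternative = "less"`).
#'
#' The null permutes individuals' labels: freely for `level = "gang"`, and
#' for `level = "party"` with the restricted scheme in which party labels
#' are shuffled only among males of the same gang, and the dyad universe is
#' restricted to same-gang dyads (the between-gang dyads are uninformative
#' about party effects and their membership cannot change under the
#' restricted scheme).
#'
#' @param values A [dyad_matrix()] of dyadic values (dissimilarity or
#'   relatedness). Dyads with missing values are dropped pairwise and
#'   counted in the result.
#' @param structure A social-structure table covering the matrix ids.
#' @param level `"gang"` or `"party"`.
#' @param n_permutations Random label permutations (ignored when `exact`).
#' @param alternative Direction on (different - same): `"greater"` for
#'   convergence in a dissimilarity matrix, `"less"` for a relatedness
#'   matrix, or `"two.sided"`.
#' @param exact Enumerate all label permutations (small groups only).
#' @param seed Optional seed.
#' @return A list of class `categorical_contrast`: the two dyad-value sets,
#'   their means and counts, and the `permutation_result` for the mean
#'   difference.
#' @export
categorical_mantel <- function(values, structure, level = c("gang", "party"),
                               n_permutations = 1000,
                               alternative = c("greater", "less", "two.sided"),
                               exact = FALSE, seed = NULL) {
  level <- rlang::arg_match(level)
  alternative <- rlang::arg_match(alternative)
  structure <- validate_structure(structure)
  if (!setequal(structure$individual, rownames(values))) {
    abort("`structure` and `values` cover different individuals.")
  }
  structure <- structure[match(rownames(values), structure$individual), ]
  n <- nrow(values)
  v <- upper_values(values)
  idx <- which(upper.tri(values), arr.ind = TRUE)

  gang <- structure$gang
  labels <- structure[[level]]
  blocks <- if (level == "party") gang else NULL

  # Dyad universe: all pairs at gang level, same-gang pairs at party level.
  universe <- if (level == "party") {
    gang[idx[, 1]] == gang[idx[, 2]]
  } else rep(TRUE, nrow(idx))
  universe <- universe & is.finite(v)
  n_dropped <- sum(!is.finite(v))
  if (!any(universe)) abort("No dyads in the comparison universe.")

  stat_for <- function(lab) {
    same <- lab[idx[universe, 1]] == lab[idx[universe, 2]]
    if (!any(same) || all(same)) return(NA_real_)
    mean(v[universe][!same]) - mean(v[universe][same])
  }
  same_obs <- labels[idx[universe, 1]] == labels[idx[universe, 2]]
  if (!any(same_obs) || all(same_obs)) {
    abort("One side of the contrast has zero dyads.")
  }
  observed <- stat_for(labels)

  if (exact) {
    perms <- if (is.null(blocks)) all_permutations(n)
             else all_block_permutations(blocks)
    null <- vapply(perms, function(p) stat_for(labels[p]), numeric(1))
    null <- null[!is.na(null)]
    p <- exact_pvalue(observed, null, alternative)
    n_perm <- length(null)
  } else {
    n_perm <- check_count(n_permutations, "n_permutations")
    null <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
      stat_for(restricted_permute(labels, blocks))
    }, numeric(1)))
    null <- null[!is.na(null)]
    p <- perm_pvalue(observed, null, alternative)
  }

  result <- new_permutation_result(
    observed = observed, null = null, p_value = p,
    statistic = "mean(different) - mean(same)",
    scheme = if (is.null(blocks)) "free" else "party_within_gang",
    alternative = alternative, n_permutations = n_perm, seed = seed,
    exact = exact,
    extra = list(level = level, n_dropped_dyads = n_dropped)
  )
  structure(
    list(
      level = level,
      same_values = v[universe][same_obs],
      different_values = v[universe][!same_obs],
      mean_same = mean(v[universe][same_obs]),
      mean_different = mean(v[universe][!same_obs]),
      n_same = sum(same_obs),
      n_different = sum(!same_obs),
      n_dropped_dyads = n_dropped,
      test = result
    ),
    class = "categorical_contrast"
  )
}

#' @export
print.categorical_contrast <- function(x, ...) {
  cat(sprintf("Categorical Mantel contrast at the %s level\n", x$level))
  cat(sprintf("  same (%d dyads): mean %.4g | different (%d dyads): mean %.4g\n",
              x$n_same, x$mean_same, x$n_different, x$mean_different))
  cat(sprintf("  diff - same = %.4g, p = %.4g (%s, %s)\n",
              x$test$observed, x$test$p_value, x$test$alternative,
              x$test$scheme))
  invisible(x)
}

#' Tidy a categorical contrast into one row per side
#'
#' @param x A `categorical_contrast`.
#' @param ... Unused.
#' @return A tibble with columns `side`, `n_dyads`, `mean`.
#' @export
tidy.categorical_contrast <- function(x, ...) {
  tibble::tibble(
    side = c("same", "different"),
    n_dyads = c(x$n_same, x$n_different),
    mean = c(x$mean_same, x$mean_different)
  )
}

#' @export
glance.categorical_contrast <- function(x, ...) {
  dplyr::mutate(glance(x$test), level = x$level,
                mean_same = x$mean_same, mean_different = x$mean_different,
                n_same = x$n_same, n_different = x$n_different)
}

#' Contrast of dyadic values between relatedness quartiles
#'
#' Splits dyads into a high-relatedness set (`W` strictly above the
#' `1 - q` quantile) and a low-relatedness set (`W` strictly below the `q`
#' quantile) and contrasts a second dyadic variable (e.g. acoustic
#' dissimilarity) between the two sets by permuting the high/low labels
#' over the selected dyads. The default alternative `"less"` asks whether
#' highly related dyads are LESS dissimilar (mean(high) - mean(low) < 0).
#'
#' @param w A [dyad_matrix()] of relatedness values.
#' @param d A [dyad_matrix()] of the contrasted values, same individuals.
#' @param q Tail proportion (0 < q < 0.5); `q = 0.25` contrasts quartiles.
#' @param n_permutations Label permutations.
#' @param alternative Direction on mean(high) - mean(low).
#' @param seed Optional seed.
#' @return A list of class `quartile_contrast` with the thresholds, side
#'   sizes and the `permutation_result`.
#' @export
quartile_contrast <- function(w, d, q = 0.25, n_permutations = 1000,
                              alternative = c("less", "greater", "two.sided"),
                              seed = NULL) {
  alternative <- rlang::arg_match(alternative)
  if (q <= 0 || q >= 0.5) abort("`q` must be in (0, 0.5).")
  d <- align_dyad_matrices(w, d)
  vw <- upper_values(w)
  vd <- upper_values(d)
  keep <- is.finite(vw) & is.finite(vd)
  vw <- vw[keep]; vd <- vd[keep]
  lo_thr <- quantile(vw, q, names = FALSE)
  hi_thr <- quantile(vw, 1 - q, names = FALSE)
  high <- vw > hi_thr
  low <- vw < lo_thr
  if (!any(high) || !any(low)) {
    abort(sprintf(paste("Empty quartile side (thresholds %.4g / %.4g; %d ties",
                        "at the thresholds): the split uses strict inequalities."),
                  lo_thr, hi_thr, sum(vw == lo_thr | vw == hi_thr)))
  }
  sel <- high | low
  vals <- vd[sel]
  is_high <- high[sel]
  observed <- mean(vals[is_high]) - mean(vals[!is_high])
  n_perm <- check_count(n_permutations, "n_permutations")
  null <- with_seed_if(seed, vapply(seq_len(n_perm), function(i) {
    ph <- sample(is_high)
    mean(vals[ph]) - mean(vals[!ph])
  }, numeric(1)))
  p <- perm_pvalue(observed, null, alternative)
  result <- new_permutation_result(
    observed = observed, null = null, p_value = p,
    statistic = "mean(high W) - mean(low W)",
    scheme = "dyad_label_permutation", alternative = alternative,
    n_permutations = n_perm, seed = seed,
    extra = list(n_high = sum(is_high), n_low = sum(!is_high))
  )
  structure(
    list(
      q = q, lo_threshold = lo_thr, hi_threshold = hi_thr,
      n_high = sum(is_high), n_low = sum(!is_high),
      n_total = sum(sel),
      mean_high = mean(vals[is_high]), mean_low = mean(vals[!is_high]),
      high_values = vals[is_high], low_values = vals[!is_high],
      test = result
    ),
    class = "quartile_contrast"
  )
}

#' @export
print.quartile_contrast <- function(x, ...) {
  cat(sprintf("Relatedness-quartile contrast (q = %.2f): W > %.3f vs W < %.3f\n",
              x$q, x$hi_threshold, x$lo_threshold))
  cat(sprintf("  high (%d dyads): mean %.4g | low (%d dyads): mean %.4g\n",
              x$n_high, x$mean_high, x$n_low, x$mean_low))
  cat(sprintf("  high - low = %.4g, p = %.4g (%s)\n",
              x$test$observed, x$test$p_value, x$test$alternative))
  invisible(x)
}
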
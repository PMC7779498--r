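#' Simulate a call-level acoustic feature table
#'
#' Generates calls under a nested random-effects model: each feature value is
#' the sum of a gang effect, a party effect, an individual effect and a
#' per-call residual, each drawn from a zero-mean normal with its own
#' standard deviation (shared across features). The number of calls per
#' individual is drawn uniformly from an integer range, emulating the highly
#' unequal call contributions of field recordings.
#'
#' Defaults emulate the study conditions the package is built around:
#' 82 acoustic parameters, 5-127 calls per male, individual signatures
#' dominating the social-level effects.
#'
#' @param structure A social-structure table (see [build_structure()]).
#' @param n_features Number of numeric acoustic features.
#' @param calls_per_ind Integer range `c(min, max)` for calls per individual.
#' @param sigma_gang,sigma_party,sigma_individual,sigma_resid Standard
#'   deviations (per feature, unitless) of the gang, party, individual and
#'   residual components. All must be >= 0.
#' @param seed Optional integer seed (the same seed reproduces the table
#'   exactly).
#' @return A tibble with columns `call_id`, `individual` and `n_features`
#'   numeric feature columns `f001`, `f002`, ...
#' @export
simulate_features <- function(structure,
                              n_features = 82,
                              calls_per_ind = c(5L, 127L),
                              sigma_gang = 0.4,
                              sigma_party = 0.4,
                              sigma_individual = 1,
                              sigma_resid = 2,
                              seed = NULL) {
  structure <- validate_structure(structure)
  n_features <- check_count(n_features, "n_features")
  if (length(calls_per_ind) != 2L || any(calls_per_ind < 1) ||
      calls_per_ind[1] > calls_per_ind[2]) {
    abort("`calls_per_ind` must be c(min, max) with 1 <= min <= max.")
  }
  sig <- c(sigma_gang, sigma_party, sigma_individual, sigma_resid)
  if (any(!is.finite(sig)) || any(sig < 0)) {
    abort("All sigmas must be finite and >= 0.")
  }

  with_seed_if(seed, {
    gangs <- unique(structure$gang)
    parties <- unique(structure$party)
    n_ind <- nrow(structure)

    gang_eff <- matrix(rnorm(length(gangs) * n_features, 0, sigma_gang),
                       nrow = length(gangs), dimnames = list(gangs, NULL))
    party_eff <- matrix(rnorm(length(parties) * n_features, 0, sigma_party),
                        nrow = length(parties), dimnames = list(parties, NULL))
    ind_eff <- matrix(rnorm(n_ind * n_features, 0, sigma_individual),
                      nrow = n_ind, dimnames = list(structure$individual, NULL))

    ind_mean <- gang_eff[structure$gang, , drop = FALSE] +
      party_eff[structure$party, , drop = FALSE] +
      ind_eff

    n_calls <- sample.int(calls_per_ind[2] - calls_per_ind[1] + 1L,
                          n_ind, replace = TRUE) + calls_per_ind[1] - 1L
    row_ind <- rep(seq_len(n_ind), n_calls)
    n_calls_total <- length(row_ind)

    values <- ind_mean[row_ind, , drop = FALSE] +
      matrix(rnorm(n_calls_total * n_features, 0, sigma_resid),
             nrow = n_calls_total)
    colnames(values) <- sprintf("f%03d", seq_len(n_features))

    dplyr::bind_cols(
      tibble::tibble(
        call_id = sprintf("c%05d", seq_len(n_calls_total)),
        individual = structure$individual[row_ind]
      ),
      tibble::as_tibble(values)
    )
  })
}

# Names of the numeric feature columns of a call table.
feature_columns <- function(features, individual = "individual") {
  setdiff(names(features)[vapply(features, is.numeric, logical(1))],
          c(individual, "call_id"))
}

# Validate a call-level feature table for discriminant analysis.
validate_features <- function(features, individual = "individual",
                              min_calls = 2L) {
  if (!is.data.frame(features) || !individual %in% names(features)) {
    abort(sprintf("`features` must be a data frame with an `%s` column.", individual))
  }
  cols <- feature_columns(features, individual)
  if (length(cols) == 0L) abort("No numeric feature columns found.")
  vals <- as.matrix(features[cols])
  if (any(!is.finite(vals))) abort("Feature values must all be finite.")
  counts <- table(features[[individual]])
  if (length(counts) < 2L) abort("Need at least 2 individuals.")
  if (any(counts < min_calls)) {
    abort(sprintf("Every individual needs >= %d calls (violated by %s).",
                  min_calls, names(counts)[which(counts < min_calls)[1]]))
  }
  invisible(cols)
}
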
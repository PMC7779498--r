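#' Build a nested gang/party social structure
#'
#' Constructs the individual -> party -> gang table that defines dyadic
#' membership matrices and permutation blocks for the convergence analysis.
#' Parties are strictly nested within gangs: every party belongs to exactly
#' one gang and every individual to exactly one party.
#'
#' @param gang_party_sizes A list with one element per gang; each element is
#'   an integer vector of party sizes within that gang. Element names (if
#'   present) are used as gang labels, otherwise `gang1`, `gang2`, ...
#' @param id_prefix Prefix for generated individual ids.
#'
#' @return A tibble with columns `individual`, `party`, `gang` (one row per
#'   individual).
#'
#' @examples
#' # The default study design: two gangs of two parties (6+7 and 5+9 males).
#' build_structure(list(mare = c(6, 7), simenti = c(5, 9)))
#' @export
build_structure <- function(gang_party_sizes, id_prefix = "m") {
  if (!is.list(gang_party_sizes) || length(gang_party_sizes) == 0L) {
    abort("`gang_party_sizes` must be a non-empty list of per-gang party-size vectors.")
  }
  sizes <- unlist(gang_party_sizes, use.names = FALSE)
  if (length(sizes) == 0L || any(!is.finite(sizes)) ||
      any(sizes < 1) || any(sizes != floor(sizes))) {
    abort("All party sizes must be positive integers.")
  }
  gang_names <- names(gang_party_sizes) %||% paste0("gang", seq_along(gang_party_sizes))
  if (is.null(names(gang_party_sizes))) names(gang_party_sizes) <- gang_names
  if (any(gang_names == "")) {
    gang_names[gang_names == ""] <- paste0("gang", which(gang_names == ""))
    names(gang_party_sizes) <- gang_names
  }

  rows <- purrr::imap(gang_party_sizes, function(psizes, gname) {
    tibble::tibble(
      gang = gname,
      party = rep(paste0(gname, "_p", seq_along(psizes)), psizes)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$individual <- sprintf("%s%02d", id_prefix, seq_len(nrow(out)))
  out <- dplyr::select(out, "individual", "party", "gang")
  validate_structure(out)
  out
}

#' Default study structure: 27 males, 2 gangs x 2 parties
#'
#' The design used throughout the package examples: a "mare" gang with
#' parties of 6 and 7 males and a "simenti" gang with parties of 5 and 9.
#'
#' @return A 27-row social-structure tibble.
#' @export
default_structure <- function() {
  build_structure(list(mare = c(6, 7), simenti = c(5, 9)))
}

#' Validate a social-structure table
#'
#' Checks the nesting invariants: unique individuals, exactly one party and
#' gang per individual, and every party contained in exactly one gang.
#'
#' @param structure A data frame with columns `individual`, `party`, `gang`.
#' @param require_full When `TRUE`, additionally require at least 2 gangs and
#'   at least 2 parties per gang (needed for the full convergence analysis).
#' @return The validated structure, invisibly coerced to a tibble.
#' @export
validate_structure <- function(structure, require_full = FALSE) {
  if (!is.data.frame(structure) ||
      !all(c("individual", "party", "gang") %in% names(structure))) {
    abort("`structure` must be a data frame with columns individual, party, gang.")
  }
  structure <- tibble::as_tibble(structure)
  if (anyNA(structure[c("individual", "party", "gang")])) {
    abort("Structure contains missing individual/party/gang labels.")
  }
  if (anyDuplicated(structure$individual)) {
    abort("Each individual must appear exactly once in the structure.")
  }
  party_gangs <- dplyr::distinct(structure, .data$party, .data$gang)
  if (anyDuplicated(party_gangs$party)) {
    bad <- party_gangs$party[duplicated(party_gangs$party)]
    abort(sprintf("Nesting violated: party %s appears in more than one gang.", bad[1]))
  }
  if (require_full) {
    n_gangs <- dplyr::n_distinct(structure$gang)
    parties_per_gang <- dplyr::count(party_gangs, .data$gang)$n
    if (n_gangs < 2L || any(parties_per_gang < 2L)) {
      abort("The full analysis needs >= 2 gangs and >= 2 parties per gang.")
    }
  }
  invisible(structure)
}

#' Binary same-membership matrix at a social level
#'
#' Builds the symmetric 0/1 dyadic matrix used as the categorical predictor
#' in the categorical Mantel tests: 1 when two individuals share the same
#' label at `level`, 0 otherwise. The diagonal is set to 1 by convention
#' (an individual trivially shares its own label); all tests use only the
#' off-diagonal dyads.
#'
#' @param structure A social-structure table (see [build_structure()]).
#' @param level `"gang"` or `"party"`.
#' @return A [dyad_matrix()] of kind `"membership"`.
#' @export
membership_matrix <- function(structure, level = c("gang", "party")) {
  level <- rlang::arg_match(level)
  structure <- validate_structure(structure)
  labels <- structure[[level]]
  m <- outer(labels, labels, `==`) * 1
  dyad_matrix(m, ids = structure$individual, kind = "membership")
}

#' Summarise call counts per individual and gang
#'
#' @param features A call-level feature table with columns `individual` and
#'   (optionally, via `structure`) gang membership.
#' @param structure Optional social-structure table used to aggregate call
#'   counts per gang.
#' @return A list with `per_individual` (tibble: individual, n_calls),
#'   `per_gang` (tibble or NULL), and scalar summaries `n_calls_total`,
#'   `mean_calls`, `min_calls`, `max_calls`.
#' @export
summarise_calls <- function(features, structure = NULL) {
  if (!"individual" %in% names(features)) {
    abort("`features` must have an `individual` column.")
  }
  per_ind <- dplyr::count(features, .data$individual, name = "n_calls")
  per_gang <- NULL
  if (!is.null(structure)) {
    structure <- validate_structure(structure)
    per_gang <- per_ind |>
      dplyr::left_join(structure, by = "individual") |>
      dplyr::count(.data$gang, wt = .data$n_calls, name = "n_calls")
  }
  list(
    per_individual = per_ind,
    per_gang = per_gang,
    n_calls_total = sum(per_ind$n_calls),
    mean_calls = mean(per_ind$n_calls),
    min_calls = min(per_ind$n_calls),
    max_calls = max(per_ind$n_calls)
  )
}
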
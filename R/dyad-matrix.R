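#' Symmetric individual-by-individual dyadic matrix
#'
#' The container shared by the acoustic-dissimilarity, relatedness and
#' membership analyses: a symmetric numeric matrix whose rows/columns are
#' individuals, tagged with the kind of quantity it holds.
#'
#' Diagonal conventions: 0 for `pairwise_F` and `dissimilarity_lnF`
#' (an individual is not dissimilar to itself), 1 for `membership` and
#' `relatedness_W` (self-relatedness under the no-inbreeding convention).
#' All dyadic tests operate on the off-diagonal upper triangle only.
#'
#' @param values A symmetric numeric matrix.
#' @param ids Character vector of individual ids (defaults to the matrix
#'   dimnames).
#' @param kind One of `"pairwise_F"`, `"dissimilarity_lnF"`,
#'   `"relatedness_W"`, `"membership"`, `"kinship"`, `"other"`.
#' @param tol Symmetry tolerance.
#' @return An object of class `dyad_matrix` (a named matrix with a `kind`
#'   attribute).
#' @export
dyad_matrix <- function(values, ids = NULL,
                        kind = c("other", "pairwise_F", "dissimilarity_lnF",
                                 "relatedness_W", "membership", "kinship"),
                        tol = 1e-8) {
  kind <- rlang::arg_match(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("Dyadic matrix must be square.")
  ids <- ids %||% rownames(values)
  if (is.null(ids)) abort("Provide `ids` or a matrix with dimnames.")
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) abort("`ids` length must match the matrix dimension.")
  if (anyDuplicated(ids)) abort("Dyadic matrix ids must be unique.")
  finite <- is.finite(values)
  if (any(abs(values - t(values))[finite & t(finite)] > tol, na.rm = TRUE)) {
    abort("Dyadic matrix must be symmetric.")
  }
  dimnames(values) <- list(ids, ids)
  structure(values, class = c("dyad_matrix", "matrix", "array"), kind = kind)
}

#' @export
print.dyad_matrix <- function(x, ...) {
  cat(sprintf("<dyad_matrix: %d individuals, kind = %s>\n",
              nrow(x), attr(x, "kind")))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE],
                    6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows/columns\n", nrow(x) - 6L))
  invisible(x)
}

dyad_kind <- function(x) attr(x, "kind") %||% "other"

#' Tidy a dyadic matrix into one row per dyad
#'
#' @param x A [dyad_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `id1`, `id2`, `value` covering the
#'   upper-triangle (i < j) dyads.
#' @export
tidy.dyad_matrix <- function(x, ...) {
  ids <- rownames(x)
  ut <- upper.tri(x)
  idx <- which(ut, arr.ind = TRUE)
  tibble::tibble(
    id1 = ids[idx[, 1]],
    id2 = ids[idx[, 2]],
    value = x[ut]
  )
}

# Align matrix B to the id ordering of A; errors on mismatched id sets.
align_dyad_matrices <- function(a, b) {
  if (!setequal(rownames(a), rownames(b))) {
    abort("The two dyadic matrices cover different individuals.")
  }
  b_ord <- unclass(b)[rownames(a), rownames(a)]
  dyad_matrix(b_ord, kind = dyad_kind(b))
}

#' Write / read a dyadic matrix as a square CSV with an id header
#'
#' The on-disk format is a square table whose first column (`individual`)
#' holds the row ids and whose remaining column names repeat the ids.
#'
#' @param x A [dyad_matrix()].
#' @param path File path.
#' @return `write_dyad_matrix()` returns `path` invisibly;
#'   `read_dyad_matrix()` returns a [dyad_matrix()].
#' @export
write_dyad_matrix <- function(x, path) {
  df <- tibble::as_tibble(unclass(x), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(individual = rownames(x)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_dyad_matrix
#' @param kind Kind tag to attach on read (the CSV does not store it).
#' @export
read_dyad_matrix <- function(path, kind = "other") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  dyad_matrix(m, ids = ids, kind = kind)
}

#' Heatmap of a dyadic matrix
#'
#' @param object A [dyad_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dyad_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- tidyr::expand_grid(id1 = factor(ids, ids), id2 = factor(ids, ids))
  df$value <- as.vector(unclass(object)[as.matrix(df[, c("id1", "id2")])])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id2, y = .data$id1,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_discrete(limits = rev(ids)) +
    ggplot2::labs(x = NULL, y = NULL, fill = dyad_kind(object)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
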
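# CSV readers/writers for the package's table dialects.

#' Read and write the package's CSV dialects
#'
#' Feature tables are plain CSV (call_id, individual, numeric features).
#' Structure tables are `individual,party,gang`. Genotype tables carry two
#' integer columns per locus (`L01_a1,L01_a2`); 0 encodes a missing allele
#' on disk and is mapped to `NA` on read.
#'
#' @param x The table to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name vocalconv-io
NULL

#' @rdname vocalconv-io
#' @export
write_feature_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname vocalconv-io
#' @export
read_feature_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname vocalconv-io
#' @export
write_structure_csv <- function(x, path) {
  readr::write_csv(validate_structure(x), path)
  invisible(path)
}

#' @rdname vocalconv-io
#' @export
read_structure_csv <- function(path) {
  validate_structure(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname vocalconv-io
#' @export
write_genotype_csv <- function(x, path) {
  out <- dplyr::mutate(x, dplyr::across(dplyr::matches("_a[12]$"),
                                        ~ dplyr::coalesce(.x, 0L)))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname vocalconv-io
#' @export
read_genotype_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  dplyr::mutate(x, dplyr::across(dplyr::matches("_a[12]$"),
                                 ~ dplyr::if_else(.x <= 0L, NA_integer_,
                                                  as.integer(.x))))
}
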
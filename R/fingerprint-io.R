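#' Read and write fingerprint tables
#'
#' Fingerprints CSV: one row per larva, columns `larva_id`, `group`,
#' `reference_group`, then the canonical measure columns. Parameter tables
#' from [larva_parameters()] use the same layout without `reference_group`.
#' Round-trips are lossless.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_fingerprints <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    larva_id = readr::col_character(),
    group = readr::col_character(),
    reference_group = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_fingerprints
#' @param x Fingerprint or parameter tibble.
#' @export
write_fingerprints <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
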
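#' Write a stage report as TSV
#'
#' Writes any stage output tibble to TSV with a deterministic column order
#' (as given) and doubles rendered with 6 significant digits, so that a
#' written report re-read with [read_report()] round-trips its values and
#' byte-identical reruns are possible. An empty tibble yields a header-only
#' file.
#'
#' @param records A tibble (possibly zero-row).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- dplyr::mutate(
    tibble::as_tibble(records),
    dplyr::across(dplyr::where(is.double), ~ signif(.x, 6))
  )
  # render doubles explicitly so the byte stream does not depend on locale
  out <- dplyr::mutate(
    out,
    dplyr::across(dplyr::where(is.double), ~ format_num(.x))
  )
  tryCatch(
    readr::write_tsv(out, path, progress = FALSE),
    error = function(e) rlang::abort(sprintf("cannot write report to '%s': %s", path, conditionMessage(e)))
  )
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
}

#' Read back a TSV stage report
#'
#' @param path Path written by [write_report()].
#' @return Tibble with numeric columns restored.
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, guess_max = Inf)
}
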
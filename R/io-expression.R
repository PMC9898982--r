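#' Read a log2 expression matrix with its sample sheet
#'
#' Reads a genes-by-samples TSV of log2 intensities (first column: gene
#' symbol; remaining columns: sample ids) together with a sample sheet
#' mapping each sample to its disease stage and molecular subgroup, and
#' returns a validated long tibble ready for the expression stage.
#'
#' Control samples must carry stage `"control"` and subgroup `"control"`
#' (the two labels are required to co-occur). Every matrix column must be
#' present in the sample sheet; samples listed in the sheet but absent from
#' the matrix are ignored.
#'
#' @param matrix_path Path to the expression TSV (gene column first).
#' @param sample_sheet_path Path to a TSV with columns `sample_id`, `stage`
#'   (MGUS/SMM/MM/control) and `subgroup` (t(4;14), t(11;14), t(14;16),
#'   t(14;20), D1, D2, control).
#' @return A tibble with columns `gene`, `sample_id`, `stage`, `subgroup`,
#'   `value` (log2 intensity).
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  mat <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
  sheet <- readr::read_tsv(sample_sheet_path, show_col_types = FALSE, progress = FALSE)
  names(mat)[1] <- "gene"
  validate_sample_sheet(sheet)

  dup <- mat$gene[duplicated(mat$gene)]
  if (length(dup) > 0) {
    rlang::abort(sprintf("duplicate gene symbol(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(is.na(mat$gene) | mat$gene == "")) {
    rlang::abort("missing gene symbol in expression matrix")
  }
  missing <- setdiff(names(mat)[-1], sheet$sample_id)
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "matrix sample(s) absent from sample sheet: %s", paste(missing, collapse = ", ")
    ))
  }

  long <- tidyr::pivot_longer(mat, -"gene", names_to = "sample_id", values_to = "value")
  if (!all(is.finite(long$value))) {
    rlang::abort("expression values must be finite log2 intensities")
  }
  out <- dplyr::inner_join(long, sheet, by = "sample_id") |>
    dplyr::select("gene", "sample_id", "stage", "subgroup", "value") |>
    dplyr::arrange(.data$gene, .data$sample_id)
  validate_expression(out)
}

validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "stage", "subgroup")
  if (!all(req %in% names(sheet))) {
    rlang::abort(sprintf(
      "sample sheet must have columns %s", paste(req, collapse = ", ")
    ))
  }
  if (anyDuplicated(sheet$sample_id)) {
    rlang::abort(sprintf(
      "duplicate sample_id(s): %s",
      paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]), collapse = ", ")
    ))
  }
  bad_stage <- setdiff(unique(sheet$stage), c(ren_stages(), ren_control()))
  if (length(bad_stage) > 0) {
    rlang::abort(sprintf("unknown stage label(s): %s", paste(bad_stage, collapse = ", ")))
  }
  bad_sub <- setdiff(unique(sheet$subgroup), c(ren_subgroups(), ren_control()))
  if (length(bad_sub) > 0) {
    rlang::abort(sprintf("unknown subgroup label(s): %s", paste(bad_sub, collapse = ", ")))
  }
  mismatch <- xor(sheet$stage == ren_control(), sheet$subgroup == ren_control())
  if (any(mismatch)) {
    rlang::abort(sprintf(
      "control stage and control subgroup must co-occur; offending sample(s): %s",
      paste(sheet$sample_id[mismatch], collapse = ", ")
    ))
  }
  invisible(sheet)
}

validate_expression <- function(expr) {
  req <- c("gene", "sample_id", "stage", "subgroup", "value")
  if (!all(req %in% names(expr))) {
    rlang::abort(sprintf("expression tibble must have columns %s", paste(req, collapse = ", ")))
  }
  expr
}
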
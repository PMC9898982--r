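#' Read genomic intervals from BED or narrowPeak files
#'
#' Parses BED3+ (chrom, start, end, optional name) or ENCODE narrowPeak
#' (10 columns; `signalValue`... with the -log10 p-value score in column 8)
#' into a sorted interval tibble with 0-based half-open coordinates.
#' narrowPeak input fills the `signal` column from its -log10 p column;
#' plain BED leaves `signal` as `NA`.
#'
#' @param path File path.
#' @param mark Optional chromatin-mark label attached to every interval
#'   (one of [ren_marks()]).
#' @param cell_line Optional cell-line label.
#' @return Tibble with columns `chrom`, `start`, `end`, `name`, `signal`,
#'   and, when given, `mark` and `cell_line`; sorted by (chrom, start).
#' @export
read_intervals <- function(path, mark = NULL, cell_line = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), signal = double()
    )
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncol <- lengths(fields)
    if (any(ncol < 3)) {
      rlang::abort(sprintf("line %d: fewer than 3 BED columns", which(ncol < 3)[1]))
    }
    is_narrowpeak <- all(ncol == 10)
    chrom <- purrr::map_chr(fields, 1)
    start <- parse_coord(purrr::map_chr(fields, 2), "start")
    end <- parse_coord(purrr::map_chr(fields, 3), "end")
    bad <- which(start >= end)
    if (length(bad) > 0) {
      rlang::abort(sprintf("line %d: start (%d) must be < end (%d)", bad[1], start[bad[1]], end[bad[1]]))
    }
    if (any(start < 0)) {
      rlang::abort(sprintf("line %d: negative start coordinate", which(start < 0)[1]))
    }
    name <- ifelse(ncol >= 4, purrr::map_chr(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_), NA_character_)
    signal <- if (is_narrowpeak) {
      # narrowPeak column 8 is the -log10 p-value ("signal p") score
      as.double(purrr::map_chr(fields, 8))
    } else {
      NA_real_
    }
    out <- tibble::tibble(chrom = chrom, start = start, end = end, name = name, signal = signal)
  }
  if (!is.null(mark)) out$mark <- mark
  if (!is.null(cell_line)) out$cell_line <- cell_line
  dplyr::arrange(out, .data$chrom, .data$start, .data$end)
}

parse_coord <- function(x, what) {
  suppressWarnings(num <- as.numeric(x))
  bad <- which(is.na(num) | num != floor(num))
  if (length(bad) > 0) {
    rlang::abort(sprintf("line %d: non-integer %s coordinate '%s'", bad[1], what, x[bad[1]]))
  }
  as.integer(num)
}

#' Read per-CpG methylation from a bedGraph-like file
#'
#' Four columns: chrom, start, end, methylation. The methylation unit is
#' auto-detected: if any value exceeds 1 the column is taken as percent and
#' divided by 100; otherwise it is taken as a fraction. Values outside
#' [0, 100] are rejected.
#'
#' @param path File path.
#' @param group Group label the methylation belongs to (a subgroup or
#'   `"control"`).
#' @return Tibble with columns `chrom`, `start`, `end`, `group`, `meth`
#'   (fraction in [0, 1]), sorted by position.
#' @export
read_cpg_methylation <- function(path, group) {
  assert_groups(group)
  tbl <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "meth"),
    col_types = "ciid", progress = FALSE, comment = "#"
  )
  if (any(tbl$meth < 0 | tbl$meth > 100)) {
    bad <- which(tbl$meth < 0 | tbl$meth > 100)[1]
    rlang::abort(sprintf("line %d: methylation value %g outside [0, 100]", bad, tbl$meth[bad]))
  }
  if (any(tbl$start >= tbl$end)) {
    bad <- which(tbl$start >= tbl$end)[1]
    rlang::abort(sprintf("line %d: start must be < end", bad))
  }
  if (any(tbl$meth > 1)) tbl$meth <- tbl$meth / 100
  tbl |>
    dplyr::mutate(group = group, .before = "meth") |>
    dplyr::arrange(.data$chrom, .data$start)
}
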
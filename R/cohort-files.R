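#' Write a simulated cohort to disk in the formats the readers consume
#'
#' Materialises a synthetic cohort as files: `expression.tsv` +
#' `samples.tsv` (for [read_expression()]), one `cpg_<group>.bedgraph` per
#' group (for [read_cpg_methylation()]; percent values), `dmrs.bed` (BED4),
#' one `peaks_<cell_line>_<mark>.narrowPeak` per mark per cell line (for
#' [read_intervals()]), the three assay tables as long TSVs, and
#' `truth.tsv` serialising the planted effects with the seed in its header.
#'
#' @param truth A [synthetic_truth()] object.
#' @param dir Output directory (created if needed).
#' @inheritParams pipeline_config
#' @return Invisibly, a named list of the paths written.
#' @export
write_cohort <- function(truth, dir, n_per_group = 10, n_control = 4,
                         noise_sd = 0.45, cpg_noise_sd = 5, reps = 3,
                         pyro_sd = 2, ct_sd = 0.05, viab_sd = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(truth$seed)
  paths <- list()

  expr <- simulate_cohort_expression(truth, n_per_group = n_per_group,
                                     n_control = n_control,
                                     noise_sd = noise_sd, seed = NA)
  sheet <- dplyr::distinct(expr, .data$sample_id, .data$stage, .data$subgroup)
  wide <- expr |>
    dplyr::select("gene", "sample_id", "value") |>
    dplyr::mutate(value = signif(.data$value, 6)) |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
  paths$expression <- file.path(dir, "expression.tsv")
  readr::write_tsv(wide, paths$expression, progress = FALSE)
  paths$samples <- file.path(dir, "samples.tsv")
  readr::write_tsv(sheet, paths$samples, progress = FALSE)

  land <- simulate_methylation_landscape(truth, cpg_noise_sd = cpg_noise_sd,
                                         seed = NA)
  for (g in unique(land$cpgs$group)) {
    slug <- gsub("[^0-9A-Za-z]", "", g)
    p <- file.path(dir, sprintf("cpg_%s.bedgraph", slug))
    land$cpgs |>
      dplyr::filter(.data$group == g) |>
      dplyr::transmute(.data$chrom, .data$start, .data$end,
                       meth = sprintf("%.4f", 100 * .data$meth)) |>
      readr::write_tsv(p, col_names = FALSE, progress = FALSE)
    paths[[paste0("cpg_", slug)]] <- p
  }
  paths$dmrs <- file.path(dir, "dmrs.bed")
  land$dmrs |>
    dplyr::transmute(.data$chrom, .data$start, .data$end, name = .data$dmr_id) |>
    readr::write_tsv(paths$dmrs, col_names = FALSE, progress = FALSE)

  for (cl in truth$cell_lines$cell_line) {
    pk <- simulate_chromatin_peaks(truth, cl, seed = NA)
    for (mk in unique(pk$mark)) {
      p <- file.path(dir, sprintf("peaks_%s_%s.narrowPeak", cl, mk))
      pk |>
        dplyr::filter(.data$mark == mk) |>
        dplyr::transmute(.data$chrom, .data$start, .data$end, .data$name,
                         score = 0L, strand = ".", signalValue = .data$signal,
                         pValue = .data$signal, qValue = -1, peak = -1L) |>
        readr::write_tsv(p, col_names = FALSE, progress = FALSE)
      paths[[sprintf("peaks_%s_%s", cl, mk)]] <- p
    }
  }

  assays <- simulate_perturbation_assays(truth, reps = reps, pyro_sd = pyro_sd,
                                         ct_sd = ct_sd, viab_sd = viab_sd,
                                         seed = NA)
  for (nm in names(assays)) {
    p <- file.path(dir, sprintf("assay_%s.tsv", nm))
    write_report(assays[[nm]], p)
    paths[[paste0("assay_", nm)]] <- p
  }

  paths$truth <- file.path(dir, "truth.tsv")
  header <- sprintf("# seed: %d", truth$seed)
  truth_tbl <- truth$effects |>
    dplyr::mutate(kind = "expression_effect", .before = 1)
  readr::write_lines(header, paths$truth)
  readr::write_tsv(truth_tbl, paths$truth, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(paths)
}
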
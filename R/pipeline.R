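# End-to-end orchestration: simulate (or read) a cohort, run the four
# analysis stages in order, and write a reproducible report bundle of TSVs
# plus a run manifest. Stage outputs are files so any stage can be rerun or
# inspected in isolation.

#' Pipeline configuration
#'
#' Thresholds, seed and input directives for [run_pipeline()]. Thresholds
#' default to the screening rules used throughout: log2 fold change 1 at
#' p 0.05, z-difference 2, differential methylation 10 percentage points,
#' R^2 0.4, 50-bp overlaps, peak signal 50.
#'
#' @param seed Integer seed recorded in the manifest and used for all
#'   randomness.
#' @param simulate If `TRUE` (default) a synthetic cohort with planted
#'   truth is generated; otherwise `inputs` must supply the data.
#' @param inputs Optional named list of in-memory inputs (`expr`, `cpgs`,
#'   `dmrs`, `dmr_meth_planted`, `peaks` [named by cell line], `assays`)
#'   built with the `read_*` readers; only consulted when
#'   `simulate = FALSE`.
#' @param thresholds Named list as in [ren_thresholds()].
#' @param n_per_group,n_control,noise_sd,cpg_noise_sd,reps,pyro_sd,ct_sd,viab_sd
#'   Generator settings passed through to the simulators.
#' @return List of class `ren_config`.
#' @export
pipeline_config <- function(seed = 1L, simulate = TRUE, inputs = NULL,
                            thresholds = ren_thresholds(),
                            n_per_group = 10, n_control = 4, noise_sd = 0.45,
                            cpg_noise_sd = 5, reps = 3, pyro_sd = 2,
                            ct_sd = 0.05, viab_sd = 0.05) {
  cfg <- list(
    seed = as.integer(seed), simulate = isTRUE(simulate), inputs = inputs,
    thresholds = utils::modifyList(ren_thresholds(), as.list(thresholds)),
    n_per_group = n_per_group, n_control = n_control, noise_sd = noise_sd,
    cpg_noise_sd = cpg_noise_sd, reps = reps, pyro_sd = pyro_sd,
    ct_sd = ct_sd, viab_sd = viab_sd
  )
  bad <- names(cfg$thresholds)[!vapply(cfg$thresholds, function(x)
    is.numeric(x) && length(x) == 1 && x > 0, logical(1))]
  if (length(bad) > 0) {
    rlang::abort(sprintf("threshold(s) must be positive numbers: %s",
                         paste(bad, collapse = ", ")))
  }
  if (is.na(cfg$seed)) rlang::abort("seed must be an integer")
  structure(cfg, class = "ren_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are
#' rejected. CLI flags (seed) override file values.
#'
#' @param path YAML file.
#' @param seed Optional seed overriding the file value.
#' @return `ren_config` list.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!is.null(seed)) raw$seed <- seed
  do.call(pipeline_config, raw)
}

#' Run the full pipeline
#'
#' Executes simulate -> expression -> methylation -> chromatin ->
#' perturbation and writes the report bundle to `outdir`: `de.tsv`,
#' `panel.tsv`, `meth_report.tsv`, `correlation.tsv`, `overlaps.tsv`,
#' `overlap_shares.tsv`, `states.tsv`, `ctcf.tsv`, `perturb_pyro.tsv`,
#' `perturb_qpcr.tsv`, `perturb_ic50.tsv`, `perturb_viability.tsv` and
#' `manifest.tsv`. Reruns with the same config produce byte-identical
#' bundles.
#'
#' @param config A [pipeline_config()] (or the seed to build one from).
#' @param outdir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a named list of the stage tibbles plus `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, quiet = FALSE) {
  if (!inherits(config, "ren_config")) config <- pipeline_config(seed = config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  set.seed(config$seed)

  truth <- synthetic_truth(seed = config$seed)
  if (config$simulate) {
    say("simulate: cohort with seed %d (%d samples/subgroup/stage)",
        config$seed, config$n_per_group)
    expr <- simulate_cohort_expression(
      truth, n_per_group = config$n_per_group, n_control = config$n_control,
      noise_sd = config$noise_sd, seed = NA
    )
    land <- simulate_methylation_landscape(truth, cpg_noise_sd = config$cpg_noise_sd,
                                           seed = NA)
    peaks <- purrr::map(
      setNames(truth$cell_lines$cell_line, truth$cell_lines$cell_line),
      ~ simulate_chromatin_peaks(truth, .x, seed = NA)
    )
    assays <- simulate_perturbation_assays(
      truth, reps = config$reps, pyro_sd = config$pyro_sd,
      ct_sd = config$ct_sd, viab_sd = config$viab_sd, seed = NA
    )
    cpgs <- land$cpgs
    dmrs <- land$dmrs
  } else {
    inp <- config$inputs
    need <- c("expr", "cpgs", "dmrs", "peaks", "assays")
    miss <- setdiff(need, names(inp))
    if (length(miss) > 0) {
      rlang::abort(sprintf("pipeline inputs missing (and simulate = FALSE): %s",
                           paste(miss, collapse = ", ")))
    }
    expr <- inp$expr; cpgs <- inp$cpgs; dmrs <- inp$dmrs
    peaks <- inp$peaks; assays <- inp$assays
  }

  # --- expression stage -----------------------------------------------------
  say("expression: %d genes x %d samples; thresholds log2fc>%g p<%g zdiff>%g",
      dplyr::n_distinct(expr$gene), dplyr::n_distinct(expr$sample_id),
      th$log2fc, th$p, th$z_diff)
  screen <- expression_screen(expr, lfc = th$log2fc, alpha = th$p,
                              z_threshold = th$z_diff)
  panel <- subgroup_consistency(screen) |>
    dplyr::mutate(subgroups = purrr::map_chr(.data$subgroups, paste, collapse = ";"))
  say("expression: %d upregulated records, %d cross-stage panel genes",
      sum(screen$upregulated), nrow(panel))

  # --- methylation stage ----------------------------------------------------
  dmr_meth <- summarize_dmr(dmrs, cpgs) |>
    differential_methylation(threshold = th$dm)
  mm_medians <- group_medians(expr) |>
    dplyr::filter(.data$stage %in% c("MM", ren_control())) |>
    dplyr::select("gene", group = "subgroup", expr = "median")
  corr <- purrr::map(c("promoter", "body"), function(rc) {
    methylation_expression_correlation(dmr_meth, mm_medians,
                                       region_class = rc, cutoff = th$r2)
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$gene, .data$region_class)
  say("methylation: %d DMRs, %d hypo / %d hyper calls, %d genes pass R2>%g",
      dplyr::n_distinct(dmr_meth$dmr_id), sum(dmr_meth$dm_status == "hypo"),
      sum(dmr_meth$dm_status == "hyper"), sum(corr$passes_cutoff), th$r2)

  # --- chromatin stage ------------------------------------------------------
  chrom <- chromatin_stage(truth, dmrs, dmr_meth, peaks, th)
  say("chromatin: %d overlap records; states: %s", nrow(chrom$overlaps),
      paste(sprintf("%s=%s", chrom$states$cell_line, chrom$states$state)[
        chrom$states$gene == "ITGB7"], collapse = ", "))

  # --- perturbation stage ---------------------------------------------------
  pyro <- pyro_anova(assays$pyro, control = "dCas9_DNMT3A",
                     treated = "dCas9_DNMT3A_sgRNA_Dox", alpha = 0.001)
  qpcr <- purrr::map(
    setdiff(unique(assays$qpcr$condition), "dCas9_DNMT3A"),
    ~ ddct_fold_change(assays$qpcr, target = "ITGB7", reference = "GAPDH",
                       control = "dCas9_DNMT3A", treated = .x)
  ) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$treated)
  ic50 <- purrr::map(sort(unique(assays$viability$condition)), function(cond) {
    f <- fit_ic50(assays$viability, condition = cond)
    dplyr::mutate(glance(f), condition = cond, .before = 1)
  }) |>
    purrr::list_rbind()
  say("perturbation: %d/%d significant CpGs; qPCR folds %s; IC50 %s uM",
      sum(pyro$significant), nrow(pyro),
      paste(sprintf("%.2f", qpcr$fold), collapse = "/"),
      paste(sprintf("%.3f", ic50$ic50), collapse = "/"))

  outputs <- list(
    de = screen, panel = panel, meth_report = dmr_meth, correlation = corr,
    overlaps = chrom$overlaps, overlap_shares = chrom$shares,
    states = chrom$states, ctcf = chrom$ctcf,
    perturb_pyro = pyro, perturb_qpcr = qpcr, perturb_ic50 = ic50,
    perturb_viability = dplyr::arrange(assays$viability, .data$condition,
                                       .data$key, .data$replicate)
  )
  for (nm in names(outputs)) {
    write_report(outputs[[nm]], file.path(outdir, paste0(nm, ".tsv")))
  }

  manifest <- dplyr::bind_rows(
    tibble::tibble(item = "seed", value = as.character(config$seed)),
    tibble::tibble(item = paste0("threshold_", names(th)),
                   value = as.character(unlist(th))),
    tibble::tibble(item = paste0("rows_", names(outputs)),
                   value = as.character(vapply(outputs, nrow, integer(1)))),
    tibble::tibble(item = paste0("stage_", names(outputs)),
                   value = c("expression", "expression", "methylation",
                             "methylation", "chromatin", "chromatin",
                             "chromatin", "chromatin", "perturbation",
                             "perturbation", "perturbation", "perturbation"))
  )
  write_report(manifest, file.path(outdir, "manifest.tsv"))
  invisible(c(outputs, list(manifest = manifest, outdir = outdir)))
}

# classify states and compute overlap statistics for every cell line
chromatin_stage <- function(truth, dmrs, dmr_meth, peaks, th) {
  overlaps <- purrr::imap(peaks, function(pk, cl) {
    sub <- truth$cell_lines$subgroup[truth$cell_lines$cell_line == cl]
    dm <- dmr_meth |>
      dplyr::filter(.data$group == sub, .data$dm_status %in% c("hypo", "hyper"))
    histone_pk <- filter_peaks_by_signal(pk, th$signal) |>
      dplyr::filter(.data$mark %in% c("H3K4me1", "H3K4me3", "H3K27ac",
                                      "H3K36me3", "H3K27me3"))
    recs <- overlap_dmr_marks(dplyr::semi_join(dmrs, dm, by = "dmr_id"),
                              histone_pk, min_overlap = th$overlap_bp)
    if (nrow(recs) == 0) return(NULL)
    dplyr::mutate(recs, cell_line = cl, .before = 1)
  }) |>
    purrr::list_rbind()

  shares <- if (nrow(overlaps) == 0) {
    tibble::tibble(cell_line = character(), mark = character(),
                   n_pairs = integer(), share_pct = double())
  } else {
    overlaps |>
      dplyr::group_by(.data$cell_line) |>
      dplyr::group_modify(~ overlap_fraction_distribution(.x)) |>
      dplyr::ungroup()
  }

  genes <- unique(dmrs$gene)
  grid <- tidyr::expand_grid(cell_line = names(peaks), gene = genes)
  states <- purrr::pmap(grid, function(cell_line, gene) {
    m <- truth$gene_models[truth$gene_models$gene == gene, ]
    sub <- truth$cell_lines$subgroup[truth$cell_lines$cell_line == cell_line]
    dm <- dplyr::filter(dmr_meth, .data$group == sub)
    call <- classify_chromatin_state(
      gene_region = list(chrom = m$chrom, start = m$tss, end = m$gene_end),
      promoter = list(chrom = m$chrom, start = m$tss - 2000L, end = m$tss + 500L),
      peaks = filter_peaks_by_signal(peaks[[cell_line]], th$signal),
      dmr_meth = dm[, c("chrom", "start", "end", "median_meth")]
    )
    tibble::tibble(cell_line = cell_line, gene = gene, state = call$state,
                   domain_span_bp = call$domain_span_bp,
                   domain_meth = call$domain_meth,
                   evidence = paste(names(call$evidence)[call$evidence],
                                    collapse = ";"))
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$cell_line, .data$gene)

  ctcf <- purrr::pmap(grid, function(cell_line, gene) {
    m <- truth$gene_models[truth$gene_models$gene == gene, ]
    pk <- filter_peaks_by_signal(peaks[[cell_line]], th$signal) |>
      dplyr::filter(.data$mark == "CTCF")
    win <- detect_ctcf_window(list(chrom = m$chrom, tss = m$tss,
                                   gene_end = m$gene_end), pk)
    if (is.null(win)) return(NULL)
    tibble::tibble(cell_line = cell_line, gene = gene,
                   chrom = win$window$chrom, start = win$window$start,
                   end = win$window$end, width_bp = win$width_bp)
  }) |>
    purrr::list_rbind()
  if (is.null(ctcf) || nrow(ctcf) == 0) {
    ctcf <- tibble::tibble(cell_line = character(), gene = character(),
                           chrom = character(), start = integer(),
                           end = integer(), width_bp = integer())
  }

  list(overlaps = overlaps %||% tibble::tibble(), shares = shares,
       states = states, ctcf = ctcf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export plain numeric matrices underlying the figures
#'
#' From a report bundle written by [run_pipeline()], writes the numeric
#' data behind the three figure families: per-stage z-score heatmap
#' matrices (`fig_heatmap_<stage>.tsv`), pie shares of DMR-by-mark overlaps
#' (`fig_pie.tsv`), and the viability dose-response curves
#' (`fig_dose.tsv`). No styling, numbers only.
#'
#' @param outdir Bundle directory.
#' @return Invisibly, the paths written.
#' @export
make_figures <- function(outdir) {
  need <- c("de.tsv", "overlap_shares.tsv", "perturb_viability.tsv")
  miss <- need[!file.exists(file.path(outdir, need))]
  if (length(miss) > 0) {
    rlang::abort(sprintf("missing bundle member(s): %s", paste(miss, collapse = ", ")))
  }
  de <- read_report(file.path(outdir, "de.tsv"))
  paths <- character()
  for (s in ren_stages()) {
    wide <- de |>
      dplyr::filter(.data$stage == s) |>
      dplyr::select("gene", "subgroup", "z_subgroup") |>
      tidyr::pivot_wider(names_from = "subgroup", values_from = "z_subgroup")
    p <- file.path(outdir, sprintf("fig_heatmap_%s.tsv", s))
    write_report(wide, p)
    paths <- c(paths, p)
  }
  shares <- read_report(file.path(outdir, "overlap_shares.tsv"))
  p <- file.path(outdir, "fig_pie.tsv")
  write_report(shares, p)
  paths <- c(paths, p)
  viab <- read_report(file.path(outdir, "perturb_viability.tsv"))
  dose <- viab |>
    dplyr::group_by(.data$condition, conc = as.numeric(.data$key)) |>
    dplyr::summarise(mean_viability = mean(.data$value),
                     sd_viability = stats::sd(.data$value), .groups = "drop") |>
    dplyr::arrange(.data$condition, .data$conc)
  p <- file.path(outdir, "fig_dose.tsv")
  write_report(dose, p)
  paths <- c(paths, p)
  invisible(paths)
}
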
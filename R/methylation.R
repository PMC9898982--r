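# Methylation stage: fallback DMR segmentation from CpG sites, per-group
# DMR medians, differential-methylation calls against control, promoter/body
# annotation, and methylation-expression correlation with the R^2 > 0.4 rule.

#' Cluster CpG sites into candidate DMR intervals
#'
#' A documented fallback segmenter: runs of at least `min_cpg` CpG sites
#' with inter-CpG gaps of at most `max_gap` bp become candidate DMRs whose
#' interval spans the first to the last member CpG (inclusive of its end).
#'
#' @param cpgs CpG tibble (`chrom`, `start`, `end`, ...), sorted by
#'   position.
#' @param min_cpg Minimum CpGs per cluster (default 3).
#' @param max_gap Maximum gap between consecutive CpG starts, bp
#'   (default 200).
#' @return Tibble `dmr_id`, `chrom`, `start`, `end`, `n_cpg`.
#' @export
call_dmrs <- function(cpgs, min_cpg = 3, max_gap = 200) {
  sites <- dplyr::distinct(cpgs, .data$chrom, .data$start, .data$end) |>
    dplyr::arrange(.data$chrom, .data$start)
  sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      gap = .data$start - dplyr::lag(.data$start),
      cluster = cumsum(is.na(.data$gap) | .data$gap > max_gap)
    ) |>
    dplyr::group_by(.data$chrom, .data$cluster) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_cpg = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::filter(.data$n_cpg >= min_cpg) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::mutate(dmr_id = sprintf("DMR_%s_%d", .data$chrom, dplyr::row_number())) |>
    dplyr::select("dmr_id", "chrom", "start", "end", "n_cpg")
}

#' Per-group median methylation of DMRs
#'
#' Median over the member CpG fractions, per group, expressed in percent.
#'
#' @param dmrs DMR interval tibble (`dmr_id`, `chrom`, `start`, `end`, and
#'   optionally `gene`, `region_class`).
#' @param cpgs CpG tibble with `group` and `meth` (fraction) columns.
#' @return `dmrs` joined to one row per group with `median_meth` (percent)
#'   and `n_cpg_group`.
#' @export
summarize_dmr <- function(dmrs, cpgs) {
  # disjoint seqlevels (a DMR set on another chromosome) is an expected
  # situation here, not a user-facing warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(tbl_to_gr(cpgs), tbl_to_gr(dmrs))
  )
  if (length(hits) == 0) rlang::abort("no CpG sites fall inside any DMR")
  memb <- tibble::tibble(
    cpg = S4Vectors::queryHits(hits), dmr = S4Vectors::subjectHits(hits)
  )
  covered <- sort(unique(memb$dmr))
  if (length(covered) < nrow(dmrs)) {
    rlang::abort(sprintf(
      "DMR(s) without member CpGs: %s",
      paste(dmrs$dmr_id[setdiff(seq_len(nrow(dmrs)), covered)], collapse = ", ")
    ))
  }
  dplyr::bind_cols(
    cpgs[memb$cpg, c("group", "meth")],
    dmrs[memb$dmr, setdiff(names(dmrs), c("group", "meth"))]
  ) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(names(dmrs), c("group", "meth")))),
                    .data$group) |>
    dplyr::summarise(
      median_meth = 100 * stats::median(.data$meth),
      n_cpg_group = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$dmr_id, .data$group)
}

#' Differential-methylation calls against control
#'
#' Adds `dm_vs_control` (signed percentage points against the control
#' median) and a status flag per group: `hyper` when DM exceeds
#' `+threshold`, `hypo` below `-threshold`, otherwise `unchanged`.
#'
#' @param dmr_meth Output of [summarize_dmr()] (long, one row per DMR x
#'   group, with a control group present).
#' @param threshold Differential-methylation threshold in percentage points
#'   (default 10, strict).
#' @return Input with `dm_vs_control` and `dm_status` columns.
#' @export
differential_methylation <- function(dmr_meth, threshold = 10) {
  ctrl <- dmr_meth |>
    dplyr::filter(.data$group == ren_control()) |>
    dplyr::select("dmr_id", control_meth = "median_meth")
  if (nrow(ctrl) == 0) rlang::abort("control median methylation missing")
  dmr_meth |>
    dplyr::left_join(ctrl, by = "dmr_id") |>
    dplyr::mutate(
      dm_vs_control = .data$median_meth - .data$control_meth,
      dm_status = dplyr::case_when(
        .data$group == ren_control() ~ "control",
        .data$dm_vs_control > threshold ~ "hyper",
        .data$dm_vs_control < -threshold ~ "hypo",
        TRUE ~ "unchanged"
      )
    ) |>
    dplyr::select(-"control_meth")
}

#' Annotate an interval relative to a gene model
#'
#' Strand-aware promoter/body/intergenic call. The promoter window is
#' TSS-2000 to TSS+500 (in transcription direction, half-open); the body
#' runs from promoter end to the annotated gene end. An interval touching
#' both is called `promoter`.
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`).
#' @param gene_model One-row tibble or list with `chrom`, `tss`, `gene_end`,
#'   `strand` (`+` or `-`; for `-`, `tss` is the larger coordinate).
#' @param promoter_up,promoter_down Promoter window extent upstream /
#'   downstream of the TSS in bp (defaults 2000 / 500).
#' @return Character vector of `promoter` / `body` / `intergenic`.
#' @export
annotate_region <- function(intervals, gene_model, promoter_up = 2000,
                            promoter_down = 500) {
  gm <- as.list(gene_model)
  minus <- identical(gm$strand, "-")
  prom <- if (!minus) {
    c(gm$tss - promoter_up, gm$tss + promoter_down)
  } else {
    c(gm$tss - promoter_down, gm$tss + promoter_up)
  }
  body <- if (!minus) c(prom[2], gm$gene_end) else c(gm$gene_end, prom[1])
  overlaps <- function(s, e, win) {
    pmin(e, win[2]) - pmax(s, win[1]) > 0
  }
  same_chrom <- intervals$chrom == gm$chrom
  dplyr::case_when(
    same_chrom & overlaps(intervals$start, intervals$end, prom) ~ "promoter",
    same_chrom & overlaps(intervals$start, intervals$end, body) ~ "body",
    TRUE ~ "intergenic"
  )
}

#' Methylation-expression correlation per gene
#'
#' For one gene and one region class, the per-group methylation summary is
#' the aggregate (median by default, mean optionally) of that group's DMR
#' medians over DMRs of the requested class; `r_squared` is the squared
#' Pearson correlation between the group methylation summaries and the
#' group expression medians. `passes_cutoff` requires `r_squared`
#' strictly above `cutoff`. Pearson R^2 is invariant under affine rescaling
#' of either vector, so percent vs fraction (or raw medians vs z-scores)
#' does not change the result. Zero variance in either vector yields an
#' `NA` R^2 with `degenerate = TRUE`.
#'
#' @param dmr_meth Long DMR methylation tibble with `gene`, `region_class`,
#'   `group`, `median_meth`.
#' @param expr_medians Tibble of group expression medians with columns
#'   `group`, `expr` and, when correlating several genes at once, `gene`
#'   (e.g. MM-stage medians from [group_medians()]).
#' @param genes Optional gene subset.
#' @param region_class `"promoter"` or `"body"`.
#' @param agg Aggregation across a gene's DMRs: `"median"` (default) or
#'   `"mean"`.
#' @param cutoff R^2 cutoff (default 0.4, strict).
#' @return Tibble `gene`, `region_class`, `r_squared`, `n_points`,
#'   `passes_cutoff`, `degenerate`.
#' @export
methylation_expression_correlation <- function(dmr_meth, expr_medians,
                                               genes = NULL,
                                               region_class = "body",
                                               agg = c("median", "mean"),
                                               cutoff = 0.4) {
  agg <- match.arg(agg)
  agg_fun <- if (agg == "median") stats::median else mean
  meth <- dmr_meth |>
    dplyr::filter(.data$region_class == !!region_class)
  if (!is.null(genes)) meth <- dplyr::filter(meth, .data$gene %in% genes)
  join_by <- intersect(c("gene", "group"), names(expr_medians))
  summaries <- meth |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(meth = agg_fun(.data$median_meth), .groups = "drop") |>
    dplyr::inner_join(expr_medians, by = join_by)

  summaries |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      degenerate = stats::sd(.data$meth) == 0 || stats::sd(.data$expr) == 0,
      r_squared = dplyr::if_else(
        dplyr::n() >= 3 & !.data$degenerate,
        suppressWarnings(stats::cor(.data$meth, .data$expr))^2,
        NA_real_
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      region_class = !!region_class,
      passes_cutoff = !is.na(.data$r_squared) & .data$r_squared > cutoff
    ) |>
    dplyr::select("gene", "region_class", "r_squared", "n_points",
                  "passes_cutoff", "degenerate")
}
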
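# Expression stage: subgroup/stage medians, Mann-Whitney differential
# expression against control plasma cells, z-score statistics over group
# medians, and construction of the cross-stage upregulated gene panel.

#' Group medians and standard deviations
#'
#' Median and sample standard deviation (n-1 denominator) of log2 intensity
#' per (gene, stage, subgroup), with the healthy-donor pools summarised once
#' under stage/subgroup `"control"`. A single-sample group gets sd 0 and is
#' flagged.
#'
#' @param expr Long expression tibble from [read_expression()] or
#'   [simulate_cohort_expression()].
#' @return Tibble `gene`, `stage`, `subgroup`, `n`, `median`, `sd`,
#'   `single_sample`.
#' @export
group_medians <- function(expr) {
  validate_expression(expr)
  counts <- dplyr::distinct(expr, .data$sample_id, .data$stage, .data$subgroup) |>
    dplyr::count(.data$stage, .data$subgroup)
  empty <- tidyr::expand_grid(stage = ren_stages(), subgroup = ren_subgroups()) |>
    dplyr::anti_join(counts, by = c("stage", "subgroup"))
  if (nrow(empty) > 0) {
    rlang::abort(sprintf(
      "empty group(s): %s",
      paste(sprintf("%s/%s", empty$stage, empty$subgroup), collapse = ", ")
    ))
  }
  expr |>
    dplyr::group_by(.data$gene, .data$stage, .data$subgroup) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = stats::median(.data$value),
      sd = ifelse(dplyr::n() > 1, stats::sd(.data$value), 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(single_sample = .data$n == 1)
}

#' Z-scores of group medians within one stage
#'
#' For each gene, the z-score of each group's median over the seven group
#' medians of that stage (six subgroups plus control), using the sample
#' standard deviation. A constant row yields all-zero z-scores and is
#' flagged.
#'
#' @param medians Output of [group_medians()].
#' @param stage One of `"MGUS"`, `"SMM"`, `"MM"`.
#' @return Tibble `gene`, `group`, `z`, `constant`.
#' @export
zscore_by_group <- function(medians, stage) {
  stopifnot(stage %in% ren_stages())
  medians |>
    dplyr::filter(.data$stage == !!stage | .data$subgroup == ren_control()) |>
    dplyr::mutate(group = .data$subgroup) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(
      constant = stats::sd(.data$median) == 0,
      z = ifelse(.data$constant, 0,
                 (.data$median - mean(.data$median)) / stats::sd(.data$median))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene", "group", "z", "constant")
}

#' Differential expression against control plasma cells
#'
#' Per (gene, subgroup, stage): median log2 difference against the pooled
#' controls and a two-tailed Mann-Whitney U p-value (exact when the smaller
#' group has at most 8 samples and there are no ties; normal approximation
#' with tie correction otherwise). Direction is `up` when log2fc > `lfc`
#' and p < `alpha`, `down` when log2fc < -`lfc` and p < `alpha`, else `ns`.
#' Groups with fewer than 3 samples get `NA` p-values, direction `ns`, and
#' a warning.
#'
#' @param expr Long expression tibble.
#' @param genes Optional gene subset.
#' @param lfc Log2 fold-change threshold (default 1).
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per gene x subgroup x stage.
#' @export
differential_expression <- function(expr, genes = NULL, lfc = 1, alpha = 0.05) {
  validate_expression(expr)
  if (!is.null(genes)) expr <- dplyr::filter(expr, .data$gene %in% genes)
  ctrl <- dplyr::filter(expr, .data$subgroup == ren_control())
  case <- dplyr::filter(expr, .data$subgroup != ren_control())
  if (nrow(ctrl) == 0) rlang::abort("no control samples in expression data")

  ctrl_by_gene <- split(ctrl$value, ctrl$gene)
  out <- case |>
    dplyr::group_by(.data$gene, .data$stage, .data$subgroup) |>
    dplyr::summarise(vals = list(.data$value), .groups = "drop") |>
    dplyr::mutate(res = purrr::map2(.data$gene, .data$vals, function(g, v) {
      mw_vs_control(v, ctrl_by_gene[[g]])
    })) |>
    tidyr::unnest("res") |>
    dplyr::select(-"vals") |>
    dplyr::mutate(
      log2fc = .data$median_subgroup - .data$median_control,
      direction = dplyr::case_when(
        !is.na(.data$p_value) & .data$log2fc > lfc & .data$p_value < alpha ~ "up",
        !is.na(.data$p_value) & .data$log2fc < -lfc & .data$p_value < alpha ~ "down",
        TRUE ~ "ns"
      )
    )
  if (any(is.na(out$p_value))) {
    rlang::warn("group(s) with fewer than 3 samples: p-value omitted, direction 'ns'")
  }
  out
}

mw_vs_control <- function(x, ctrl) {
  tibble::tibble(
    n_subgroup = length(x), n_control = length(ctrl),
    median_subgroup = stats::median(x), median_control = stats::median(ctrl),
    p_value = mann_whitney_p(x, ctrl)
  )
}

#' Two-tailed Mann-Whitney U p-value
#'
#' Exact when `min(n1, n2) <= 8` and there are no ties; otherwise the normal
#' approximation with tie correction. Returns `NA` when either group has
#' fewer than 3 observations.
#'
#' @param x,y Numeric samples.
#' @return p-value in [0, 1], or `NA`.
#' @export
mann_whitney_p <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) return(NA_real_)
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- min(length(x), length(y)) <= 8 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value
  )
  # degenerate all-tied samples: no evidence against the null
  if (is.nan(p)) p <- 1
  p
}

#' Select (gene, subgroup) pairs by z-score difference
#'
#' Keeps pairs whose z-score exceeds the control z-score by strictly more
#' than `threshold`.
#'
#' @param z_table Output of [zscore_by_group()] (must contain the control
#'   group).
#' @param threshold Z-difference threshold (default 2, strict).
#' @return Tibble `gene`, `subgroup`, `z_subgroup`, `z_control`, `z_diff`.
#' @export
zdiff_select <- function(z_table, threshold = 2) {
  if (!ren_control() %in% z_table$group) {
    rlang::abort("z-score table must contain a control column")
  }
  ctrl <- z_table |>
    dplyr::filter(.data$group == ren_control()) |>
    dplyr::select("gene", z_control = "z")
  z_table |>
    dplyr::filter(.data$group != ren_control()) |>
    dplyr::left_join(ctrl, by = "gene") |>
    dplyr::mutate(z_diff = .data$z - .data$z_control) |>
    dplyr::filter(.data$z_diff > threshold) |>
    dplyr::select("gene", subgroup = "group", z_subgroup = "z", "z_control", "z_diff")
}

#' Full expression screen
#'
#' Combines the Mann-Whitney fold/p screen with the per-stage z-score
#' filter: a (gene, subgroup, stage) is called `upregulated` when direction
#' is `up` *and* its z-score exceeds the control z by more than
#' `z_threshold`.
#'
#' @inheritParams differential_expression
#' @param z_threshold Z-difference threshold (default 2).
#' @return Tibble of differential-expression records with `z_subgroup`,
#'   `z_control`, `z_diff` and `upregulated` columns.
#' @export
expression_screen <- function(expr, genes = NULL, lfc = 1, alpha = 0.05,
                              z_threshold = 2) {
  de <- differential_expression(expr, genes = genes, lfc = lfc, alpha = alpha)
  med <- group_medians(expr)
  z <- purrr::map(ren_stages(), function(s) {
    zt <- zscore_by_group(med, s)
    ctrl <- dplyr::filter(zt, .data$group == ren_control()) |>
      dplyr::select("gene", z_control = "z")
    zt |>
      dplyr::filter(.data$group != ren_control()) |>
      dplyr::left_join(ctrl, by = "gene") |>
      dplyr::mutate(stage = s, z_diff = .data$z - .data$z_control) |>
      dplyr::select("gene", "stage", subgroup = "group",
                    z_subgroup = "z", "z_control", "z_diff")
  }) |>
    purrr::list_rbind()
  de |>
    dplyr::left_join(z, by = c("gene", "stage", "subgroup")) |>
    dplyr::mutate(upregulated = .data$direction == "up" & .data$z_diff > z_threshold)
}

up_sets_by_stage <- function(screen) {
  up <- dplyr::filter(screen, .data$upregulated)
  purrr::map(setNames(ren_stages(), ren_stages()), function(s) {
    dplyr::filter(up, .data$stage == s) |>
      dplyr::select("gene", "subgroup")
  })
}

#' Genes upregulated at every disease stage
#'
#' A gene enters the cross-stage panel if it is upregulated in at least one
#' subgroup at each of MGUS, SMM and MM (the subgroup may differ by stage);
#' this equals the intersection of the per-stage gene sets.
#'
#' @param up_sets Named list (`MGUS`, `SMM`, `MM`) of tibbles with columns
#'   `gene`, `subgroup`, or an [expression_screen()] result.
#' @return Sorted character vector of panel genes.
#' @export
cross_stage_panel <- function(up_sets) {
  up_sets <- as_up_sets(up_sets)
  sort(purrr::reduce(purrr::map(up_sets, ~ unique(.x$gene)), intersect))
}

#' Subgroups in which a panel gene is consistently upregulated
#'
#' For each cross-stage panel gene, the subgroups in which it is
#' upregulated at *all three* stages. The set may be empty for a panel gene
#' whose subgroup shifts between stages.
#'
#' @inheritParams cross_stage_panel
#' @return Tibble `gene`, `subgroups` (list-column of character vectors).
#' @export
subgroup_consistency <- function(up_sets) {
  up_sets <- as_up_sets(up_sets)
  panel <- cross_stage_panel(up_sets)
  tibble::tibble(
    gene = panel,
    subgroups = purrr::map(panel, function(g) {
      sort(purrr::reduce(
        purrr::map(up_sets, ~ .x$subgroup[.x$gene == g]), intersect
      ))
    })
  )
}

as_up_sets <- function(x) {
  if (is.data.frame(x)) x <- up_sets_by_stage(x)
  if (!all(ren_stages() %in% names(x))) {
    rlang::abort("up-sets must cover stages MGUS, SMM and MM")
  }
  x[ren_stages()]
}
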
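# Methylation stage: segmentation, DMR summaries, DM calls, annotation,
# methylation-expression correlation.

cpg_tbl <- function(starts, chrom = "chr1", group = "control", meth = 0.5) {
  tibble::tibble(chrom = chrom, start = starts, end = starts + 2L,
                 group = group, meth = meth)
}

test_that("CpG clustering follows the min-count / max-gap rule", {
  d <- call_dmrs(cpg_tbl(c(100L, 150L, 220L, 300L)))
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 100L)
  expect_equal(d$end, 302L)
  expect_equal(d$n_cpg, 4L)

  expect_equal(nrow(call_dmrs(cpg_tbl(c(100L, 150L)))), 0L)

  two <- call_dmrs(cpg_tbl(c(100L, 150L, 220L, 720L, 800L, 880L)))
  expect_equal(nrow(two), 2L)
  expect_equal(two$start, c(100L, 720L))
})

test_that("DMR medians are percent medians over member CpGs", {
  dmrs <- tibble::tibble(dmr_id = "d1", chrom = "chr1", start = 0L, end = 1000L)
  cpgs <- cpg_tbl(c(10L, 20L, 30L), meth = c(0.80, 0.84, 0.88))
  m <- summarize_dmr(dmrs, cpgs)
  expect_equal(m$median_meth, 84)
  expect_equal(m$n_cpg_group, 3L)

  single <- summarize_dmr(dmrs, cpg_tbl(10L, meth = 0.42))
  expect_equal(single$median_meth, 42)

  # invariance to CpG ordering
  shuffled <- cpgs[c(3, 1, 2), ]
  expect_equal(summarize_dmr(dmrs, shuffled)$median_meth, 84)

  empty <- tibble::tibble(dmr_id = "far", chrom = "chr2", start = 0L, end = 10L)
  expect_error(summarize_dmr(empty, cpgs), "no CpG")
  expect_error(summarize_dmr(dplyr::bind_rows(dmrs, empty), cpgs), "far")
})

test_that("differential methylation thresholds at 10 points, strictly", {
  dm <- tibble::tibble(
    dmr_id = "d1", group = c("control", "t(4;14)", "D1", "t(14;16)"),
    median_meth = c(40, 55, 45, 20)
  )
  out <- differential_methylation(dm)
  expect_equal(out$dm_vs_control[out$group == "t(4;14)"], 15)
  expect_equal(out$dm_status[out$group == "t(4;14)"], "hyper")
  expect_equal(out$dm_status[out$group == "D1"], "unchanged")
  expect_equal(out$dm_vs_control[out$group == "t(14;16)"], -20)
  expect_equal(out$dm_status[out$group == "t(14;16)"], "hypo")
  expect_error(differential_methylation(dm[dm$group != "control", ]),
               "control")
})

test_that("relabelling the control group negates every DM value", {
  dm <- tibble::tibble(
    dmr_id = rep(c("d1", "d2"), each = 2),
    group = rep(c("control", "t(4;14)"), 2),
    median_meth = c(40, 55, 80, 62)
  )
  fwd <- differential_methylation(dm)
  swapped <- dm |>
    dplyr::mutate(group = ifelse(.data$group == "control", "t(4;14)", "control"))
  rev <- differential_methylation(swapped)
  expect_equal(
    sort(rev$dm_vs_control[rev$group != "control"]),
    sort(-fwd$dm_vs_control[fwd$group != "control"])
  )
})

test_that("promoter/body/intergenic annotation is strand-aware", {
  gm <- list(chrom = "chr1", tss = 10000L, gene_end = 30000L, strand = "+")
  iv <- tibble::tibble(
    chrom = "chr1",
    start = c(9000L, 20000L, 40000L, 9900L),
    end = c(9400L, 20400L, 40400L, 11000L)
  )
  expect_equal(annotate_region(iv, gm),
               c("promoter", "body", "intergenic", "promoter"))
  # minus strand: promoter sits above the TSS coordinate
  gm_minus <- list(chrom = "chr1", tss = 30000L, gene_end = 10000L, strand = "-")
  iv2 <- tibble::tibble(chrom = "chr1", start = c(31000L, 20000L),
                        end = c(31400L, 20400L))
  expect_equal(annotate_region(iv2, gm_minus), c("promoter", "body"))
})

test_that("methylation-expression R^2 follows the Pearson contract", {
  groups <- c("control", "t(4;14)", "t(11;14)", "t(14;16)", "t(14;20)", "D1", "D2")
  dm <- tibble::tibble(
    dmr_id = "d1", gene = "G", region_class = "body",
    group = groups, median_meth = c(10, 20, 30, 40, 50, 60, 70)
  )
  em <- tibble::tibble(group = groups, expr = c(8, 9, 10, 11, 12, 13, 14))
  r <- methylation_expression_correlation(dm, em, region_class = "body")
  expect_equal(r$r_squared, 1)
  expect_true(r$passes_cutoff)
  expect_equal(r$n_points, 7L)

  # affine invariance: percent vs fraction does not change R^2
  dm_frac <- dplyr::mutate(dm, median_meth = .data$median_meth / 100)
  expect_equal(
    methylation_expression_correlation(dm_frac, em, region_class = "body")$r_squared,
    1
  )

  flat <- dplyr::mutate(dm, median_meth = 33)
  r0 <- methylation_expression_correlation(flat, em, region_class = "body")
  expect_true(is.na(r0$r_squared))
  expect_true(r0$degenerate)
  expect_false(r0$passes_cutoff)
})

test_that("noise-free planted coupling gives R^2 = 1 for ITGB7 body DMRs", {
  truth <- synthetic_truth(seed = 9)
  expr <- simulate_cohort_expression(truth, noise_sd = 0)
  land <- simulate_methylation_landscape(truth, cpg_noise_sd = 0)
  dm <- summarize_dmr(land$dmrs, land$cpgs)
  em <- group_medians(expr) |>
    dplyr::filter(.data$stage %in% c("MM", "control")) |>
    dplyr::select("gene", group = "subgroup", expr = "median")
  r <- methylation_expression_correlation(dm, em, genes = "ITGB7",
                                          region_class = "body")
  expect_equal(r$r_squared, 1)
  # median and mean aggregation agree on direction here
  r_mean <- methylation_expression_correlation(dm, em, genes = "ITGB7",
                                               region_class = "body",
                                               agg = "mean")
  expect_true(r_mean$passes_cutoff)
})

test_that("noisy planted coupling still recovers a strong R^2", {
  # with CpG noise of 5 points the group summary moves by ~1-2 points
  # against a 20-point planted spread, so R^2 stays near 1
  truth <- synthetic_truth(seed = 1)
  r2 <- vapply(1:20, function(s) {
    land <- simulate_methylation_landscape(truth, cpg_noise_sd = 5, seed = 300 + s)
    expr <- simulate_cohort_expression(truth, noise_sd = 0.45, seed = 300 + s)
    dm <- summarize_dmr(land$dmrs, land$cpgs)
    em <- group_medians(expr) |>
      dplyr::filter(.data$stage %in% c("MM", "control")) |>
      dplyr::select("gene", group = "subgroup", expr = "median")
    methylation_expression_correlation(dm, em, genes = "ITGB7",
                                       region_class = "body")$r_squared
  }, numeric(1))
  expect_gte(min(r2), 0.8)
  expect_gte(stats::median(r2), 0.9)
})

test_that("noise-free hypo/hyper flags match the planted shifts exactly", {
  truth <- synthetic_truth(seed = 10)
  land <- simulate_methylation_landscape(truth, cpg_noise_sd = 0)
  out <- summarize_dmr(land$dmrs, land$cpgs) |>
    differential_methylation(threshold = 10)
  planted <- truth$dmr_meth |>
    dplyr::left_join(
      dplyr::filter(truth$dmr_meth, .data$group == "control") |>
        dplyr::select("dmr_id", ctrl = "meth_pct"),
      by = "dmr_id"
    ) |>
    dplyr::mutate(expected = dplyr::case_when(
      .data$group == "control" ~ "control",
      .data$meth_pct - .data$ctrl > 10 ~ "hyper",
      .data$meth_pct - .data$ctrl < -10 ~ "hypo",
      TRUE ~ "unchanged"
    ))
  joined <- dplyr::inner_join(out, planted, by = c("dmr_id", "group"))
  expect_equal(joined$dm_status, joined$expected)
})
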
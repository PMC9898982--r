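# Expression stage: medians, z-scores, Mann-Whitney tests, panel logic.

test_that("group medians and sd follow the sample (n-1) convention", {
  expr <- full_grid_expr(override = list(
    list(stage = "MM", subgroup = "D1", values = c(8, 9, 10))
  ))
  gm <- group_medians(expr)
  row <- gm[gm$stage == "MM" & gm$subgroup == "D1", ]
  expect_equal(row$median, 9)
  expect_equal(row$sd, 1)
  expect_false(row$single_sample)
})

test_that("a single-sample group reports sd 0 with a flag", {
  expr <- full_grid_expr(n = 3)
  expr <- expr[!(expr$stage == "MM" & expr$subgroup == "D2" &
                   expr$sample_id != "MM_D2_1"), ]
  gm <- group_medians(expr)
  row <- gm[gm$stage == "MM" & gm$subgroup == "D2", ]
  expect_true(row$single_sample)
  expect_equal(row$sd, 0)
})

test_that("an empty group is rejected by name", {
  expr <- full_grid_expr()
  expr <- expr[!(expr$stage == "SMM" & expr$subgroup == "t(14;20)"), ]
  expect_error(group_medians(expr), "SMM/t\\(14;20\\)")
})

test_that("z-scores over group medians normalise to mean 0 / sd 1", {
  gm <- tibble::tibble(
    gene = "G1",
    stage = c("MM", "MM", "control"),
    subgroup = c("D1", "D2", "control"),
    n = 3, median = c(1, 2, 3), sd = 0.1, single_sample = FALSE
  )
  z <- zscore_by_group(gm, "MM")
  expect_equal(z$z[order(z$group)], c(-1, 0, 1)[order(z$group)],
               ignore_attr = TRUE)
  expect_equal(sort(z$z), c(-1, 0, 1))

  # property: any non-constant row has mean 0 and sd 1 within 1e-9
  set.seed(42)
  for (i in 1:20) {
    gm_i <- tibble::tibble(
      gene = "G", stage = c(rep("MM", 6), "control"),
      subgroup = c("t(4;14)", "t(11;14)", "t(14;16)", "t(14;20)", "D1", "D2",
                   "control"),
      n = 5, median = rnorm(7), sd = 1, single_sample = FALSE
    )
    z_i <- zscore_by_group(gm_i, "MM")
    expect_lt(abs(mean(z_i$z)), 1e-9)
    expect_lt(abs(stats::sd(z_i$z) - 1), 1e-9)
  }

  gm$median <- rep(5, 3)
  z0 <- zscore_by_group(gm, "MM")
  expect_true(all(z0$z == 0))
  expect_true(all(z0$constant))
})

test_that("differential expression matches the worked examples", {
  expr <- make_expr("ITGB7", list(
    "t(14;16)" = c(12.90, 12.96, 13.02),
    "control" = c(8.58, 8.60, 8.62)
  ))
  de <- differential_expression(expr)
  expect_equal(de$log2fc, 12.96 - 8.60)
  expect_equal(de$median_control, 8.60)

  # U = 0 for {1,2,3,4} vs {5,6,7,8}: exact two-tailed p = 2/70
  expr2 <- make_expr("G", list("D1" = 5:8, "control" = 1:4))
  de2 <- differential_expression(expr2)
  expect_equal(de2$p_value, 2 / 70)
  expect_equal(de2$direction, "up")

  # identical groups: fc 0, p 1, ns
  expr3 <- make_expr("G", list("D1" = c(1, 2, 3), "control" = c(1, 2, 3)))
  de3 <- differential_expression(expr3)
  expect_equal(de3$log2fc, 0)
  expect_equal(de3$p_value, 1)
  expect_equal(de3$direction, "ns")
})

test_that("small groups yield NA p-values with direction ns and a warning", {
  expr <- make_expr("G", list("D1" = c(9, 10), "control" = c(1, 2, 3)))
  expect_warning(de <- differential_expression(expr), "fewer than 3")
  expect_true(is.na(de$p_value))
  expect_equal(de$direction, "ns")
})

test_that("exact Mann-Whitney path agrees with full enumeration", {
  set.seed(20240917)
  for (i in 1:200) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    repeat {
      x <- sample(1:50, n1)
      y <- sample(setdiff(1:50, x), n2)
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(mann_whitney_p(x, y), mw_exact_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("tied samples fall back to the corrected approximation", {
  x <- c(1, 2, 2, 3, 4)
  y <- c(2, 3, 3, 5, 6)
  expect_equal(
    mann_whitney_p(x, y),
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  )
})

test_that("z-difference selection is strictly greater-than", {
  zt <- tibble::tibble(
    gene = c("A", "A", "B", "B", "C", "C"),
    group = rep(c("t(14;16)", "control"), 3),
    z = c(2.5, 0.2, 2.2, 0.2, 0.2, 0.2),
    constant = FALSE
  )
  kept <- zdiff_select(zt, threshold = 2)
  expect_equal(kept$gene, "A")
  expect_equal(kept$z_diff, 2.3)
  # exactly at the threshold is excluded
  expect_false("B" %in% kept$gene)
  expect_error(zdiff_select(zt[zt$group != "control", ]), "control")
})

test_that("cross-stage panel and subgroup consistency follow the set logic", {
  up <- list(
    MGUS = tibble::tibble(gene = c("A", "B", "C"),
                          subgroup = c("D1", "t(11;14)", "t(14;16)")),
    SMM = tibble::tibble(gene = c("A", "C"), subgroup = c("D1", "t(14;16)")),
    MM = tibble::tibble(gene = c("A", "C"), subgroup = c("D1", "D2"))
  )
  expect_equal(cross_stage_panel(up), c("A", "C"))
  cons <- subgroup_consistency(up)
  expect_equal(cons$subgroups[cons$gene == "A"][[1]], "D1")
  # panel gene whose subgroup shifts at MM: empty consistency set
  expect_length(cons$subgroups[cons$gene == "C"][[1]], 0)
  expect_false("B" %in% cons$gene)
  expect_error(cross_stage_panel(up[c("MGUS", "SMM")]), "MGUS, SMM and MM")
})

test_that("noise-free screen recovers planted effects and nothing else", {
  truth <- synthetic_truth(seed = 13)
  expr <- simulate_cohort_expression(truth, noise_sd = 0)
  screen <- expression_screen(expr)
  up <- dplyr::filter(screen, .data$upregulated)
  planted_up <- dplyr::filter(truth$effects, .data$effect > 1)
  expect_equal(
    dplyr::arrange(up[, c("gene", "subgroup", "stage")],
                   .data$gene, .data$subgroup, .data$stage),
    dplyr::arrange(planted_up[, c("gene", "subgroup", "stage")],
                   .data$gene, .data$subgroup, .data$stage)
  )
  # panel is a subset of each stage's gene set
  panel <- cross_stage_panel(screen)
  for (s in c("MGUS", "SMM", "MM")) {
    expect_true(all(panel %in% up$gene[up$stage == s]))
  }
})
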
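# Chromatin integration: signal filtering, overlap engine vs brute force,
# share distributions, state classification, CTCF windows.

peak_tbl <- function(starts, ends, mark, signal = 100, chrom = "chrT") {
  tibble::tibble(chrom = chrom, start = as.integer(starts),
                 end = as.integer(ends), mark = mark, signal = signal)
}

test_that("signal filtering is strictly greater-than", {
  pk <- peak_tbl(c(0, 100, 200), c(50, 150, 250), "H3K27ac",
                 signal = c(60, 50, 49))
  kept <- filter_peaks_by_signal(pk, 50)
  expect_equal(kept$signal, 60)
  expect_equal(nrow(filter_peaks_by_signal(pk[0, ], 50)), 0L)
})

test_that("overlap records require 50 summed bases and merge same-mark peaks", {
  dmrs <- tibble::tibble(dmr_id = c("d1", "d2"), chrom = "chrT",
                         start = c(100L, 100L), end = c(200L, 149L))
  pk <- peak_tbl(150, 260, "H3K4me1")
  rec <- overlap_dmr_marks(dmrs[1, ], pk)
  expect_equal(rec$overlap_bp, 50L)
  # 29 bp only: below threshold, no record
  expect_equal(nrow(overlap_dmr_marks(dmrs[2, ], peak_tbl(120, 300, "H3K4me1"))), 0L)
  # two overlapping peaks of one mark merge into one record with summed bases
  two <- dplyr::bind_rows(peak_tbl(100, 130, "H3K4me1"),
                          peak_tbl(120, 160, "H3K4me1"))
  rec2 <- overlap_dmr_marks(dmrs[1, ], two)
  expect_equal(nrow(rec2), 1L)
  expect_equal(rec2$overlap_bp, 60L)
})

test_that("overlap engine equals per-base brute force on random instances", {
  set.seed(99)
  for (i in 1:1000) {
    ds <- sample(0:9000, 1)
    dw <- sample(30:1000, 1)
    n_pk <- sample(1:5, 1)
    ps <- sample(0:9000, n_pk, replace = TRUE)
    pw <- sample(10:1000, n_pk, replace = TRUE)
    dmr <- tibble::tibble(dmr_id = "d", chrom = "chrT",
                          start = ds, end = ds + dw)
    pk <- tibble::tibble(chrom = "chrT", start = ps, end = ps + pw,
                         mark = "H3K27ac", signal = 100)
    expected <- brute_overlap_bp(ds, ds + dw, ps, ps + pw)
    got <- overlap_dmr_marks(dmr, pk, min_overlap = 1)
    expect_identical(if (nrow(got) == 0) 0L else got$overlap_bp,
                     as.integer(expected))
  }
})

test_that("overlap shares use the pair-count denominator with half-up rounding", {
  # 2 DMRs x 3 marks: every share 2/6 = 33%
  rec_a <- tidyr::expand_grid(
    dmr_id = c("d1", "d2"),
    mark = c("H3K4me1", "H3K4me3", "H3K27ac")
  ) |>
    dplyr::mutate(overlap_bp = 60L)
  shares_a <- overlap_fraction_distribution(rec_a)
  expect_true(all(shares_a$share_pct == 33))
  expect_equal(attr(shares_a, "total_pairs"), 6L)

  # 3 DMRs with H3K4me1 plus 7 DMRs x 3 marks: 3/24 = 13%, 7/24 = 29%
  rec_b <- dplyr::bind_rows(
    tibble::tibble(dmr_id = paste0("a", 1:3), mark = "H3K4me1", overlap_bp = 60L),
    tidyr::expand_grid(dmr_id = paste0("b", 1:7),
                       mark = c("H3K4me3", "H3K27ac", "H3K36me3")) |>
      dplyr::mutate(overlap_bp = 60L)
  )
  shares_b <- overlap_fraction_distribution(rec_b)
  expect_equal(shares_b$share_pct[shares_b$mark == "H3K4me1"], 13)
  expect_true(all(shares_b$share_pct[shares_b$mark != "H3K4me1"] == 29))

  one <- overlap_fraction_distribution(rec_b[1, ])
  expect_equal(one$share_pct, 100)
  expect_error(overlap_fraction_distribution(rec_b[0, ]), "no overlap")
})

test_that("rounded shares stay within half a point of the exact shares", {
  # half-up rounding is forced by the printed percentages (12.5 -> 13); it
  # keeps every share within 0.5 of exact, so totals sit within
  # 100 +- n_marks/2
  set.seed(7)
  for (i in 1:50) {
    rec <- tibble::tibble(
      dmr_id = sample(paste0("d", 1:10), sample(2:30, 1), replace = TRUE),
      mark = sample(c("H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3", "H3K27me3"),
                    length(dmr_id), replace = TRUE),
      overlap_bp = 50L
    ) |>
      dplyr::distinct(dmr_id, mark, .keep_all = TRUE)
    shares <- overlap_fraction_distribution(rec)
    exact <- 100 * shares$n_pairs / sum(shares$n_pairs)
    expect_true(all(abs(shares$share_pct - exact) <= 0.5))
    expect_lte(abs(sum(shares$share_pct) - 100), nrow(shares) / 2)
  }
})

# handmade landscape fixtures for the classifier
gene_region <- list(chrom = "chrT", start = 10000L, end = 24000L)
promoter <- list(chrom = "chrT", start = 8000L, end = 10500L)
dmr_meth_at <- function(pct) {
  tibble::tibble(chrom = "chrT", start = 12000L, end = 12400L, median_meth = pct)
}
active_peaks <- dplyr::bind_rows(
  peak_tbl(11000, 23000, "H3K4me3"),
  peak_tbl(11000, 23000, "H3K27ac")
)
se_peaks <- dplyr::bind_rows(
  active_peaks,
  peak_tbl(11000, 15000, "H3K4me1"),
  peak_tbl(13000, 19000, "BRD4"),
  peak_tbl(13500, 19500, "MED1"),
  peak_tbl(12000, 14000, "DHS")
)

test_that("the three planted architectures classify as published", {
  biv <- classify_chromatin_state(
    gene_region, promoter,
    dplyr::bind_rows(peak_tbl(8000, 10500, "H3K27me3"),
                     peak_tbl(8200, 9500, "H3K4me1"))
  )
  expect_equal(biv$state, "bivalent")

  act <- classify_chromatin_state(gene_region, promoter, active_peaks,
                                  dmr_meth = dmr_meth_at(40))
  expect_equal(act$state, "active_enhancer")
  expect_equal(act$domain_span_bp, 12000L)

  se <- classify_chromatin_state(gene_region, promoter, se_peaks,
                                 dmr_meth = dmr_meth_at(5))
  expect_equal(se$state, "super_enhancer")
  expect_true(all(se$evidence[c("brd4_domain", "med1_domain", "dhs_domain")]))

  none <- classify_chromatin_state(gene_region, promoter, active_peaks[0, ])
  expect_equal(none$state, "none")
})

test_that("classification is monotone in the SE criteria", {
  # adding SE-criterion peaks to an active-enhancer call never demotes it
  act_plus <- classify_chromatin_state(
    gene_region, promoter,
    dplyr::bind_rows(active_peaks, peak_tbl(13000, 19000, "BRD4")),
    dmr_meth = dmr_meth_at(40)
  )
  expect_equal(act_plus$state, "active_enhancer")
  # removing any single SE criterion demotes super_enhancer
  for (drop_mark in c("H3K4me1", "BRD4", "MED1", "DHS")) {
    call <- classify_chromatin_state(
      gene_region, promoter,
      dplyr::filter(se_peaks, .data$mark != drop_mark),
      dmr_meth = dmr_meth_at(5)
    )
    expect_false(call$state == "super_enhancer")
  }
  meth_up <- classify_chromatin_state(gene_region, promoter, se_peaks,
                                      dmr_meth = dmr_meth_at(45))
  expect_equal(meth_up$state, "active_enhancer")
})

test_that("chromosome mismatch between promoter and gene region is rejected", {
  expect_error(
    classify_chromatin_state(gene_region,
                             list(chrom = "chrZ", start = 1L, end = 10L),
                             active_peaks),
    "same chromosome"
  )
})

test_that("CTCF windows span flank peak to flank peak", {
  gm <- list(chrom = "chrT", tss = 10000L, gene_end = 24000L)
  ctcf <- tibble::tibble(
    chrom = "chrT", start = c(4000L, 26600L), end = c(4400L, 27000L),
    mark = "CTCF", signal = 100
  )
  win <- detect_ctcf_window(gm, ctcf)
  expect_equal(win$width_bp, 23000L)
  expect_equal(win$window$start, 4000L)
  expect_equal(win$window$end, 27000L)
  # window contains the gene
  expect_lte(win$window$start, gm$tss)
  expect_gte(win$window$end, gm$gene_end)

  expect_null(detect_ctcf_window(gm, ctcf[2, ]))
  expect_null(detect_ctcf_window(gm, ctcf[1, ]))
  far <- dplyr::mutate(ctcf, start = start - 60000L, end = end - 60000L)
  expect_null(detect_ctcf_window(gm, far))
})

test_that("planted states are recovered, also under boundary jitter", {
  truth <- synthetic_truth(seed = 21)
  land <- simulate_methylation_landscape(truth, cpg_noise_sd = 0)
  dm <- summarize_dmr(land$dmrs, land$cpgs) |> differential_methylation()
  classify_cl <- function(cl, jitter_sd = 0, seed = truth$seed) {
    m <- truth$gene_models[truth$gene_models$gene == "ITGB7", ]
    sub <- truth$cell_lines$subgroup[truth$cell_lines$cell_line == cl]
    pk <- filter_peaks_by_signal(
      simulate_chromatin_peaks(truth, cl, jitter_sd = jitter_sd, seed = seed)
    )
    classify_chromatin_state(
      list(chrom = m$chrom, start = m$tss, end = m$gene_end),
      list(chrom = m$chrom, start = m$tss - 2000L, end = m$tss + 500L),
      pk, dmr_meth = dplyr::filter(dm, .data$group == sub)
    )$state
  }
  expect_equal(classify_cl("primary_B"), "bivalent")
  expect_equal(classify_cl("H929"), "active_enhancer")
  expect_equal(classify_cl("MM1S"), "super_enhancer")
  expect_equal(classify_cl("U266"), "none")

  # +-200 bp boundary jitter: recovery in >= 95% of seeds
  hits <- vapply(1:100, function(s) {
    classify_cl("MM1S", jitter_sd = 200, seed = 500 + s) == "super_enhancer" &&
      classify_cl("H929", jitter_sd = 200, seed = 500 + s) == "active_enhancer"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
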
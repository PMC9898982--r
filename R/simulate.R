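# Synthetic-cohort generator. Every pipeline stage is testable against a
# cohort with planted, exactly recoverable ground truth: subgroup-specific
# log2 expression effects, DMR methylation profiles, per-cell-line chromatin
# landscapes realising bivalent / active-enhancer / super-enhancer rules,
# and perturbation-assay readouts (pyrosequencing, qPCR, viability).

#' Planted ground truth for a synthetic cohort
#'
#' Builds the `ren_truth` object all simulators consume. The defaults plant
#' the adhesion-gene biology the pipeline is designed to recover:
#'
#' * an 8-gene upregulated panel (ITGA4 in t(11;14); ITGA8 in D1; DSG2 in
#'   t(4;14); VCAM1 in t(11;14) and D1; ITGAE, ITGB7, CD28 and CD86 in the
#'   MF cluster t(14;16)/t(14;20)) with effects present at all three stages;
#'   the ITGB7 effect is +4.36 log2 over a control baseline of 8.60, so the
#'   noise-free subgroup median is 12.96;
#' * nine gene-body DMRs on ITGB7 (62 CpG sites) whose group medians couple
#'   linearly (negatively) to expression, hypomethylated in the MF cluster
#'   and hypermethylated at a subset of DMRs in t(4;14); body DMRs on DSG2
#'   (72 CpG sites, positive coupling) and promoter DMRs on ITGAE;
#' * per-cell-line chromatin landscapes: bivalent ITGB7 in primary B cells,
#'   a 12-kb H3K4me3/H3K27ac broad domain (active enhancer) in H929, a
#'   super-enhancer (plus H3K4me1, BRD4, MED1, DHS) in MM1S, no state in
#'   U266, and CTCF flanks at TSS-6 kb / 3'-end+3 kb giving a 23-kb window;
#' * perturbation readouts: a 3.2-fold qPCR effect for sgRNA-3 (3.0-fold for
#'   sgRNA-1, none for sgRNA-2 or without Dox), +25-percentage-point
#'   pyrosequencing shifts at 6/8, 4/6 and 3/3 CpGs of the three targeted
#'   DMRs, and JQ1 dose-response curves with IC50 0.11 / 0.10 / 0.08 uM at
#'   24 / 48 / 72 h.
#'
#' @param seed Integer seed recorded in the truth and used by default by
#'   every simulator.
#' @return A list of class `ren_truth`.
#' @export
synthetic_truth <- function(seed = 1L) {
  genes <- adhesion_genes()

  baselines <- setNames(
    round(7.5 + 3 * (seq_along(genes) - 1) / (length(genes) - 1), 2), genes
  )
  baselines["ITGB7"] <- 8.60
  baselines["ITGA4"] <- 9.06

  mf <- c("t(14;16)", "t(14;20)")
  up <- dplyr::bind_rows(
    tibble::tibble(gene = "ITGA4", subgroup = "t(11;14)", effect = 1.5),
    tibble::tibble(gene = "ITGA8", subgroup = "D1", effect = 1.8),
    tibble::tibble(gene = "DSG2", subgroup = "t(4;14)", effect = 2.0),
    tibble::tibble(gene = "VCAM1", subgroup = c("t(11;14)", "D1"), effect = 1.6),
    tibble::tibble(gene = "ITGAE", subgroup = mf, effect = 2.2),
    tibble::tibble(gene = "ITGB7", subgroup = mf, effect = 4.36),
    tibble::tibble(gene = "CD28", subgroup = mf, effect = 1.9),
    tibble::tibble(gene = "CD86", subgroup = mf, effect = 1.7)
  )
  down <- tidyr::expand_grid(
    gene = c("ITGA5", "ITGAL", "ITGB2", "ICAM1"),
    subgroup = ren_subgroups()
  ) |>
    dplyr::mutate(effect = -1.5)
  effects <- tidyr::crossing(dplyr::bind_rows(up, down), stage = ren_stages()) |>
    dplyr::select("gene", "subgroup", "stage", "effect")

  gene_models <- tibble::tibble(
    gene = genes,
    chrom = "chrA",
    tss = 1000000L * seq_along(genes),
    gene_end = 1000000L * seq_along(genes) + ifelse(genes == "ITGB7", 14000L, 20000L),
    strand = "+"
  )

  dmrs <- dplyr::bind_rows(
    itgb7_dmrs(gene_models), dsg2_dmrs(gene_models), itgae_dmrs(gene_models)
  )
  dmr_meth <- dplyr::bind_rows(
    itgb7_dmr_meth(), dsg2_dmr_meth(), itgae_dmr_meth()
  )

  cell_lines <- tibble::tibble(
    cell_line = c("primary_B", "H929", "U266", "MM1S", "SACHI"),
    subgroup = c("control", "t(4;14)", "t(11;14)", "t(14;16)", "t(14;20)")
  )
  states <- tibble::tibble(
    cell_line = c("primary_B", "H929", "U266", "MM1S"),
    gene = "ITGB7",
    state = c("bivalent", "active_enhancer", "none", "super_enhancer")
  )

  qpcr <- tibble::tibble(
    condition = c("dCas9_DNMT3A_sgRNA1_Dox", "dCas9_DNMT3A_sgRNA2_Dox",
                  "dCas9_DNMT3A_sgRNA3_Dox", "dCas9_DNMT3A_sgRNA3_noDox"),
    fold = c(3.0, 1.0, 3.2, 1.0)
  )

  pyro <- dplyr::bind_rows(
    tibble::tibble(dmr_id = "ITGB7_DMR1", cpg_index = 1:8, control_pct = 8,
                   shift = c(rep(25, 6), 0, 0)),
    tibble::tibble(dmr_id = "ITGB7_DMR2", cpg_index = 1:6, control_pct = 10,
                   shift = c(rep(25, 4), 0, 0)),
    tibble::tibble(dmr_id = "ITGB7_DMR3", cpg_index = 1:3, control_pct = 6,
                   shift = rep(25, 3))
  ) |>
    dplyr::mutate(treated_pct = .data$control_pct + .data$shift)

  ic50 <- tibble::tibble(
    time_h = c(24, 48, 72), ic50 = c(0.11, 0.10, 0.08),
    hill = 1.5, top = 1, bottom = 0.05
  )

  structure(
    list(
      genes = genes, baselines = baselines, effects = effects,
      gene_models = gene_models, dmrs = dmrs, dmr_meth = dmr_meth,
      cell_lines = cell_lines, states = states,
      qpcr = qpcr, pyro = pyro, ic50 = ic50,
      doses = c(0.025, 0.05, 0.1, 0.25, 0.5, 1, 2),
      seed = as.integer(seed)
    ),
    class = "ren_truth"
  )
}

# nine body DMRs; DMR-1..7 inside the 12-kb broad domain [TSS+1k, TSS+13k),
# DMR-8/9 beyond it (still in the gene body); 62 CpG sites in total,
# with DMR-1/2/3 carrying the 8/6/3 CpGs targeted by the CRISPR assay
itgb7_dmrs <- function(models) {
  m <- models[models$gene == "ITGB7", ]
  starts <- c(m$tss + 2000L + (0:6) * 1400L, m$tss + 13200L, m$tss + 13600L)
  tibble::tibble(
    dmr_id = paste0("ITGB7_DMR", 1:9), gene = "ITGB7", chrom = m$chrom,
    start = starts, end = starts + 400L, region_class = "body",
    n_cpg = c(8L, 6L, 3L, 7L, 7L, 7L, 8L, 8L, 8L)
  )
}

# control body methylation 23%; MF cluster hypomethylated (-20) at DMR-1..7;
# t(4;14) hypermethylated at DMR-2/3 (inside the domain; intermediate band)
# and DMR-8/9 (outside it); t(11;14) mildly hypo at DMR-4..7; D1/D2 hyper at
# three distal DMRs. Group medians over the nine DMRs stay exactly linear in
# the planted expression medians (23% at baseline groups, 3% in MF).
itgb7_dmr_meth <- function() {
  base <- 23
  prof <- list(
    "control" = rep(base, 9),
    "t(4;14)" = base + c(0, 22, 17, 0, 0, 0, 0, 15, 12),
    "t(11;14)" = base + c(0, 0, 0, -15, -15, -15, -15, 0, 0),
    "t(14;16)" = base + c(rep(-20, 7), 0, 0),
    "t(14;20)" = base + c(rep(-20, 7), 0, 0),
    "D1" = base + c(0, 0, 0, 15, 0, 0, 0, 15, 15),
    "D2" = base + c(0, 0, 0, 0, 0, 0, 15, 15, 15)
  )
  purrr::imap(prof, function(v, g) {
    tibble::tibble(dmr_id = paste0("ITGB7_DMR", 1:9), group = g, meth_pct = v)
  }) |>
    purrr::list_rbind()
}

dsg2_dmrs <- function(models) {
  m <- models[models$gene == "DSG2", ]
  starts <- c(m$tss - 1800L + (0:3) * 500L, m$tss + 3000L + (0:4) * 2000L)
  tibble::tibble(
    dmr_id = paste0("DSG2_DMR", 1:9), gene = "DSG2", chrom = m$chrom,
    start = starts, end = starts + 400L,
    region_class = c(rep("promoter", 4), rep("body", 5)),
    n_cpg = rep(8L, 9)
  )
}

# body DMRs couple positively to the t(4;14)-specific expression effect;
# DMR-7/8/9 carry the high methylation (45/72/84% in t(4;14)); promoter
# DMRs are flat and uninformative
dsg2_dmr_meth <- function() {
  prof <- list(
    "control" = c(rep(5, 4), 1, 1, 20, 30, 40),
    "t(4;14)" = c(rep(5, 4), 1, 1, 45, 72, 84),
    "t(11;14)" = c(rep(5, 4), 1, 1, 10, 14, 18),
    "t(14;16)" = c(rep(5, 4), 1, 1, 10, 14, 18),
    "t(14;20)" = c(rep(5, 4), 1, 1, 10, 14, 18),
    "D1" = c(rep(5, 4), 1, 1, 10, 14, 18),
    "D2" = c(rep(5, 4), 1, 1, 10, 14, 18)
  )
  purrr::imap(prof, function(v, g) {
    tibble::tibble(dmr_id = paste0("DSG2_DMR", 1:9), group = g, meth_pct = v)
  }) |>
    purrr::list_rbind()
}

itgae_dmrs <- function(models) {
  m <- models[models$gene == "ITGAE", ]
  starts <- m$tss - 1600L + (0:2) * 600L
  tibble::tibble(
    dmr_id = paste0("ITGAE_DMR", 1:3), gene = "ITGAE", chrom = m$chrom,
    start = starts, end = starts + 400L, region_class = "promoter",
    n_cpg = rep(4L, 3)
  )
}

# atypical positive promoter coupling: highest methylation and highest
# expression both in the MF cluster
itgae_dmr_meth <- function() {
  groups <- c(ren_control(), ren_subgroups())
  purrr::map(groups, function(g) {
    v <- if (g %in% c("t(14;16)", "t(14;20)")) c(45, 48, 42) else c(10, 12, 11)
    tibble::tibble(dmr_id = paste0("ITGAE_DMR", 1:3), group = g, meth_pct = v)
  }) |>
    purrr::list_rbind()
}

#' Simulate a cohort expression matrix
#'
#' Control baseline per gene plus planted additive log2 effects, with
#' per-sample Gaussian noise on the log2 scale.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_per_group Samples per subgroup per stage (default 10).
#' @param n_control Healthy-donor control pools (default 4).
#' @param noise_sd Per-sample Gaussian noise, log2 units (default 0.45,
#'   matching the spread of the planted group standard deviations).
#' @param seed Seed; defaults to `truth$seed`. Pass `NA` to use the current
#'   RNG stream.
#' @return Long expression tibble (`gene`, `sample_id`, `stage`, `subgroup`,
#'   `value`), as returned by [read_expression()].
#' @export
simulate_cohort_expression <- function(truth, n_per_group = 10, n_control = 4,
                                       noise_sd = 0.45, seed = truth$seed) {
  stopifnot(inherits(truth, "ren_truth"), n_per_group >= 3, noise_sd >= 0)
  missing <- setdiff(truth$effects$gene, truth$genes)
  if (length(missing) > 0) {
    rlang::abort(sprintf("planted gene(s) absent from gene list: %s",
                         paste(missing, collapse = ", ")))
  }
  if (!is.na(seed)) set.seed(seed)

  sheet <- dplyr::bind_rows(
    tidyr::expand_grid(stage = ren_stages(), subgroup = ren_subgroups(),
                       rep = seq_len(n_per_group)),
    tidyr::expand_grid(stage = ren_control(), subgroup = ren_control(),
                       rep = seq_len(n_control))
  ) |>
    dplyr::mutate(sample_id = sprintf(
      "S_%s_%s_%02d", .data$stage, gsub("[^0-9A-Za-z]", "", .data$subgroup), .data$rep
    )) |>
    dplyr::select("sample_id", "stage", "subgroup")

  expr <- tidyr::expand_grid(gene = truth$genes, sheet) |>
    dplyr::left_join(truth$effects, by = c("gene", "subgroup", "stage")) |>
    dplyr::mutate(
      effect = dplyr::coalesce(.data$effect, 0),
      value = unname(truth$baselines[.data$gene]) + .data$effect +
        rnorm(dplyr::n(), sd = noise_sd)
    ) |>
    dplyr::select("gene", "sample_id", "stage", "subgroup", "value") |>
    dplyr::arrange(.data$gene, .data$sample_id)
  expr
}

#' Simulate the CpG methylation landscape
#'
#' Evenly spaced CpG sites are laid down inside each planted DMR; per group,
#' CpG fractions are drawn around the planted DMR median with Gaussian noise
#' (in percentage points) and truncated to [0, 1].
#'
#' @param truth A [synthetic_truth()] object.
#' @param cpg_noise_sd Per-CpG noise, percentage points (default 5).
#' @param seed Seed; defaults to `truth$seed`; `NA` for current stream.
#' @return List with `cpgs` (tibble `chrom`, `start`, `end`, `group`,
#'   `meth`) and `dmrs` (the planted DMR intervals).
#' @export
simulate_methylation_landscape <- function(truth, cpg_noise_sd = 5,
                                           seed = truth$seed) {
  stopifnot(inherits(truth, "ren_truth"), cpg_noise_sd >= 0)
  if (any(truth$dmr_meth$meth_pct < 0 | truth$dmr_meth$meth_pct > 100)) {
    rlang::abort("planted DMR methylation must be within [0, 100]")
  }
  if (!is.na(seed)) set.seed(seed)

  sites <- truth$dmrs |>
    dplyr::rowwise() |>
    dplyr::mutate(pos = list(as.integer(round(
      seq(.data$start, .data$end - 2L, length.out = .data$n_cpg)
    )))) |>
    dplyr::ungroup() |>
    dplyr::select("dmr_id", "chrom", "pos") |>
    tidyr::unnest("pos")

  cpgs <- tidyr::expand_grid(
    group = c(ren_control(), ren_subgroups()), sites
  ) |>
    dplyr::left_join(truth$dmr_meth, by = c("dmr_id", "group")) |>
    dplyr::mutate(
      meth = pmin(1, pmax(0, .data$meth_pct / 100 +
                            rnorm(dplyr::n(), sd = cpg_noise_sd / 100))),
      start = .data$pos, end = .data$pos + 2L
    ) |>
    dplyr::select("chrom", "start", "end", "group", "meth") |>
    dplyr::arrange(.data$group, .data$chrom, .data$start)

  list(cpgs = cpgs, dmrs = truth$dmrs)
}

#' Simulate chromatin peak landscapes for one cell line
#'
#' Emits per-mark peak sets realising the planted chromatin state of each
#' gene: a bivalent promoter (H3K27me3 + H3K4me1, no acetylation), a 12-kb
#' H3K4me3/H3K27ac broad co-domain for active enhancers, and additionally
#' H3K4me1, BRD4, MED1 and DHS occupancy for super-enhancers, with CTCF
#' flanks at TSS-6 kb and 3'-end+3 kb for enhancer/SE genes. Peak scores are
#' -log10 p style signals above the filtering threshold; a few low-signal
#' decoy peaks are included so signal filtering is exercised.
#'
#' @param truth A [synthetic_truth()] object.
#' @param cell_line One of `truth$cell_lines$cell_line`.
#' @param jitter_sd Gaussian jitter (bp) applied to peak boundaries
#'   (default 0).
#' @param seed Seed; defaults to `truth$seed`; `NA` for current stream.
#' @return Peak tibble: `chrom`, `start`, `end`, `name`, `signal`, `mark`,
#'   `cell_line`, sorted by (mark, chrom, start).
#' @export
simulate_chromatin_peaks <- function(truth, cell_line, jitter_sd = 0,
                                     seed = truth$seed) {
  stopifnot(inherits(truth, "ren_truth"))
  if (!cell_line %in% truth$cell_lines$cell_line) {
    rlang::abort(sprintf("unknown cell line '%s'", cell_line))
  }
  if (!is.na(seed)) set.seed(seed)

  states <- dplyr::filter(truth$states, .data$cell_line == !!cell_line)
  bad <- setdiff(states$state, c("bivalent", "active_enhancer", "super_enhancer", "none"))
  if (length(bad) > 0) {
    rlang::abort(sprintf("unknown chromatin state label(s): %s", paste(bad, collapse = ", ")))
  }

  peaks <- purrr::pmap(states, function(cell_line, gene, state) {
    m <- truth$gene_models[truth$gene_models$gene == gene, ]
    state_peaks(state, m$chrom, m$tss, m$gene_end)
  }) |>
    purrr::list_rbind()

  # low-signal decoys, dropped by the signal > 50 filter
  decoy <- tibble::tibble(
    chrom = "chrA", start = c(500000L, 700000L), end = c(500400L, 700400L),
    mark = c("H3K27ac", "H3K4me3"), signal = c(20, 30)
  )
  peaks <- dplyr::bind_rows(peaks, decoy)

  if (jitter_sd > 0) {
    peaks <- peaks |>
      dplyr::mutate(
        start = pmax(0L, as.integer(round(.data$start + rnorm(dplyr::n(), sd = jitter_sd)))),
        end = as.integer(round(.data$end + rnorm(dplyr::n(), sd = jitter_sd))),
        end = pmax(.data$end, .data$start + 1L)
      )
  }
  peaks |>
    dplyr::mutate(
      name = sprintf("%s_%s_%d", cell_line, .data$mark, dplyr::row_number()),
      cell_line = cell_line
    ) |>
    dplyr::select("chrom", "start", "end", "name", "signal", "mark", "cell_line") |>
    dplyr::arrange(.data$mark, .data$chrom, .data$start)
}

state_peaks <- function(state, chrom, tss, gene_end) {
  pk <- function(start, end, mark, signal) {
    tibble::tibble(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), mark = mark, signal = signal)
  }
  domain <- c(tss + 1000L, tss + 13000L)  # 12-kb broad co-domain
  switch(
    state,
    none = pk(integer(), integer(), character(), double()),
    bivalent = dplyr::bind_rows(
      pk(tss - 2000L, tss + 500L, "H3K27me3", 120),   # covers the promoter
      pk(tss + 500L, tss + 6000L, "H3K27me3", 90),    # intragenic repression
      pk(tss - 1855L, tss + 100L, "H3K4me1", 70)
    ),
    active_enhancer = dplyr::bind_rows(
      pk(domain[1], domain[2], "H3K4me3", 150),
      pk(domain[1], domain[2], "H3K27ac", 140),
      # small H3K4me1 peak over the proximal DMRs
      pk(tss + 1900L, tss + 4900L, "H3K4me1", 60),
      pk(tss - 6000L, tss - 5600L, "CTCF", 110),
      pk(gene_end + 2600L, gene_end + 3000L, "CTCF", 100)
    ),
    super_enhancer = dplyr::bind_rows(
      pk(domain[1], domain[2], "H3K4me3", 170),
      pk(domain[1], domain[2], "H3K27ac", 180),
      pk(domain[1], domain[2], "H3K36me3", 90),
      pk(tss + 1900L, tss + 4900L, "H3K4me1", 130),
      pk(tss + 3000L, tss + 9000L, "BRD4", 160),
      pk(tss + 3500L, tss + 9500L, "MED1", 150),
      pk(tss + 2000L, tss + 4000L, "DHS", 120),
      pk(tss + 6000L, tss + 8000L, "DHS", 110),
      pk(tss - 1500L, tss - 1100L, "MAF", 80),
      pk(tss + 100L, tss + 500L, "MAF", 75),
      pk(tss - 6000L, tss - 5600L, "CTCF", 130),
      pk(gene_end + 2600L, gene_end + 3000L, "CTCF", 120)
    ),
    rlang::abort(sprintf("unknown chromatin state label '%s'", state))
  )
}

#' Simulate perturbation assay tables
#'
#' Generates the three assay tables in long format: pyrosequencing percent
#' methylation per CpG per condition, qPCR Ct values constructed so that
#' `2^-ddCt` equals the planted fold change in the noise-free limit
#' (GAPDH reference held constant across conditions), and viability from a
#' 4-parameter log-logistic curve with the planted per-time-point IC50.
#'
#' @param truth A [synthetic_truth()] object.
#' @param reps Replicates per condition (default 3).
#' @param pyro_sd,ct_sd Gaussian noise for pyrosequencing (percentage
#'   points) and qPCR (Ct cycles).
#' @param viab_sd Multiplicative viability noise (coefficient of
#'   variation).
#' @param seed Seed; defaults to `truth$seed`; `NA` for current stream.
#' @return List of tibbles `pyro`, `qpcr`, `viability`, each with columns
#'   `assay`, `condition`, `replicate`, `key`, `value`.
#' @export
simulate_perturbation_assays <- function(truth, reps = 3, pyro_sd = 0,
                                         ct_sd = 0, viab_sd = 0,
                                         seed = truth$seed) {
  stopifnot(inherits(truth, "ren_truth"), reps >= 3)
  if (any(truth$qpcr$fold <= 0)) {
    rlang::abort("planted qPCR fold change must be positive")
  }
  if (!is.na(seed)) set.seed(seed)

  pyro <- tidyr::expand_grid(truth$pyro, replicate = seq_len(reps)) |>
    tidyr::pivot_longer(c("control_pct", "treated_pct"),
                        names_to = "condition", values_to = "mu") |>
    dplyr::mutate(
      condition = ifelse(.data$condition == "control_pct",
                         "dCas9_DNMT3A", "dCas9_DNMT3A_sgRNA_Dox"),
      assay = "PYRO",
      key = sprintf("%s_CpG%d", .data$dmr_id, .data$cpg_index),
      value = pmin(100, pmax(0, .data$mu + rnorm(dplyr::n(), sd = pyro_sd)))
    ) |>
    dplyr::select("assay", "condition", "replicate", "key", "value")

  ref_ct <- 18
  target_ct0 <- 24
  qpcr_grid <- dplyr::bind_rows(
    tibble::tibble(condition = "dCas9_DNMT3A", fold = 1),
    truth$qpcr
  ) |>
    tidyr::expand_grid(replicate = seq_len(reps))
  qpcr <- purrr::pmap(qpcr_grid, function(condition, fold, replicate) {
    tibble::tibble(
      assay = "QPCR", condition = condition, replicate = replicate,
      key = c("ITGB7", "GAPDH"),
      value = c(target_ct0 - log2(fold), ref_ct) + rnorm(2, sd = ct_sd)
    )
  }) |>
    purrr::list_rbind()

  viability <- tidyr::expand_grid(
    truth$ic50, dose = truth$doses, replicate = seq_len(reps)
  ) |>
    dplyr::mutate(
      assay = "VIABILITY",
      condition = sprintf("JQ1_%dh", .data$time_h),
      key = as.character(.data$dose),
      value = pmax(0, (.data$bottom + (.data$top - .data$bottom) /
                         (1 + (.data$dose / .data$ic50)^.data$hill)) *
                     (1 + rnorm(dplyr::n(), sd = viab_sd)))
    ) |>
    dplyr::select("assay", "condition", "replicate", "key", "value")

  list(pyro = pyro, qpcr = qpcr, viability = viability)
}
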
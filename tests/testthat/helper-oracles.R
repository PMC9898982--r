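# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Exact two-tailed Mann-Whitney p by full enumeration of rank assignments
# (no ties assumed): every size-n1 subset of ranks 1..n is equally likely
# under the null.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2, function(idx) {
    sum(idx) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Per-base brute-force overlap of one interval with a set of (possibly
# overlapping) peaks on a toy chromosome.
brute_overlap_bp <- function(dmr_start, dmr_end, peak_starts, peak_ends,
                             chrom_len = 20000) {
  covered <- rep(FALSE, chrom_len)
  for (i in seq_along(peak_starts)) {
    covered[(peak_starts[i] + 1):peak_ends[i]] <- TRUE
  }
  sum(covered[(dmr_start + 1):dmr_end])
}

# Small handmade expression cohort: per-group sample values supplied as a
# named list group_label -> numeric vector; control label "control".
make_expr <- function(gene, values_by_group, stage = "MM") {
  purrr::imap(values_by_group, function(v, g) {
    st <- if (g == "control") "control" else stage
    tibble::tibble(
      gene = gene,
      sample_id = sprintf("%s_%s_%d", st, gsub("[^0-9A-Za-z]", "", g), seq_along(v)),
      stage = st, subgroup = g, value = v
    )
  }) |>
    purrr::list_rbind()
}

# Expression tibble covering every stage x subgroup so group_medians() does
# not reject the cohort; one gene, constant baseline except where overridden.
full_grid_expr <- function(gene = "G1", baseline = 8, n = 3,
                           override = NULL) {
  grid <- tidyr::expand_grid(
    stage = c("MGUS", "SMM", "MM"),
    subgroup = c("t(4;14)", "t(11;14)", "t(14;16)", "t(14;20)", "D1", "D2"),
    rep = seq_len(n)
  )
  ctrl <- tidyr::expand_grid(stage = "control", subgroup = "control",
                             rep = seq_len(n))
  out <- dplyr::bind_rows(grid, ctrl) |>
    dplyr::mutate(
      gene = gene,
      sample_id = sprintf("%s_%s_%d", stage, gsub("[^0-9A-Za-z]", "", subgroup), rep),
      value = baseline
    ) |>
    dplyr::select(gene, sample_id, stage, subgroup, value)
  if (!is.null(override)) {
    for (o in override) {
      idx <- out$stage == o$stage & out$subgroup == o$subgroup
      out$value[idx] <- o$values
    }
  }
  out
}
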
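# Chromatin integration: signal filtering of peaks, the >=50-bp DMR-by-mark
# overlap statistic with percentage distributions, the rule-based
# bivalent / active-enhancer / super-enhancer classifier, and CTCF-window
# detection around a gene.

#' Filter peaks by signal score
#'
#' Keeps peaks whose -log10 p signal is strictly greater than `min_signal`.
#'
#' @param peaks Peak tibble with a `signal` column.
#' @param min_signal Signal threshold (default 50, strict).
#' @return Filtered peak tibble.
#' @export
filter_peaks_by_signal <- function(peaks, min_signal = 50) {
  dplyr::filter(peaks, !is.na(.data$signal) & .data$signal > min_signal)
}

#' DMR-by-mark overlap records
#'
#' For every (DMR, mark) pair, peaks of that mark are merged and the total
#' number of DMR bases they cover is summed; one record is emitted when the
#' summed coverage reaches `min_overlap` bp.
#'
#' @param dmrs DMR interval tibble (`dmr_id`, `chrom`, `start`, `end`).
#' @param peaks Peak tibble with a `mark` column (pre-filtered by signal).
#' @param min_overlap Minimum overlapped bases (default 50).
#' @return Tibble `dmr_id`, `mark`, `overlap_bp`.
#' @export
overlap_dmr_marks <- function(dmrs, peaks, min_overlap = 50) {
  if (nrow(dmrs) == 0 || nrow(peaks) == 0) {
    return(tibble::tibble(dmr_id = character(), mark = character(),
                          overlap_bp = integer()))
  }
  dmr_gr <- tbl_to_gr(dmrs)
  out <- purrr::map(split(peaks, peaks$mark), function(pk) {
    merged <- GenomicRanges::reduce(tbl_to_gr(pk))
    hits <- GenomicRanges::findOverlaps(dmr_gr, merged)
    if (length(hits) == 0) return(NULL)
    ov <- GenomicRanges::pintersect(
      dmr_gr[S4Vectors::queryHits(hits)], merged[S4Vectors::subjectHits(hits)]
    )
    tibble::tibble(
      dmr_id = dmrs$dmr_id[S4Vectors::queryHits(hits)],
      mark = pk$mark[1],
      overlap_bp = GenomicRanges::width(ov)
    ) |>
      dplyr::group_by(.data$dmr_id, .data$mark) |>
      dplyr::summarise(overlap_bp = as.integer(sum(.data$overlap_bp)),
                       .groups = "drop")
  }) |>
    purrr::list_rbind()
  if (nrow(out) == 0) {
    return(tibble::tibble(dmr_id = character(), mark = character(),
                          overlap_bp = integer()))
  }
  out |>
    dplyr::filter(.data$overlap_bp >= min_overlap) |>
    dplyr::arrange(.data$dmr_id, .data$mark)
}

#' Percentage distribution of overlap records across marks
#'
#' Each (DMR, mark) overlapping pair counts once; a mark's share is
#' 100 x its pair count / total pairs, rounded half-up to integer percent
#' (so shares sum to 100 +- 1). This pair-count denominator is the
#' convention under which 2 DMRs overlapping 3 marks each give 33% per
#' mark, and 3 + 7x3 pairs give 13% / 29% / 29% / 29%.
#'
#' @param records Output of [overlap_dmr_marks()] (non-empty).
#' @return Tibble `mark`, `n_pairs`, `share_pct`, plus attribute
#'   `total_pairs`.
#' @export
overlap_fraction_distribution <- function(records) {
  if (nrow(records) == 0) rlang::abort("no overlap records to summarise")
  out <- records |>
    dplyr::count(.data$mark, name = "n_pairs") |>
    dplyr::mutate(share_pct = round_half_up(100 * .data$n_pairs / sum(.data$n_pairs))) |>
    dplyr::arrange(dplyr::desc(.data$n_pairs), .data$mark)
  attr(out, "total_pairs") <- sum(out$n_pairs)
  out
}

#' Rule-based chromatin-state classification
#'
#' Evaluates three architectures over the gene region plus promoter, using
#' signal-filtered peaks and the methylation of overlapping DMRs:
#'
#' * **bivalent** - H3K27me3 covers at least `bivalent_cov` (20%) of the
#'   promoter, H3K4me1 or H3K4me3 overlaps the promoter, and no H3K27ac
#'   peak lies in the region;
#' * **active_enhancer** - the merged span co-covered by both H3K4me3 and
#'   H3K27ac (gap-merged at `gap_merge` bp) reaches `broad_span` (5 kb)
#'   within the region, and the methylation of DMRs overlapping that
#'   co-domain sits in the intermediate band (`meth_band`, default
#'   20-60%);
#' * **super_enhancer** - the same broad co-domain plus H3K4me1 overlapping
#'   it, at least one BRD4, one MED1 and one DHS peak in the domain, and
#'   overlapping-DMR methylation below the low bound (< 20%).
#'
#' The call is the highest-priority rule fully satisfied (SE >
#' active_enhancer > bivalent > none); every criterion's truth value is
#' returned as evidence.
#'
#' @param gene_region Interval list/one-row tibble (`chrom`, `start`,
#'   `end`): the gene span.
#' @param promoter Interval like `gene_region`.
#' @param peaks Signal-filtered peak tibble with `mark`.
#' @param dmr_meth Optional tibble `chrom`, `start`, `end`, `median_meth`
#'   (percent) of DMRs for the relevant subgroup.
#' @param broad_span Minimum merged co-domain span, bp (default 5000).
#' @param gap_merge Gap tolerance when merging the co-domain, bp
#'   (default 1000).
#' @param meth_band Intermediate methylation band, percent
#'   (default `c(20, 60)`); below `meth_band[1]` counts as the low band.
#' @param bivalent_cov Minimum H3K27me3 promoter coverage fraction
#'   (default 0.2).
#' @return List of class `ren_state_call`: `state`, `evidence` (named
#'   logical), `domain_span_bp`, `domain_meth`.
#' @export
classify_chromatin_state <- function(gene_region, promoter, peaks,
                                     dmr_meth = NULL, broad_span = 5000,
                                     gap_merge = 1000, meth_band = c(20, 60),
                                     bivalent_cov = 0.2) {
  gene_region <- as.list(gene_region)
  promoter <- as.list(promoter)
  if (!identical(gene_region$chrom, promoter$chrom)) {
    rlang::abort("gene region and promoter must be on the same chromosome")
  }
  region <- list(chrom = gene_region$chrom,
                 start = min(gene_region$start, promoter$start),
                 end = max(gene_region$end, promoter$end))

  in_win <- function(mark, win) {
    pk <- dplyr::filter(peaks, .data$mark == !!mark, .data$chrom == win$chrom)
    pk[pmin(pk$end, win$end) - pmax(pk$start, win$start) > 0, , drop = FALSE]
  }
  cover_bp <- function(pk, win) {
    if (nrow(pk) == 0) return(0L)
    clipped <- dplyr::mutate(pk, start = pmax(.data$start, win$start),
                             end = pmin(.data$end, win$end))
    sum(GenomicRanges::width(GenomicRanges::reduce(tbl_to_gr(clipped))))
  }

  # bivalent criteria on the promoter
  k27me3_cov <- cover_bp(in_win("H3K27me3", promoter), promoter) /
    (promoter$end - promoter$start)
  biv_k4 <- nrow(in_win("H3K4me1", promoter)) > 0 || nrow(in_win("H3K4me3", promoter)) > 0
  no_k27ac <- nrow(in_win("H3K27ac", region)) == 0

  # broad H3K4me3/H3K27ac co-domain within the region
  k4me3 <- in_win("H3K4me3", region)
  k27ac <- in_win("H3K27ac", region)
  domain <- co_domain(k4me3, k27ac, region, gap_merge)
  domain_span <- if (is.null(domain)) 0L else domain$end - domain$start

  domain_meth <- NA_real_
  if (!is.null(domain) && !is.null(dmr_meth) && nrow(dmr_meth) > 0) {
    ov <- dmr_meth$chrom == domain$chrom &
      pmin(dmr_meth$end, domain$end) - pmax(dmr_meth$start, domain$start) > 0
    if (any(ov)) domain_meth <- stats::median(dmr_meth$median_meth[ov])
  }

  se_marks <- if (is.null(domain)) {
    c(H3K4me1 = FALSE, BRD4 = FALSE, MED1 = FALSE, DHS = FALSE)
  } else {
    c(
      H3K4me1 = nrow(in_win("H3K4me1", domain)) > 0,
      BRD4 = nrow(in_win("BRD4", domain)) > 0,
      MED1 = nrow(in_win("MED1", domain)) > 0,
      DHS = nrow(in_win("DHS", domain)) > 0
    )
  }

  evidence <- c(
    h3k27me3_promoter_cov = k27me3_cov >= bivalent_cov,
    h3k4_promoter = biv_k4,
    no_h3k27ac_region = no_k27ac,
    broad_codomain = domain_span >= broad_span,
    meth_intermediate = !is.na(domain_meth) &&
      domain_meth >= meth_band[1] && domain_meth <= meth_band[2],
    meth_low = !is.na(domain_meth) && domain_meth < meth_band[1],
    h3k4me1_domain = unname(se_marks["H3K4me1"]),
    brd4_domain = unname(se_marks["BRD4"]),
    med1_domain = unname(se_marks["MED1"]),
    dhs_domain = unname(se_marks["DHS"])
  )

  state <- if (evidence[["broad_codomain"]] && evidence[["meth_low"]] &&
               all(se_marks)) {
    "super_enhancer"
  } else if (evidence[["broad_codomain"]] && evidence[["meth_intermediate"]]) {
    "active_enhancer"
  } else if (evidence[["h3k27me3_promoter_cov"]] && evidence[["h3k4_promoter"]] &&
             evidence[["no_h3k27ac_region"]]) {
    "bivalent"
  } else {
    "none"
  }

  structure(
    list(state = state, evidence = evidence,
         domain_span_bp = as.integer(domain_span), domain_meth = domain_meth),
    class = "ren_state_call"
  )
}

#' @export
print.ren_state_call <- function(x, ...) {
  cat("chromatin state:", x$state, "\n")
  cat("co-domain span:", x$domain_span_bp, "bp; DMR methylation:",
      ifelse(is.na(x$domain_meth), "NA", sprintf("%.1f%%", x$domain_meth)), "\n")
  ev <- paste(names(x$evidence), ifelse(x$evidence, "yes", "no"), sep = "=")
  cat("evidence:", paste(ev, collapse = ", "), "\n")
  invisible(x)
}

# largest gap-merged span covered by BOTH H3K4me3 and H3K27ac inside region
co_domain <- function(k4me3, k27ac, region, gap_merge) {
  if (nrow(k4me3) == 0 || nrow(k27ac) == 0) return(NULL)
  clip <- function(pk) {
    dplyr::mutate(pk, start = pmax(.data$start, region$start),
                  end = pmin(.data$end, region$end))
  }
  a <- GenomicRanges::reduce(tbl_to_gr(clip(k4me3)), min.gapwidth = gap_merge)
  b <- GenomicRanges::reduce(tbl_to_gr(clip(k27ac)), min.gapwidth = gap_merge)
  both <- GenomicRanges::intersect(a, b)
  if (length(both) == 0) return(NULL)
  both <- GenomicRanges::reduce(both, min.gapwidth = gap_merge)
  widest <- both[which.max(GenomicRanges::width(both))]
  list(chrom = as.character(GenomicRanges::seqnames(widest)),
       start = GenomicRanges::start(widest) - 1L,
       end = GenomicRanges::end(widest))
}

#' Detect a CTCF-bounded window around a gene
#'
#' Finds the nearest CTCF peak fully upstream of the TSS and the nearest
#' fully downstream of the 3' end, each within `max_flank` bp, and returns
#' the window spanning from the upstream peak's start to the downstream
#' peak's end. Returns `NULL` when either flank is absent.
#'
#' @param gene_model List/one-row tibble with `chrom`, `tss`, `gene_end`
#'   (tss < gene_end on the forward layout used here).
#' @param ctcf CTCF peak tibble (`chrom`, `start`, `end`).
#' @param max_flank Maximum flank distance, bp (default 50000).
#' @return List `window` (chrom/start/end), `upstream_peak`,
#'   `downstream_peak`, `width_bp`, or `NULL`.
#' @export
detect_ctcf_window <- function(gene_model, ctcf, max_flank = 50000) {
  gm <- as.list(gene_model)
  stopifnot(gm$tss < gm$gene_end)
  pk <- dplyr::filter(ctcf, .data$chrom == gm$chrom)
  up <- dplyr::filter(pk, .data$end <= gm$tss, gm$tss - .data$end <= max_flank)
  down <- dplyr::filter(pk, .data$start >= gm$gene_end,
                        .data$start - gm$gene_end <= max_flank)
  if (nrow(up) == 0 || nrow(down) == 0) return(NULL)
  up <- up[which.max(up$end), ]
  down <- down[which.min(down$start), ]
  list(
    window = list(chrom = gm$chrom, start = up$start, end = down$end),
    upstream_peak = as.list(up[, c("chrom", "start", "end")]),
    downstream_peak = as.list(down[, c("chrom", "start", "end")]),
    width_bp = down$end - up$start
  )
}
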
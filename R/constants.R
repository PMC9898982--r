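# Shared vocabulary: disease stages, molecular subgroups, chromatin marks,
# and the default screening thresholds used across the pipeline.

#' Disease stages, molecular subgroups and chromatin marks
#'
#' The cohort vocabulary used throughout the package. Disease progresses
#' MGUS -> SMM -> MM; samples are stratified into four IgH-translocation
#' subgroups and two hyperdiploidy subgroups (D1/D2, split by CCND1 vs CCND2
#' overexpression). Healthy-donor plasma-B-cell pools are labelled
#' `"control"` for both stage and subgroup.
#'
#' @format Character vectors.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
ren_stages <- function() c("MGUS", "SMM", "MM")

#' @rdname vocabulary
#' @export
ren_subgroups <- function() c("t(4;14)", "t(11;14)", "t(14;16)", "t(14;20)", "D1", "D2")

#' @rdname vocabulary
#' @export
ren_control <- function() "control"

#' @rdname vocabulary
#' @export
ren_marks <- function() {
  c("H3K4me1", "H3K4me3", "H3K27ac", "H3K36me3", "H3K27me3",
    "BRD4", "MED1", "CTCF", "DHS", "MAF")
}

#' Adhesion-related gene panel
#'
#' The 36-gene screening panel: 18 alpha-integrin and 8 beta-integrin
#' subunits, 8 non-integrin adhesion molecules, and the co-stimulatory
#' molecules CD28 and CD86.
#'
#' @return Character vector of 36 gene symbols.
#' @export
adhesion_genes <- function() {
  c(
    # alpha-integrin subunits (18)
    "ITGA1", "ITGA2", "ITGA3", "ITGA4", "ITGA5", "ITGA6", "ITGA7", "ITGA8",
    "ITGA9", "ITGA10", "ITGA11", "ITGA2B", "ITGAD", "ITGAE", "ITGAL",
    "ITGAM", "ITGAV", "ITGAX",
    # beta-integrin subunits (8)
    "ITGB1", "ITGB2", "ITGB3", "ITGB4", "ITGB5", "ITGB6", "ITGB7", "ITGB8",
    # non-integrin adhesion molecules (8)
    "ICAM1", "MUC1", "CDH1", "CDH2", "CD44", "DSG2", "NCAM1", "VCAM1",
    # co-stimulatory signalling molecules (2)
    "CD28", "CD86"
  )
}

#' Default screening thresholds
#'
#' The thresholds applied by the pipeline stages: log2 fold-change > 1 at
#' p < 0.05 for differential expression, z-score difference > 2 versus
#' control, differential methylation > 10 percentage points, R-squared >
#' 0.4 for methylation-expression coupling, >= 50 bp for DMR-by-mark
#' overlaps, and peak signal (-log10 p) > 50.
#'
#' @return Named list of numeric thresholds.
#' @export
ren_thresholds <- function() {
  list(
    log2fc = 1, p = 0.05, z_diff = 2, dm = 10, r2 = 0.4,
    overlap_bp = 50, signal = 50
  )
}

# round half away from zero (base round() is banker's: round(12.5) == 12)
round_half_up <- function(x) floor(x + 0.5)

# interval tibble (chrom/start/end) -> GRanges; 0-based half-open in, so
# shift to 1-based closed for IRanges and back on the way out
tbl_to_gr <- function(tbl) {
  GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
}

gr_to_tbl <- function(gr) {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

assert_groups <- function(x, arg = "group") {
  valid <- c(ren_subgroups(), ren_control())
  bad <- setdiff(unique(x), valid)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unknown %s label(s): %s (expected one of %s)",
      arg, paste(bad, collapse = ", "), paste(valid, collapse = ", ")
    ))
  }
  invisible(x)
}
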
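#' Run the cohort CNA pipeline end to end
#'
#' Convenience wrapper chaining the analysis stages: preprocessing and
#' segmentation, mixture calling, region reduction, breakpoint detection on
#' the enrichment-free panel (re-segmented when enrichment probes are
#' present), per-probe and per-gene recurrence tests, and instability
#' scores. Association and survival screens are separate calls
#' ([compare_groups()], [logrank_permutation_regions()]) because they need
#' labels.
#'
#' @param cohort a [cna_cohort()].
#' @param genes optional gene models (see [read_gene_bed()]) for recurrent
#'   breakpoint-gene detection.
#' @param alpha,n_perm,undo_sd_short,undo_sd_long,undo_len,circ_width
#'   segmentation settings, see [segment_cohort()].
#' @param detrend remove wave artifacts before segmentation.
#' @param averror region-reduction heterogeneity budget.
#' @param fdr_cut FDR threshold for breakpoint recurrence tests.
#' @return list with elements `seg`, `mixture`, `calls`, `regions`, `bps`
#'   (breakpoint set with per-probe tests), `gene_breaks` (when `genes`
#'   given) and `scores`.
#' @export
cna_pipeline <- function(cohort, genes = NULL, alpha = 0.01, n_perm = 1000,
                         undo_sd_short = 2, undo_sd_long = 3, undo_len = 30,
                         circ_width = Inf, detrend = FALSE,
                         averror = 0.015, fdr_cut = 0.1) {
    seg <- segment_cohort(cohort, alpha = alpha, n_perm = n_perm,
                          undo_sd_short = undo_sd_short,
                          undo_sd_long = undo_sd_long, undo_len = undo_len,
                          circ_width = circ_width, detrend = detrend)
    mixture <- fit_call_mixture(seg)
    calls <- call_states(seg, mixture)
    regions <- reduce_regions(calls, averror = averror)
    if (any(cohort$panel$is_enrichment)) {
        seg_bp <- segment_cohort(drop_enrichment_probes(cohort),
                                 alpha = alpha, n_perm = n_perm,
                                 undo_sd_short = undo_sd_short,
                                 undo_sd_long = undo_sd_long,
                                 undo_len = undo_len,
                                 circ_width = circ_width, detrend = detrend)
    } else {
        seg_bp <- seg
    }
    bps <- test_breakpoint_locations(detect_breakpoints(seg_bp),
                                     fdr_cut = fdr_cut)
    gene_breaks <- NULL
    if (!is.null(genes))
        gene_breaks <- test_recurrent_genes(map_genes(bps, genes),
                                            fdr_cut = fdr_cut)
    list(seg = seg, mixture = mixture, calls = calls, regions = regions,
         bps = bps, gene_breaks = gene_breaks,
         scores = instability_scores(calls, bps))
}
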
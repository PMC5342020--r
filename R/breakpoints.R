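#' Detect CNA-associated chromosomal breakpoints
#'
#' A breakpoint is flagged, per sample, at the first probe of every segment
#' except each chromosome's first segment — the unique probe address where
#' the copy-number state changes. The cohort must be segmented on a panel
#' without enrichment probes (see [drop_enrichment_probes()]) so the
#' genome-wide per-probe breakage rate is estimated on evenly spaced probes.
#'
#' @param seg_cohort a `seg_cohort` segmented on an enrichment-free panel.
#' @return object of class `breakpoint_set`: probe x sample logical `flags`,
#'   per-probe cohort `count`, genome-wide per-probe breakpoint `rate`
#'   (total breakpoints / (probes x samples)) and per-sample totals
#'   `bp_score`.
#' @export
detect_breakpoints <- function(seg_cohort) {
    stopifnot(inherits(seg_cohort, "seg_cohort"))
    if (any(seg_cohort$panel$is_enrichment))
        stop("panel still contains enrichment probes; re-segment after ",
             "drop_enrichment_probes()")
    panel <- seg_cohort$panel
    P <- nrow(panel); S <- length(seg_cohort$samples)
    flags <- matrix(FALSE, P, S,
                    dimnames = list(panel$probe_id, seg_cohort$samples))
    segs <- seg_cohort$segments
    chrom_first <- !duplicated(panel$chrom)
    s_idx <- match(segs$sample, seg_cohort$samples)
    is_bp <- !chrom_first[segs$start_probe]
    flags[cbind(segs$start_probe[is_bp], s_idx[is_bp])] <- TRUE
    count <- rowSums(flags)
    structure(list(panel = panel, samples = seg_cohort$samples,
                   flags = flags, count = count,
                   rate = sum(count) / (P * S),
                   bp_score = colSums(flags)),
              class = "breakpoint_set")
}

#' @export
print.breakpoint_set <- function(x, ...) {
    cat("breakpoint_set:", sum(x$count), "breakpoints over",
        nrow(x$flags), "probes x", ncol(x$flags),
        "samples (rate ", signif(x$rate, 3), ")\n", sep = " ")
    invisible(x)
}

#' Test per-probe breakpoint recurrence
#'
#' Under random breakage each probe collects breakpoints independently at
#' the genome-wide rate r; the per-probe p-value is the binomial tail
#' P(X >= observed count) with X ~ Binomial(n_samples, r), corrected by
#' Benjamini-Hochberg over all usable probes.
#'
#' @param bps a `breakpoint_set`.
#' @param fdr_cut significance threshold on the BH-FDR.
#' @return the `breakpoint_set` with per-probe `p`, `fdr` and logical
#'   `significant` added.
#' @export
test_breakpoint_locations <- function(bps, fdr_cut = 0.1) {
    stopifnot(inherits(bps, "breakpoint_set"))
    S <- length(bps$samples)
    if (bps$rate == 0) {
        bps$p <- rep(1, length(bps$count))
    } else {
        bps$p <- unname(pbinom(bps$count - 1L, S, bps$rate,
                               lower.tail = FALSE))
    }
    bps$fdr <- p.adjust(bps$p, method = "BH")
    bps$significant <- bps$fdr < fdr_cut
    bps$fdr_cut <- fdr_cut
    bps
}

#' Map breakpoints onto gene footprints, pooling indistinguishable genes
#'
#' A gene's associated probes are the usable probes whose position falls
#' within its \[start, end\] interval; the gene is affected in a sample iff
#' at least one associated probe carries a breakpoint. Genes with identical
#' associated probe sets cannot be distinguished at array resolution and are
#' merged into one pooled entry (named after the alphabetically first
#' member, suffixed `*`), whose affected-sample set is the union over
#' members.
#'
#' @param bps a `breakpoint_set`.
#' @param genes data.frame of gene models (gene_name, chrom, start, end;
#'   1-based inclusive), e.g. from [read_gene_bed()].
#' @return object of class `gene_break_table`: per pooled gene the member
#'   names, probe indices, number of affected samples and frequency.
#' @export
map_genes <- function(bps, genes) {
    stopifnot(inherits(bps, "breakpoint_set"))
    panel <- bps$panel
    probe_sets <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
        idx <- which(panel$chrom == genes$chrom[i] &
                     panel$pos >= genes$start[i] &
                     panel$pos <= genes$end[i])
        probe_sets[[i]] <- idx
    }
    n_probes <- lengths(probe_sets)
    if (any(n_probes == 0))
        message(sum(n_probes == 0),
                " gene(s) with no associated probes excluded: ",
                paste(head(genes$gene_name[n_probes == 0], 5),
                      collapse = ", "))
    keep <- which(n_probes > 0)
    key <- vapply(probe_sets[keep],
                  function(p) paste(p, collapse = ","), "")
    pools <- split(keep, key)
    S <- length(bps$samples)
    rows <- lapply(pools, function(members) {
        nm <- sort(genes$gene_name[members])
        probes <- probe_sets[[members[1]]]
        affected <- colSums(bps$flags[probes, , drop = FALSE]) > 0
        data.frame(
            pool_name = if (length(nm) > 1) paste0(nm[1], "*") else nm[1],
            member_genes = paste(nm, collapse = ";"),
            n_members = length(nm),
            chrom = genes$chrom[members[1]],
            n_probes = length(probes),
            probe_first = probes[1], probe_last = probes[length(probes)],
            n_affected = sum(affected),
            frequency = sum(affected) / S,
            stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    o <- order(chrom_rank(tab$chrom), tab$probe_first)
    tab <- tab[o, , drop = FALSE]
    affected_mat <- do.call(rbind, lapply(pools[o], function(members) {
        probes <- probe_sets[[members[1]]]
        colSums(bps$flags[probes, , drop = FALSE]) > 0
    }))
    rownames(affected_mat) <- tab$pool_name
    structure(list(table = tab, affected = affected_mat,
                   samples = bps$samples, rate = bps$rate),
              class = "gene_break_table")
}

#' @export
print.gene_break_table <- function(x, ...) {
    cat("gene_break_table:", nrow(x$table), "(pooled) genes;",
        sum(x$table$n_affected > 0), "affected in >= 1 sample\n")
    invisible(x)
}

#' Identify recurrent breakpoint genes with a discrete FDR
#'
#' Per (pooled) gene g with m_g associated probes, the null probability of
#' being affected in one sample is q_g = 1 - (1 - r)^m_g under the
#' genome-wide breakage rate r; the p-value is P(X >= k_g) with
#' X ~ Binomial(n_samples, q_g). Multiple testing uses a Tarone-Gilbert
#' discrete FDR: genes whose minimum achievable p-value (all samples
#' affected, q_g^n) exceeds `fdr_cut` can never be rejected and are excluded
#' before Benjamini-Hochberg, which shrinks the correction denominator and
#' never flags fewer genes than plain BH.
#'
#' @param gbt a `gene_break_table` from [map_genes()].
#' @param fdr_cut significance threshold.
#' @return the `gene_break_table` with columns `p`, `min_p`, `fdr` (1 for
#'   excluded genes) and `significant` added to its `table`.
#' @export
test_recurrent_genes <- function(gbt, fdr_cut = 0.1) {
    stopifnot(inherits(gbt, "gene_break_table"))
    tab <- gbt$table
    S <- length(gbt$samples)
    q <- 1 - (1 - gbt$rate)^tab$n_probes
    tab$p <- pbinom(tab$n_affected - 1L, S, q, lower.tail = FALSE)
    tab$min_p <- q^S
    tab$fdr <- rep(1, nrow(tab))
    testable <- tab$min_p <= fdr_cut
    if (any(testable))
        tab$fdr[testable] <- p.adjust(tab$p[testable], method = "BH")
    tab$significant <- tab$fdr < fdr_cut
    gbt$table <- tab
    gbt$fdr_cut <- fdr_cut
    gbt
}
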
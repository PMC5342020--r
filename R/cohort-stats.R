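# internal: 2x2 chi-square (no continuity correction) for many regions at
# once. carriers: samples x regions binary matrix; g: binary group vector.
chisq2x2_vec <- function(carriers, g) {
    S <- length(g)
    n1 <- sum(g)
    m1 <- colSums(carriers)
    a <- as.vector(crossprod(carriers, g))
    num <- S * (a * S - n1 * m1)^2  # S^2 (a - n1 m1 / S)^2 = S^2 (ad-bc)^2/S^2
    den <- n1 * (S - n1) * m1 * (S - m1)
    stat <- ifelse(den > 0, num / den, 0)
    stat
}

#' Two-group association tests over CNA regions with permutation FDR
#'
#' For each region and aberration type (gain vs no-gain, loss vs no-loss,
#' amplifications counting as gains), computes the 2x2 chi-square statistic
#' without continuity correction, a permutation p-value under group-label
#' shuffling, and a permutation-based FDR: the average number of null
#' statistics reaching a region's observed statistic divided by the number
#' of observed statistics reaching it. The FDR family pools both aberration
#' types (one multiple-testing correction over all tests, as when FDR is
#' applied to the pooled permutation p-values), with permutations shared
#' between types. Regions aberrant in fewer than `min_freq` of samples are
#' excluded per type before testing.
#'
#' @param region_set a `cna_regions` object.
#' @param labels two-level factor over samples.
#' @param n_perm number of label permutations.
#' @param min_freq minimum carrier frequency for a region to be tested.
#' @param fdr_cut significance threshold on the permutation FDR.
#' @param seed optional RNG seed for the permutations.
#' @param types aberration types to test.
#' @return data.frame (region, chrom, type, stat, p, fdr, significant,
#'   carrier frequencies per group).
#' @export
compare_groups <- function(region_set, labels, n_perm = 10000,
                           min_freq = 0.10, fdr_cut = 0.2, seed = NULL,
                           types = c("gain", "loss")) {
    stopifnot(inherits(region_set, "cna_regions"))
    labels <- as.factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    if (any(table(labels) == 0)) stop("a group is empty")
    if (length(labels) != length(region_set$samples))
        stop("labels must align with samples")
    if (!is.null(seed)) set.seed(seed)
    g <- as.numeric(labels == levels(labels)[1])
    # assemble one combined family over region x type: the FDR is estimated
    # over all tests together, with permutations shared between types
    Cs <- list(); info <- list()
    for (type in types) {
        carr <- if (type == "gain") t(region_set$calls >= 1)
                else t(region_set$calls == -1)  # samples x regions
        keep <- which(colMeans(carr) >= min_freq)
        if (!length(keep)) next
        Cs[[type]] <- carr[, keep, drop = FALSE]
        info[[type]] <- data.frame(region = keep, type = type,
                                   stringsAsFactors = FALSE)
    }
    if (!length(Cs)) return(NULL)
    C <- do.call(cbind, Cs)
    info <- do.call(rbind, info)
    obs <- chisq2x2_vec(C, g)
    R <- length(obs)
    exceed <- numeric(R)
    fdr_num <- numeric(R)
    for (b in seq_len(n_perm)) {
        st <- chisq2x2_vec(C, sample(g))
        exceed <- exceed + (st >= obs - 1e-9)
        fdr_num <- fdr_num + (R - findInterval(obs - 1e-9, sort(st)))
    }
    p <- (1 + exceed) / (1 + n_perm)
    rk <- vapply(obs, function(t) sum(obs >= t - 1e-9), 0)
    fdr <- pmin((fdr_num / n_perm) / rk, 1)
    f1 <- 100 * colMeans(C[g == 1, , drop = FALSE])
    f2 <- 100 * colMeans(C[g == 0, , drop = FALSE])
    res <- data.frame(
        region = info$region,
        chrom = region_set$regions$chrom[info$region],
        type = info$type, stat = obs, p = p, fdr = fdr,
        significant = fdr < fdr_cut,
        freq_pct_group1 = f1, freq_pct_group2 = f2,
        stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Chi-square statistic and permutation p for one 2x2 table layout
#'
#' Convenience wrapper for a single carrier/group split: chi-square without
#' continuity correction plus a label-permutation p-value.
#'
#' @param carrier logical/binary vector.
#' @param group logical/binary vector.
#' @param n_perm permutations.
#' @param seed optional RNG seed.
#' @return list(stat, p_asymptotic, p_perm).
#' @export
chisq_permutation <- function(carrier, group, n_perm = 10000, seed = NULL) {
    stopifnot(length(carrier) == length(group))
    if (!is.null(seed)) set.seed(seed)
    C <- matrix(as.numeric(carrier), ncol = 1)
    g <- as.numeric(group)
    obs <- chisq2x2_vec(C, g)
    exceed <- 0
    for (b in seq_len(n_perm))
        exceed <- exceed + (chisq2x2_vec(C, sample(g)) >= obs - 1e-9)
    list(stat = obs,
         p_asymptotic = pchisq(obs, df = 1, lower.tail = FALSE),
         p_perm = (1 + exceed) / (1 + n_perm))
}

#' Per-sample chromosomal-instability scores
#'
#' The CNA-score counts the probes of a sample in a non-neutral copy-number
#' state; the BP-score counts its CNA-associated breakpoint locations
#' (computed on the enrichment-free panel).
#'
#' @param calls a `cna_calls` object.
#' @param bps a `breakpoint_set` (may be based on a filtered panel).
#' @return data.frame (sample, cna_score, bp_score).
#' @export
instability_scores <- function(calls, bps) {
    stopifnot(inherits(calls, "cna_calls"), inherits(bps, "breakpoint_set"))
    if (!identical(calls$samples, bps$samples))
        stop("calls and breakpoints cover different samples")
    data.frame(sample = calls$samples,
               cna_score = colSums(calls$states != 0),
               bp_score = unname(bps$bp_score))
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration p-value when the combined sample size is at most 20 and
#' there are no ties; normal approximation (with tie correction and
#' continuity correction) otherwise. All-tied input returns p = 1.
#'
#' @param values numeric scores.
#' @param labels two-level grouping.
#' @return list(U, p).
#' @export
mann_whitney_scores <- function(values, labels) {
    labels <- as.factor(labels)
    if (nlevels(labels) != 2) stop("labels must have exactly two levels")
    x <- values[labels == levels(labels)[1]]
    y <- values[labels == levels(labels)[2]]
    if (!length(x) || !length(y)) stop("both groups must be non-empty")
    if (length(unique(values)) == 1)
        return(list(U = length(x) * length(y) / 2, p = 1))
    exact <- (length(x) + length(y) <= 20) && !any(duplicated(values))
    wt <- suppressWarnings(wilcox.test(x, y, exact = exact))
    list(U = unname(wt$statistic), p = wt$p.value)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional hypergeometric test: two-sided p is the total probability of
#' tables (fixed margins) no more likely than the observed one. The sample
#' odds ratio is returned as is and with Haldane's 0.5 continuity correction
#' for display when a cell is zero.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list(p, odds_ratio, odds_ratio_display, flagged) where `flagged`
#'   marks a zero margin (p = 1, OR undefined).
#' @export
fisher_exact <- function(tab) {
    tab <- as.matrix(tab)
    if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
        any(tab != round(tab)))
        stop("need a 2x2 table of non-negative integer counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        return(list(p = 1, odds_ratio = NA_real_,
                    odds_ratio_display = NA_real_, flagged = TRUE))
    p <- fisher.test(tab)$p.value
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    ord <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
    list(p = p, odds_ratio = or, odds_ratio_display = ord, flagged = FALSE)
}

#' Hierarchical clustering of samples on call posteriors
#'
#' Pairwise sample dissimilarity is the mean over regions of the total
#' variation distance between the two samples' four-class posterior vectors
#' (a metric in \[0, 1\]); agglomeration uses Ward linkage ('ward.D', the
#' classic criterion) and is deterministic.
#'
#' @param region_set a `cna_regions` object (clustering uses its
#'   probe-averaged region posteriors).
#' @param k optional number of flat clusters to cut.
#' @return list(hclust, dist, clusters) — `clusters` is `NULL` unless `k`
#'   is given.
#' @export
cluster_samples <- function(region_set, k = NULL) {
    stopifnot(inherits(region_set, "cna_regions"))
    S <- length(region_set$samples)
    if (S < 2) stop("need >= 2 samples to cluster")
    R <- dim(region_set$post)[1]
    # samples x (regions*4); manhattan/2/R = mean TV distance over regions
    M <- matrix(aperm(region_set$post, c(2, 1, 3)), nrow = S)
    rownames(M) <- region_set$samples
    d <- dist(M, method = "manhattan") / (2 * R)
    hc <- hclust(d, method = "ward.D")
    list(hclust = hc, dist = d,
         clusters = if (!is.null(k)) cutree(hc, k = k))
}
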
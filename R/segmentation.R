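#' Median-normalize log2 ratios
#'
#' Subtracts each sample's median log2 ratio so the per-sample median is
#' exactly zero.
#'
#' @param cohort a [cna_cohort()].
#' @return the cohort with normalized ratios.
#' @export
median_normalize <- function(cohort) {
    stopifnot(inherits(cohort, "cna_cohort"))
    med <- apply(cohort$ratios, 2, median)
    cohort$ratios <- sweep(cohort$ratios, 2, med)
    cohort
}

#' Remove low-frequency wave artifacts
#'
#' Estimates a per-sample, per-chromosome low-frequency trend and subtracts
#' it, in two stages. Stage one captures the bulk of the wave with a
#' step-rejecting smoother (running median whose window exceeds twice the
#' width of typical copy-number segments, then loess), applied twice to
#' undo the median's amplitude attenuation. Stage two protects genuine
#' copy-number steps: the stage-one residual is segmented, each boundary's
#' jump height is estimated from local mean differences in the raw signal
#' (trend-free over short windows, so artifact-induced boundaries get
#' near-zero jumps), the cumulative step function is subtracted, and the
#' trend is re-fit by plain loess on the step-free remainder. Copy-number
#' steps much narrower than the span window are preserved; smooth waves
#' with period above the span window are removed.
#'
#' @param cohort a [cna_cohort()].
#' @param span loess span as a fraction of each chromosome's probes, in
#'   (0, 1]; the running-median window is `span * n / 1.2` probes.
#' @param min_jump smallest boundary jump (log2 units) treated as a genuine
#'   copy-number step; smaller local differences are attributed to trend
#'   drift and left for the smoother.
#' @return the detrended cohort.
#' @export
detrend_waves <- function(cohort, span = 0.3, min_jump = 0.25) {
    stopifnot(inherits(cohort, "cna_cohort"))
    if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
    lofit <- function(y, pos) {
        stats::fitted(stats::loess(y ~ pos, span = span, degree = 2,
                                   control = stats::loess.control(
                                       surface = "direct")))
    }
    for (ch in unique(cohort$panel$chrom)) {
        idx <- which(cohort$panel$chrom == ch)
        n <- length(idx)
        if (n < 10) {
            warning("chromosome ", ch, " has < 10 probes; not detrended")
            next
        }
        pos <- cohort$panel$pos[idx]
        k <- min(max(3L, as.integer(span * n / 1.2)), n - 1L)
        if (k %% 2 == 0) k <- k + 1L
        chrom1 <- data.frame(probe_id = as.character(seq_len(n)),
                             chrom = ch, pos = pos)
        class(chrom1) <- c("probe_panel", "data.frame")
        for (s in seq_along(cohort$samples)) {
            y <- cohort$ratios[idx, s]
            trend <- numeric(n)
            for (it in 1:2) {  # stage one: median-prefiltered wave capture
                m <- stats::runmed(y - trend, k, endrule = "median")
                trend <- trend + lofit(m, pos)
            }
            # stage two: remove copy-number steps before the final fit.
            # Boundaries come from segmenting the stage-one residual; jump
            # heights are estimated from local mean differences in the raw
            # signal (trend-free over short windows), so boundaries induced
            # by stage-one artifacts receive near-zero jumps and genuine
            # steps their full height.
            for (it in 1:2) {
                sg <- cbs_segment(y - trend, chrom1, alpha = 0.01,
                                  n_perm = 200)
                p <- numeric(n)
                if (nrow(sg) > 1) {
                    bnd <- sg$start_probe[-1]
                    lims <- c(1L, bnd, n + 1L)
                    lev <- 0
                    for (bi in seq_along(bnd)) {
                        b <- bnd[bi]
                        h <- min(20L, b - lims[bi], lims[bi + 2] - b)
                        jump <- mean(y[b:(b + h - 1)]) -
                            mean(y[(b - h):(b - 1)])
                        # smooth-trend drift produces small spurious jumps;
                        # only calling-relevant step heights are removed
                        if (abs(jump) < min_jump) jump <- 0
                        lev <- lev + jump
                        p[b:n] <- lev
                    }
                }
                trend <- lofit(y - p, pos)
            }
            cohort$ratios[idx, s] <- y - trend
        }
    }
    cohort
}

#' Noise SD of a probe series
#'
#' Median absolute deviation of lag-1 differences scaled by 1/sqrt(2): an
#' estimate of the probe-level noise SD that is insensitive to segmental
#' structure.
#'
#' @param x numeric vector of log2 ratios (>= 2 probes).
#' @param cutoff QC failure threshold.
#' @return list with `mad` and logical `pass` (`mad < cutoff`).
#' @export
qc_mad <- function(x, cutoff = 0.4) {
    if (length(x) < 2) stop("qc_mad needs >= 2 probes")
    m <- mad(diff(x)) / sqrt(2)
    list(mad = m, pass = m < cutoff)
}

# internal: recursive circular-binary segmentation of one chromosome's
# ratios. A kept scan may contribute one change point (edge arc) or two
# (interior arc). Returns integer vector of segment start offsets (1-based,
# within window).
split_recursive <- function(x, alpha, n_perm, circ_width, min_width = 2L) {
    n <- length(x)
    if (n < 2 * min_width) return(1L)
    early <- ceiling(alpha * (n_perm + 1))
    res <- .cbs_perm(x, as.integer(min(circ_width, n)), n_perm, early)
    if (res$p >= alpha) return(1L)
    cuts <- setdiff(c(res$i, res$j), c(0L, n))
    starts <- 1L
    lo <- 0L
    for (cut in c(cuts, n)) {
        part <- split_recursive(x[(lo + 1):cut], alpha, n_perm, circ_width,
                                min_width)
        starts <- union(starts, lo + part)
        lo <- cut
        starts <- union(starts, if (lo < n) lo + 1L)
    }
    sort(starts)
}

# internal: SD-undo pruning. starts = segment start offsets within a
# chromosome window; merges adjacent segments whose mean difference is below
# undo_sd * sigma, using the long-segment multiplier when both flanking
# segments exceed undo_len probes.
undo_merge <- function(x, starts, sigma, undo_sd_short, undo_sd_long,
                       undo_len) {
    repeat {
        if (length(starts) < 2) break
        ends <- c(starts[-1] - 1L, length(x))
        means <- vapply(seq_along(starts),
                        function(i) mean(x[starts[i]:ends[i]]), 0)
        lens <- ends - starts + 1L
        d <- abs(diff(means))
        mult <- ifelse(lens[-length(lens)] > undo_len & lens[-1] > undo_len,
                       undo_sd_long, undo_sd_short)
        undo <- d < mult * sigma
        if (!any(undo)) break
        j <- which(undo)[which.min(d[undo])]
        starts <- starts[-(j + 1)]
    }
    starts
}

#' Segment one sample's log2 ratios
#'
#' Circular binary segmentation: per chromosome, the maximal standardized
#' mean contrast of an arc of probes against the rest of the window is
#' located recursively, a split being retained only when its within-window
#' permutation p-value falls below `alpha` (an interior arc contributes two
#' change points, an edge-anchored arc one); followed by "SD-undo" pruning that re-merges adjacent
#' segments whose mean difference is below `undo_sd * sigma`, where `sigma`
#' is the sample's residual SD (MAD of lag-1 differences / sqrt(2)) and the
#' multiplier is `undo_sd_short` for short flanking segments and
#' `undo_sd_long` when both neighbours exceed `undo_len` probes.
#'
#' @param x numeric vector of one sample's ratios in panel order.
#' @param panel the matching [probe_panel()].
#' @param alpha significance level for keeping a split.
#' @param n_perm permutations per candidate split.
#' @param undo_sd_short,undo_sd_long SD-undo multipliers.
#' @param undo_len probe-count threshold separating short from long segments.
#' @param circ_width maximum width (probes) of interior arcs scanned by the
#'   circular statistic; the default scans all arcs (full circular
#'   statistic). Lowering it bounds the quadratic scan cost but loses exact
#'   localization of interior segments wider than the cap.
#' @return data.frame (chrom, start_probe, end_probe, num_probes, seg_mean)
#'   with global probe indices.
#' @export
cbs_segment <- function(x, panel, alpha = 0.01, n_perm = 1000,
                        undo_sd_short = 2, undo_sd_long = 3, undo_len = 30,
                        circ_width = Inf) {
    stopifnot(length(x) == nrow(panel))
    sigma <- if (length(x) >= 2) mad(diff(x)) / sqrt(2) else 0
    out <- list()
    for (ch in unique(panel$chrom)) {
        idx <- which(panel$chrom == ch)
        xc <- x[idx]
        if (length(xc) == 1) {
            starts <- 1L
        } else {
            starts <- split_recursive(xc, alpha, n_perm, circ_width)
            if (sigma > 0)
                starts <- undo_merge(xc, starts, sigma, undo_sd_short,
                                     undo_sd_long, undo_len)
        }
        ends <- c(starts[-1] - 1L, length(xc))
        out[[ch]] <- data.frame(
            chrom = ch,
            start_probe = idx[starts],
            end_probe = idx[ends],
            num_probes = ends - starts + 1L,
            seg_mean = vapply(seq_along(starts),
                              function(i) mean(xc[starts[i]:ends[i]]), 0),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Re-center a segmented sample at its modal state
#'
#' Estimates the mode of the probe-count-weighted segment-mean distribution
#' by kernel density and subtracts it from all segment means (and ratios),
#' re-centering the dominant — assumed copy-number-neutral — state at zero.
#'
#' @param segments per-sample segment data.frame from [cbs_segment()].
#' @param x optional ratio vector to shift along with the means.
#' @return list with shifted `segments`, shifted `x` (if given) and the
#'   subtracted `shift`.
#' @export
mode_normalize <- function(segments, x = NULL) {
    w <- segments$num_probes / sum(segments$num_probes)
    if (nrow(segments) == 1 || length(unique(segments$seg_mean)) == 1) {
        shift <- segments$seg_mean[1]
    } else {
        bw <- tryCatch(stats::bw.SJ(segments$seg_mean),
                       error = function(e) stats::bw.nrd0(segments$seg_mean))
        d <- density(segments$seg_mean, weights = w, bw = bw, n = 2048)
        shift <- d$x[which.max(d$y)]
    }
    segments$seg_mean <- segments$seg_mean - shift
    list(segments = segments, x = if (!is.null(x)) x - shift, shift = shift)
}

#' Segment a whole cohort
#'
#' Runs the per-sample preprocessing and segmentation pipeline:
#' median normalization, optional wave detrending, CBS-style segmentation,
#' post-segmental mode normalization, and MAD-based QC.
#'
#' @param cohort a [cna_cohort()].
#' @param detrend logical; remove wave artifacts first (default off).
#' @param span detrending span.
#' @param mad_cutoff QC threshold on the per-sample noise MAD.
#' @inheritParams cbs_segment
#' @return object of class `seg_cohort`: panel, samples, normalized `ratios`,
#'   `segments` (one data.frame over all samples) and per-sample `qc`.
#' @export
segment_cohort <- function(cohort, alpha = 0.01, n_perm = 1000,
                           undo_sd_short = 2, undo_sd_long = 3,
                           undo_len = 30, circ_width = Inf,
                           detrend = FALSE, span = 0.3,
                           mad_cutoff = 0.4) {
    stopifnot(inherits(cohort, "cna_cohort"))
    cohort <- median_normalize(cohort)
    if (detrend) cohort <- detrend_waves(cohort, span)
    segs <- vector("list", length(cohort$samples))
    qc <- data.frame(sample = cohort$samples, mad = NA_real_, pass = NA)
    for (s in seq_along(cohort$samples)) {
        x <- cohort$ratios[, s]
        sg <- cbs_segment(x, cohort$panel, alpha, n_perm,
                          undo_sd_short, undo_sd_long, undo_len, circ_width)
        mn <- mode_normalize(sg, x)
        cohort$ratios[, s] <- mn$x
        sg <- mn$segments
        sg <- cbind(sample = cohort$samples[s], sg, stringsAsFactors = FALSE)
        segs[[s]] <- sg
        q <- qc_mad(x, mad_cutoff)
        qc$mad[s] <- q$mad
        qc$pass[s] <- q$pass
    }
    structure(list(panel = cohort$panel, samples = cohort$samples,
                   ratios = cohort$ratios,
                   segments = do.call(rbind, segs), qc = qc),
              class = "seg_cohort")
}

#' @export
print.seg_cohort <- function(x, ...) {
    cat("seg_cohort:", length(x$samples), "samples,",
        nrow(x$segments), "segments,",
        sum(!x$qc$pass), "QC failures\n")
    invisible(x)
}
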
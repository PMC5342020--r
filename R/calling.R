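STATE_LEVELS <- c(-1L, 0L, 1L, 2L)
STATE_NAMES <- c("loss", "neutral", "gain", "amplification")

# internal: weighted Gaussian EM with per-class location boxes enforcing
# identifiability (loss < neutral < gain < amplification); the neutral box
# is [-0.1, 0.1]. Returns list(pi, mu, sd, loglik, degenerate).
em_weighted <- function(y, w, mu0, sd0, pi0, lo, hi,
                        max_iter = 500, tol = 1e-8) {
    K <- length(mu0)
    mu <- pmin(pmax(mu0, lo), hi); sdv <- sd0; pi <- pi0
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
        dens <- vapply(seq_len(K),
                       function(k) pi[k] * dnorm(y, mu[k], sdv[k]),
                       numeric(length(y)))
        tot <- rowSums(dens)
        tot[tot < 1e-300] <- 1e-300
        r <- dens / tot
        ll <- sum(w * log(tot))
        Nk <- colSums(w * r)
        pi <- Nk / sum(Nk)
        for (k in seq_len(K)) {
            if (Nk[k] < 1e-12) next
            mu[k] <- sum(w * r[, k] * y) / Nk[k]
            sdv[k] <- sqrt(sum(w * r[, k] * (y - mu[k])^2) / Nk[k])
        }
        mu <- pmin(pmax(mu, lo), hi)
        sdv <- pmin(pmax(sdv, 0.03), 0.5)
        if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
        ll_old <- ll
    }
    list(pi = pi, mu = mu, sd = sdv, loglik = ll,
         degenerate = any(pi < 1e-4))
}

#' Fit the cohort-wide copy-number state mixture
#'
#' Fits a four-component Gaussian mixture (loss < neutral < gain <
#' amplification, mean ordering enforced, neutral mean constrained to
#' \[-0.1, 0.1\]) to all segment means in the cohort, each mean weighted by
#' its segment's probe count. EM is initialized by quantile seeding (2.5, 50,
#' 90 and 99th percentiles) with 10 deterministically jittered restarts; the
#' best-likelihood fit is kept. If the amplification component degenerates
#' (weight < 1e-4) the model is refit with three components and the
#' amplification class retained with zero weight.
#'
#' @param seg_cohort a `seg_cohort` from [segment_cohort()], or a data.frame
#'   of segments with columns `seg_mean` and `num_probes`.
#' @param class_boxes 2 x 4 matrix of per-class mean bounds (rows lo/hi,
#'   columns loss/neutral/gain/amplification). These keep the components
#'   identifiable when a class is rare or absent; defaults reflect typical
#'   tumor-content-diluted log2 offsets.
#' @return object of class `cna_mixture`: `pi`, `mu`, `sd` (length 4, in
#'   state order loss/neutral/gain/amplification) and `loglik`.
#' @export
fit_call_mixture <- function(seg_cohort,
                             class_boxes = rbind(
                                 lo = c(-3, -0.1, 0.15, 0.8),
                                 hi = c(-0.15, 0.1, 0.75, 3))) {
    segs <- if (inherits(seg_cohort, "seg_cohort")) seg_cohort$segments
            else seg_cohort
    y <- segs$seg_mean
    w <- segs$num_probes
    if (diff(range(y)) < 1e-8) {
        # single effective state: everything neutral
        m <- mean(y)
        out <- list(pi = c(1e-9, 1 - 3e-9, 1e-9, 1e-9),
                    mu = c(m - 0.6, m, m + 0.45, m + 1.2),
                    sd = rep(0.05, 4), loglik = NA_real_, n_components = 1L)
        class(out) <- "cna_mixture"
        return(out)
    }
    if (length(unique(y)) < 4)
        stop("need >= 4 distinct segment means cohort-wide")
    wq <- function(p) quantile(y, p, names = FALSE)
    mu0 <- wq(c(0.025, 0.5, 0.9, 0.99))
    sd0 <- rep(max(0.05, sqrt(sum(w * (y - mean(y))^2) / sum(w)) / 4), 4)
    pi0 <- c(0.15, 0.6, 0.2, 0.05)
    fit_k <- function(K) {
        best <- NULL
        for (j in 0:9) {
            set.seed(1000 + j)  # fixed restart seeds for determinism
            jit <- if (j == 0) rep(0, K) else rnorm(K, 0, 0.02 * j)
            f <- em_weighted(y, w, sort(mu0[seq_len(K)] + jit),
                             sd0[seq_len(K)],
                             pi0[seq_len(K)] / sum(pi0[seq_len(K)]),
                             class_boxes["lo", seq_len(K)],
                             class_boxes["hi", seq_len(K)])
            if (is.null(best) || f$loglik > best$loglik) best <- f
        }
        best
    }
    fit <- fit_k(4)
    n_comp <- 4L
    if (fit$degenerate) {
        fit3 <- fit_k(3)
        fit <- list(pi = c(fit3$pi, 1e-12), mu = c(fit3$mu, max(y) + 1),
                    sd = c(fit3$sd, 0.05), loglik = fit3$loglik)
        fit$pi <- fit$pi / sum(fit$pi)
        n_comp <- 3L
    }
    out <- list(pi = fit$pi, mu = fit$mu, sd = fit$sd, loglik = fit$loglik,
                n_components = n_comp)
    names(out$pi) <- names(out$mu) <- names(out$sd) <- STATE_NAMES
    class(out) <- "cna_mixture"
    out
}

#' @export
print.cna_mixture <- function(x, ...) {
    cat("cna_mixture (", x$n_components, " effective components)\n", sep = "")
    print(round(rbind(pi = x$pi, mu = x$mu, sd = x$sd), 4))
    invisible(x)
}

#' Call copy-number states from segment means
#'
#' Computes per-segment class posteriors by Bayes' rule under the fitted
#' mixture, weighting the log-likelihood by the segment's probe count, and
#' assigns the state whose posterior exceeds 0.5 (defaulting to neutral when
#' no class reaches 0.5). Probes inherit their segment's state and posterior.
#'
#' @param seg_cohort a `seg_cohort`.
#' @param mixture a `cna_mixture` from [fit_call_mixture()].
#' @return object of class `cna_calls`: probe x sample `states` matrix with
#'   values in \{-1, 0, 1, 2\}, probe x sample x class posterior array
#'   `post`, the segment table with posterior columns, and the mixture.
#' @export
call_states <- function(seg_cohort, mixture) {
    stopifnot(inherits(seg_cohort, "seg_cohort"),
              inherits(mixture, "cna_mixture"))
    segs <- seg_cohort$segments
    n_seg <- nrow(segs)
    loglik <- vapply(1:4, function(k)
        log(mixture$pi[k]) +
            segs$num_probes * dnorm(segs$seg_mean, mixture$mu[k],
                                    mixture$sd[k], log = TRUE),
        numeric(n_seg))
    m <- apply(loglik, 1, max)
    post <- exp(loglik - m)
    post <- post / rowSums(post)
    colnames(post) <- STATE_NAMES
    best <- apply(post, 1, which.max)
    state <- ifelse(post[cbind(seq_len(n_seg), best)] > 0.5,
                    STATE_LEVELS[best], 0L)
    segs$post_loss <- post[, 1]; segs$post_neutral <- post[, 2]
    segs$post_gain <- post[, 3]; segs$post_amp <- post[, 4]
    segs$state <- state

    P <- nrow(seg_cohort$panel); S <- length(seg_cohort$samples)
    states <- matrix(0L, P, S, dimnames = list(seg_cohort$panel$probe_id,
                                               seg_cohort$samples))
    ppost <- array(0, dim = c(P, S, 4),
                   dimnames = list(seg_cohort$panel$probe_id,
                                   seg_cohort$samples, STATE_NAMES))
    for (i in seq_len(n_seg)) {
        s <- match(segs$sample[i], seg_cohort$samples)
        idx <- segs$start_probe[i]:segs$end_probe[i]
        states[idx, s] <- segs$state[i]
        ppost[idx, s, ] <- rep(post[i, ], each = length(idx))
    }
    structure(list(panel = seg_cohort$panel, samples = seg_cohort$samples,
                   states = states, post = ppost, segments = segs,
                   mixture = mixture),
              class = "cna_calls")
}

#' @export
print.cna_calls <- function(x, ...) {
    tab <- table(factor(x$states, levels = STATE_LEVELS, labels = STATE_NAMES))
    cat("cna_calls:", nrow(x$states), "probes x", ncol(x$states), "samples\n")
    print(round(100 * tab / sum(tab), 1))
    invisible(x)
}

#' Reduce probe-level calls to co-aberrant regions
#'
#' Greedy left-to-right merge of adjacent probes (within chromosomes) into
#' maximal runs in which every member probe disagrees with the region's
#' consensus call signature (per-sample modal state) in at most `averror` of
#' samples on average. With `averror = 0` regions are exactly the maximal
#' runs of identical call columns.
#'
#' @param calls a `cna_calls` object.
#' @param averror tolerated average per-sample call-disagreement rate.
#' @return object of class `cna_regions`: `regions` (chrom, first_probe,
#'   last_probe, n_probes), region x sample `calls` matrix, region x sample x
#'   class posterior array `post` (probe-averaged), and per-region
#'   gain/loss frequencies.
#' @export
reduce_regions <- function(calls, averror = 0.015) {
    stopifnot(inherits(calls, "cna_calls"))
    panel <- calls$panel
    S <- ncol(calls$states)
    st_idx <- matrix(match(calls$states, STATE_LEVELS), nrow(calls$states))
    regions <- list(); rcalls <- list(); rpost <- list()
    consensus_of <- function(counts) STATE_LEVELS[apply(counts, 2, which.max)]
    for (ch in unique(panel$chrom)) {
        idx <- which(panel$chrom == ch)
        start <- 1L
        counts <- matrix(0L, 4, S)
        counts[cbind(st_idx[idx[1], ], seq_len(S))] <- 1L
        flush <- function(a, b) {
            gidx <- idx[a:b]
            cons <- consensus_of(counts)
            regions[[length(regions) + 1]] <<- data.frame(
                chrom = ch, first_probe = gidx[1],
                last_probe = gidx[length(gidx)], n_probes = length(gidx),
                stringsAsFactors = FALSE)
            rcalls[[length(rcalls) + 1]] <<- cons
            pp <- calls$post[gidx, , , drop = FALSE]
            rpost[[length(rpost) + 1]] <<-
                apply(pp, c(2, 3), mean)
        }
        for (j in seq_along(idx)[-1]) {
            cand <- counts
            cand[cbind(st_idx[idx[j], ], seq_len(S))] <-
                cand[cbind(st_idx[idx[j], ], seq_len(S))] + 1L
            cons <- consensus_of(cand)
            member <- calls$states[idx[start:j], , drop = FALSE]
            dis <- rowMeans(member != rep(cons, each = j - start + 1))
            if (max(dis) <= averror) {
                counts <- cand
            } else {
                flush(start, j - 1L)
                start <- j
                counts <- matrix(0L, 4, S)
                counts[cbind(st_idx[idx[j], ], seq_len(S))] <- 1L
            }
        }
        flush(start, length(idx))
    }
    regions <- do.call(rbind, regions)
    rownames(regions) <- NULL
    cm <- do.call(rbind, rcalls)
    dimnames(cm) <- list(NULL, calls$samples)
    pa <- array(0, dim = c(nrow(regions), S, 4),
                dimnames = list(NULL, calls$samples, STATE_NAMES))
    for (i in seq_len(nrow(regions))) pa[i, , ] <- rpost[[i]]
    freq <- data.frame(gain_pct = 100 * rowMeans(cm >= 1),
                       loss_pct = 100 * rowMeans(cm == -1))
    structure(list(regions = regions, calls = cm, post = pa, freq = freq,
                   samples = calls$samples, averror = averror),
              class = "cna_regions")
}

#' @export
print.cna_regions <- function(x, ...) {
    cat("cna_regions: ", nrow(x$regions), " regions x ", length(x$samples),
        " samples (averror ", x$averror, ")\n", sep = "")
    invisible(x)
}

#' Gain and loss frequencies, overall or per group
#'
#' Gains count states >= +1 (amplifications count as gains); losses count
#' state -1. Frequencies are percentages of samples.
#'
#' @param x a `cna_regions` or `cna_calls` object, or a state matrix.
#' @param labels optional grouping factor over samples.
#' @return data.frame with gain/loss percentage columns (per group when
#'   `labels` is given).
#' @export
aberration_frequencies <- function(x, labels = NULL) {
    m <- if (inherits(x, "cna_regions")) x$calls
         else if (inherits(x, "cna_calls")) x$states
         else as.matrix(x)
    if (is.null(labels)) {
        return(data.frame(gain_pct = 100 * rowMeans(m >= 1),
                          loss_pct = 100 * rowMeans(m == -1)))
    }
    labels <- as.factor(labels)
    if (length(labels) != ncol(m))
        stop("labels must match the number of samples")
    if (any(table(labels) == 0)) stop("empty group in labels")
    out <- data.frame(row.names = seq_len(nrow(m)))
    for (g in levels(labels)) {
        sub <- m[, labels == g, drop = FALSE]
        out[[paste0("gain_pct_", g)]] <- 100 * rowMeans(sub >= 1)
        out[[paste0("loss_pct_", g)]] <- 100 * rowMeans(sub == -1)
    }
    out
}
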
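# internal: log-rank chi-square for many binary group columns at once.
# times/events define one survival dataset; Z is a samples x columns binary
# matrix. Uses the standard O-E statistic with hypergeometric variance at
# each distinct event time (equivalent to the Cox score test with Breslow
# tie handling at beta = 0).
logrank_chisq_mat <- function(times, events, Z) {
    Z <- as.matrix(Z)
    S <- length(times)
    o <- order(times)
    t_s <- times[o]; e_s <- as.logical(events)[o]
    Zs <- Z[o, , drop = FALSE]
    # suffix sums: risk-set totals for each start index
    suf <- apply(Zs[S:1, , drop = FALSE], 2, cumsum)[S:1, , drop = FALSE]
    ut <- unique(t_s[e_s])
    U <- numeric(ncol(Z)); V <- numeric(ncol(Z))
    for (t in ut) {
        first <- match(t, t_s)          # first index in risk set
        at <- which(t_s == t & e_s)     # events at this time
        d <- length(at)
        n_t <- S - first + 1
        z_risk <- suf[first, ]
        z_ev <- colSums(Zs[at, , drop = FALSE])
        U <- U + z_ev - d * z_risk / n_t
        if (n_t > 1)
            V <- V + d * (n_t - d) / (n_t - 1) *
                (z_risk / n_t) * (1 - z_risk / n_t)
    }
    ifelse(V > 0, U^2 / V, 0)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive follow-up times.
#' @param events logical event indicators.
#' @return data.frame (time, n_risk, n_event, n_censor, survival) at the
#'   distinct observed times.
#' @export
km_estimate <- function(times, events) {
    if (!length(times)) stop("empty input")
    if (any(times <= 0)) stop("times must be positive")
    fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-sided log-rank test for a binary group
#'
#' Standard O-E log-rank with hypergeometric variance at each event time
#' (df = 1); identical to the Cox partial-likelihood score test at beta = 0
#' under Breslow tie handling.
#'
#' @param times positive follow-up times.
#' @param events logical event indicators.
#' @param group binary/logical group membership.
#' @return list(chisq, p).
#' @export
logrank_test <- function(times, events, group) {
    g <- as.numeric(as.factor(group)) - 1
    if (length(unique(g)) != 2) stop("need two non-empty groups")
    if (!any(events)) return(list(chisq = 0, p = 1))
    chisq <- logrank_chisq_mat(times, events, matrix(g, ncol = 1))
    list(chisq = unname(chisq), p = pchisq(chisq, 1, lower.tail = FALSE))
}

#' Permutation log-rank screening of CNA regions against DFS
#'
#' Dichotomizes each region per aberration type (carrier vs non-carrier),
#' computes the log-rank chi-square, and obtains permutation p-values by
#' shuffling the (time, event) tuples against the call columns; the
#' permutation FDR is the averaged-exceedance estimator also used by
#' [compare_groups()], over the pooled gain/loss family with shared
#' permutations. Regions below `min_freq` carrier frequency, or aberrant in
#' every sample, are excluded.
#'
#' @param region_set a `cna_regions` object.
#' @param clinical a [clinical_table()] aligned to the cohort samples.
#' @param n_perm permutations.
#' @param min_freq minimum carrier frequency.
#' @param fdr_cut significance threshold on the permutation FDR.
#' @param seed optional RNG seed.
#' @param types aberration types to test.
#' @return data.frame (region, chrom, type, chisq, p, fdr, significant).
#' @export
logrank_permutation_regions <- function(region_set, clinical,
                                        n_perm = 10000, min_freq = 0.10,
                                        fdr_cut = 0.2, seed = NULL,
                                        types = c("gain", "loss")) {
    stopifnot(inherits(region_set, "cna_regions"))
    check_samples(clinical$sample_id, region_set$samples, "region set")
    cl <- clinical[match(region_set$samples, clinical$sample_id), ]
    if (!is.null(seed)) set.seed(seed)
    S <- length(region_set$samples)
    Zs <- list(); info <- list()
    for (type in types) {
        carr <- if (type == "gain") t(region_set$calls >= 1)
                else t(region_set$calls == -1)
        freq <- colMeans(carr)
        keep <- which(freq >= min_freq & freq < 1)
        if (!length(keep)) next
        Zs[[type]] <- carr[, keep, drop = FALSE] * 1
        info[[type]] <- data.frame(region = keep, type = type,
                                   stringsAsFactors = FALSE)
    }
    if (!length(Zs)) return(NULL)
    Z <- do.call(cbind, Zs)
    info <- do.call(rbind, info)
    obs <- logrank_chisq_mat(cl$dfs_time, cl$event, Z)
    R <- length(obs)
    exceed <- numeric(R); fdr_num <- numeric(R)
    for (b in seq_len(n_perm)) {
        st <- logrank_chisq_mat(cl$dfs_time, cl$event,
                                Z[sample.int(S), , drop = FALSE])
        exceed <- exceed + (st >= obs - 1e-9)
        fdr_num <- fdr_num + (R - findInterval(obs - 1e-9, sort(st)))
    }
    p <- (1 + exceed) / (1 + n_perm)
    rk <- vapply(obs, function(t) sum(obs >= t - 1e-9), 0)
    fdr <- pmin((fdr_num / n_perm) / rk, 1)
    res <- data.frame(
        region = info$region,
        chrom = region_set$regions$chrom[info$region],
        type = info$type, chisq = obs, p = p, fdr = fdr,
        significant = fdr < fdr_cut, stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Cox proportional-hazards ratio for a binary covariate
#'
#' Partial-likelihood fit with Breslow tie handling; the hazard ratio is
#' exp(coefficient) with a 95% Wald confidence interval. Monotone
#' partial likelihood (complete separation of events) is flagged and the
#' hazard ratio reported as infinite (or zero).
#'
#' @param times positive follow-up times.
#' @param events logical event indicators.
#' @param covariate binary/logical covariate.
#' @param ties tie handling, "breslow" (default) or "efron".
#' @return list(hr, ci_lower, ci_upper, p, coef, se, infinite).
#' @export
cox_hr <- function(times, events, covariate, ties = c("breslow", "efron")) {
    ties <- match.arg(ties)
    z <- as.numeric(as.factor(covariate)) - 1
    if (length(unique(z)) != 2) stop("both covariate levels must be present")
    if (sum(events) < 1) stop("need at least one event")
    fit <- withCallingHandlers(
        survival::coxph(survival::Surv(times, as.numeric(events)) ~ z,
                        ties = ties, control =
                            survival::coxph.control(eps = 1e-10,
                                                    iter.max = 50)),
        warning = function(w) invokeRestart("muffleWarning"))
    beta <- unname(coef(fit))
    se <- sqrt(unname(fit$var[1, 1]))
    infinite <- !is.finite(beta) || abs(beta) > 15 || se > 1e3
    list(hr = exp(beta),
         ci_lower = exp(beta - 1.96 * se),
         ci_upper = exp(beta + 1.96 * se),
         p = 2 * stats::pnorm(-abs(beta / se)),
         coef = beta, se = se, infinite = infinite)
}
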
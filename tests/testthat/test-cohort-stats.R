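test_that("the 2x2 chi-square matches the hand formula and chisq.test", {
    # 48/1 loss carriers among 49 relapsed vs 48/17 among 65 relapse-free
    carrier <- c(rep(1, 48), 0, rep(1, 48), rep(0, 17))
    group <- c(rep(1, 49), rep(0, 65))
    res <- chisq_permutation(carrier, group, n_perm = 2000, seed = 1)
    hand <- 114 * (48 * 17 - 1 * 48)^2 / (49 * 65 * 96 * 18)
    expect_equal(res$stat, hand, tolerance = 1e-12)
    ct <- suppressWarnings(chisq.test(table(group, carrier),
                                      correct = FALSE))
    expect_equal(res$stat, unname(ct$statistic), tolerance = 1e-12)
    expect_lt(res$p_asymptotic, 0.001)
    expect_lt(res$p_perm, 0.01)
})

make_region_set <- function(calls) {
    R <- nrow(calls); S <- ncol(calls)
    structure(list(regions = data.frame(chrom = "1",
                                        first_probe = seq_len(R),
                                        last_probe = seq_len(R),
                                        n_probes = 1L),
                   calls = calls, post = array(0.25, c(R, S, 4)),
                   freq = NULL, samples = colnames(calls),
                   averror = 0.015),
              class = "cna_regions")
}

test_that("identical call distributions give null association results", {
    calls <- matrix(rep(c(-1L, -1L, 0L, 0L), 8), nrow = 2, ncol = 16,
                    byrow = TRUE)
    colnames(calls) <- sprintf("s%02d", 1:16)
    rs <- make_region_set(calls)
    labels <- factor(rep(c("a", "b"), 8))  # balanced across carriers
    res <- compare_groups(rs, labels, n_perm = 500, seed = 3)
    expect_true(all(res$p > 0.5))
    expect_true(all(res$fdr > 0.5))
})

test_that("permutation p-values are seed-reproducible and label-symmetric", {
    set.seed(4)
    calls <- matrix(sample(c(-1L, 0L), 20 * 30, replace = TRUE), 20, 30)
    colnames(calls) <- sprintf("s%02d", 1:30)
    rs <- make_region_set(calls)
    labels <- factor(rep(c("x", "y"), 15))
    r1 <- compare_groups(rs, labels, n_perm = 300, seed = 11)
    r2 <- compare_groups(rs, labels, n_perm = 300, seed = 11)
    expect_identical(r1, r2)
    flipped <- factor(labels, levels = rev(levels(labels)))
    r3 <- compare_groups(rs, flipped, n_perm = 300, seed = 11)
    expect_equal(r1$stat, r3$stat, tolerance = 1e-12)
    # region order invariance of statistics
    o <- sample(nrow(calls))
    r4 <- compare_groups(make_region_set(calls[o, ]), labels,
                         n_perm = 300, seed = 11)
    expect_equal(sort(r4$stat), sort(r1$stat), tolerance = 1e-12)
})

test_that("low-frequency regions are excluded before testing", {
    calls <- rbind(matrix(0L, 1, 40), matrix(-1L, 1, 40))
    calls[1, 1:2] <- -1L  # 5% carriers: below the 10% filter
    calls[2, 1:20] <- 0L  # 50% carriers
    colnames(calls) <- sprintf("s%02d", 1:40)
    rs <- make_region_set(calls)
    res <- compare_groups(rs, factor(rep(c("a", "b"), 20)), n_perm = 200,
                          seed = 5)
    expect_true(all(res$region == 2))
})

test_that("an all-neutral sample scores (0, 0)", {
    panel <- make_multi_panel(100, c("1", "2"))
    states <- matrix(0L, 200, 2, dimnames = list(panel$probe_id,
                                                 c("flat", "tail_loss")))
    states[121:200, 2] <- -1L  # loss running to the end of chromosome 2
    calls <- structure(list(panel = panel, samples = colnames(states),
                            states = states,
                            post = array(0.25, c(200, 2, 4))),
                       class = "cna_calls")
    segs <- rbind(
        data.frame(sample = "flat", chrom = c("1", "2"),
                   start_probe = c(1L, 101L), end_probe = c(100L, 200L),
                   num_probes = 100L, seg_mean = 0),
        data.frame(sample = "tail_loss", chrom = c("1", "2", "2"),
                   start_probe = c(1L, 101L, 121L),
                   end_probe = c(100L, 120L, 200L),
                   num_probes = c(100L, 20L, 80L),
                   seg_mean = c(0, 0, -0.6)))
    sc <- structure(list(panel = panel, samples = colnames(states),
                         segments = segs), class = "seg_cohort")
    sco <- instability_scores(calls, detect_breakpoints(sc))
    expect_equal(sco$cna_score, c(0, 80))
    expect_equal(sco$bp_score, c(0, 1))
})

test_that("a mid-chromosome aberrant segment contributes two breakpoints", {
    panel <- make_panel(300)
    segs <- data.frame(sample = "s", chrom = "1",
                       start_probe = c(1L, 101L, 201L),
                       end_probe = c(100L, 200L, 300L),
                       num_probes = 100L, seg_mean = c(0, -0.6, 0))
    sc <- structure(list(panel = panel, samples = "s", segments = segs),
                    class = "seg_cohort")
    states <- matrix(0L, 300, 1, dimnames = list(panel$probe_id, "s"))
    states[101:200, 1] <- -1L
    calls <- structure(list(panel = panel, samples = "s", states = states,
                            post = array(0.25, c(300, 1, 4))),
                       class = "cna_calls")
    sco <- instability_scores(calls, detect_breakpoints(sc))
    expect_equal(sco$cna_score, 100)
    expect_equal(sco$bp_score, 2)
})

test_that("instability scores separate mutants given generator coupling", {
    # mutation-coupled instability: mutants receive 3 extra aberrant
    # segments on top of a constant background
    pow <- 0; n_rep <- 5
    for (r in seq_len(n_rep)) {
        cfg <- sim_config(
            n_samples = 60, n_chromosomes = 2, n_probes_per_chrom = 300,
            archetype_regions = data.frame(
                chrom = "1", start_probe = 1L, end_probe = 150L,
                state = "loss", freq = 1.0),
            relapse_region = NULL,
            mutation_models = data.frame(gene = "APC", freq = 0.45,
                                         extra_segments = 3L),
            seed = 700 + r)
        sim <- simulate_cohort(cfg)
        seg <- segment_cohort(sim$cohort, n_perm = 200)
        calls <- call_states(seg, fit_call_mixture(seg))
        sco <- instability_scores(calls, detect_breakpoints(seg))
        mut <- sim$mutations[, "APC"] == 1
        mw <- mann_whitney_scores(sco$cna_score,
                                  factor(ifelse(mut, "mut", "wt")))
        med_diff <- median(sco$cna_score[mut]) -
            median(sco$cna_score[!mut])
        if (mw$p < 0.05 && med_diff > 0) pow <- pow + 1
    }
    expect_gte(pow / n_rep, 0.8)
})

test_that("Mann-Whitney matches exact enumeration for small groups", {
    # enumeration oracle over all C(6,3) = 20 assignments
    vals <- c(1, 2, 3, 4, 5, 6)
    obs_u <- function(ix) {
        x <- vals[ix]; y <- vals[-ix]
        sum(outer(x, y, ">")) # U for group 1
    }
    combos <- combn(6, 3)
    us <- apply(combos, 2, obs_u)
    u_obs <- obs_u(1:3)
    # two-sided exact p: arrangements at least as extreme as observed
    p_exact <- mean(pmin(us, 9 - us) <= min(u_obs, 9 - u_obs))
    res <- mann_whitney_scores(vals, factor(rep(c("a", "b"), each = 3)))
    expect_equal(res$U, 0)
    expect_equal(res$p, p_exact)
    expect_equal(res$p, 0.1)
    # symmetry and degenerate cases
    res_sw <- mann_whitney_scores(vals, factor(rep(c("b", "a"), each = 3)))
    expect_equal(res_sw$p, res$p)
    expect_equal(mann_whitney_scores(rep(1, 6),
                                     rep(c("a", "b"), 3))$p, 1)
})

test_that("Fisher exact matches full hypergeometric enumeration", {
    tab <- matrix(c(10L, 0L, 0L, 10L), 2, 2)
    # enumeration oracle: P(table) over all tables with these margins
    probs <- dhyper(0:10, 10, 10, 10)
    p_oracle <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
    res <- fisher_exact(tab)
    expect_equal(res$p, p_oracle, tolerance = 1e-12)
    expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
    expect_equal(fisher_exact(matrix(c(5L, 5L, 5L, 5L), 2, 2))$p, 1)
    # transposition invariance
    tab2 <- matrix(c(7L, 3L, 2L, 9L), 2, 2)
    expect_equal(fisher_exact(tab2)$p, fisher_exact(t(tab2))$p)
    # zero margin flagged
    zm <- fisher_exact(matrix(c(0L, 0L, 5L, 5L), 2, 2, byrow = TRUE))
    expect_true(zm$flagged)
    expect_equal(zm$p, 1)
})

test_that("posterior clustering is a metric and recovers planted archetypes", {
    # duplicated sample: zero dissimilarity, merged first
    post <- array(runif(10 * 3 * 4), c(10, 3, 4))
    post <- post / rep(apply(post, c(1, 2), sum), 4)
    post[, 2, ] <- post[, 1, ]
    rs <- structure(list(regions = data.frame(chrom = "1",
                                              first_probe = 1:10,
                                              last_probe = 1:10,
                                              n_probes = 1L),
                         calls = matrix(0L, 10, 3,
                                        dimnames = list(NULL,
                                                        c("a", "b", "c"))),
                         post = post, samples = c("a", "b", "c")),
                    class = "cna_regions")
    cl <- cluster_samples(rs)
    dm <- as.matrix(cl$dist)
    expect_equal(dm["a", "b"], 0)
    expect_identical(sort(cl$hclust$merge[1, ]), c(-2L, -1L))
    # metric properties on random posteriors
    expect_equal(dm, t(dm))
    for (i in 1:3) for (j in 1:3) for (k in 1:3)
        expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
    expect_error(cluster_samples(structure(list(samples = "x"),
                                           class = "cna_regions")),
                 ">= 2")
})

test_that("two planted CNA archetypes separate into two clusters", {
    set.seed(72)
    # each archetype spans half a chromosome (a quarter of the genome),
    # keeping the neutral state dominant for mode normalization
    archetypes <- data.frame(
        chrom = c("1", "2"), start_probe = 1L, end_probe = 100L,
        state = c("loss", "gain"), freq = 0)
    # build two sample groups carrying opposite archetypes by merging two sims
    cfgA <- sim_config(n_samples = 10, n_chromosomes = 2,
                       n_probes_per_chrom = 200, relapse_region = NULL,
                       archetype_regions = transform(archetypes,
                                                     freq = c(1, 0)),
                       mutation_models = data.frame(gene = "APC", freq = 0,
                                                    extra_segments = 0L),
                       seed = 73)
    cfgB <- cfgA; cfgB$archetype_regions$freq <- c(0, 1); cfgB$seed <- 74L
    simA <- simulate_cohort(cfgA); simB <- simulate_cohort(cfgB)
    ratios <- cbind(simA$cohort$ratios, simB$cohort$ratios)
    colnames(ratios) <- sprintf("s%02d", 1:20)
    co <- cna_cohort(simA$cohort$panel, ratios)
    seg <- segment_cohort(co, n_perm = 200)
    calls <- call_states(seg, fit_call_mixture(seg))
    rs <- reduce_regions(calls)
    cl <- cluster_samples(rs, k = 2)
    truth <- rep(1:2, each = 10)
    # Rand index
    pairs <- combn(20, 2)
    same_t <- truth[pairs[1, ]] == truth[pairs[2, ]]
    same_c <- cl$clusters[pairs[1, ]] == cl$clusters[pairs[2, ]]
    rand <- mean(same_t == same_c)
    expect_gt(rand, 0.9)
})

test_that("null permutation FDR stays controlled at the nominal level", {
    set.seed(75)
    vr <- c()
    for (rep in 1:30) {
        S <- 40; R <- 120
        calls <- matrix(0L, R, S, dimnames = list(NULL,
                                                  sprintf("s%02d", 1:S)))
        for (i in seq_len(R)) {
            f <- runif(1, 0.15, 0.6)
            calls[i, sample.int(S, round(f * S))] <- sample(c(-1L, 1L), 1)
        }
        rs <- make_region_set(calls)
        res <- compare_groups(rs, factor(rep(c("a", "b"), S / 2)),
                              n_perm = 500, seed = rep * 13)
        vr <- c(vr, as.numeric(any(res$fdr < 0.2)))
    }
    se <- sd(vr) / sqrt(length(vr))
    expect_lte(mean(vr), 0.2 + 2 * max(se, 0.05))
})
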
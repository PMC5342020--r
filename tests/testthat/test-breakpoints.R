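# minimal seg_cohort built by hand
manual_seg <- function(panel, samples, seg_list) {
    segs <- do.call(rbind, lapply(names(seg_list), function(s) {
        cbind(sample = s, seg_list[[s]], stringsAsFactors = FALSE)
    }))
    structure(list(panel = panel, samples = samples, segments = segs),
              class = "seg_cohort")
}

test_that("breakpoints sit at the first probe of non-initial segments", {
    panel <- make_panel(100)
    # one genome-wide segment: no breakpoints
    sc <- manual_seg(panel, "s1", list(s1 = data.frame(
        chrom = "1", start_probe = 1L, end_probe = 100L,
        num_probes = 100L, seg_mean = 0)))
    bps <- detect_breakpoints(sc)
    expect_identical(sum(bps$flags), 0L)
    expect_identical(bps$rate, 0)
    # split at probe 51: single flag there
    sc2 <- manual_seg(panel, "s1", list(s1 = data.frame(
        chrom = "1", start_probe = c(1L, 51L), end_probe = c(50L, 100L),
        num_probes = 50L, seg_mean = c(0, 1))))
    bps2 <- detect_breakpoints(sc2)
    expect_identical(unname(which(bps2$flags[, 1])), 51L)
    expect_equal(bps2$rate, 1 / 100)
})

test_that("enrichment probes must be removed before breakpoint analysis", {
    panel <- make_panel(50, enrichment = c(rep(FALSE, 49), TRUE))
    sc <- manual_seg(panel, "s1", list(s1 = data.frame(
        chrom = "1", start_probe = 1L, end_probe = 50L,
        num_probes = 50L, seg_mean = 0)))
    expect_error(detect_breakpoints(sc), "enrichment")
})

test_that("detected breakpoints equal generator truth when segmentation is exact", {
    sim <- small_sim(n_samples = 12, seed = 61, noise_sd = 0.02)
    seg <- segment_cohort(sim$cohort, n_perm = 300)
    bps <- detect_breakpoints(seg)
    expect_identical(sort(detected_bp_keys(bps)), sort(truth_bp_keys(sim)))
    # per-sample flag count equals segments minus chromosomes
    segs_per_sample <- table(seg$segments$sample)
    n_chrom <- length(unique(seg$panel$chrom))
    expect_equal(unname(bps$bp_score[names(segs_per_sample)]),
                 as.vector(segs_per_sample) - n_chrom)
    # column sums match probe counts
    expect_identical(sum(bps$count), sum(bps$bp_score))
})

test_that("binomial tail p-values match a brute-force summation oracle", {
    brute <- function(k, n, r) sum(dbinom(k:n, n, r))
    panel <- make_panel(30)
    flags <- matrix(FALSE, 30, 100,
                    dimnames = list(panel$probe_id, sprintf("s%03d", 1:100)))
    flags[5, 1:5] <- TRUE   # probe 5 hit in 5 samples
    flags[9, 1] <- TRUE
    bset <- structure(list(panel = panel, samples = colnames(flags),
                           flags = flags, count = rowSums(flags),
                           rate = sum(flags) / (30 * 100),
                           bp_score = colSums(flags)),
                      class = "breakpoint_set")
    tested <- test_breakpoint_locations(bset)
    r <- bset$rate
    expect_equal(tested$p[5], brute(5, 100, r), tolerance = 1e-12)
    expect_equal(tested$p[9], brute(1, 100, r), tolerance = 1e-12)
    expect_equal(tested$p[1], 1)  # count 0
    expect_equal(tested$fdr,
                 p.adjust(tested$p, "BH"), tolerance = 1e-12)
})

test_that("no breakpoints cohort-wide gives all-ones p-values", {
    panel <- make_panel(10)
    flags <- matrix(FALSE, 10, 5,
                    dimnames = list(panel$probe_id, paste0("s", 1:5)))
    bset <- structure(list(panel = panel, samples = colnames(flags),
                           flags = flags, count = rowSums(flags),
                           rate = 0, bp_score = colSums(flags)),
                      class = "breakpoint_set")
    expect_true(all(test_breakpoint_locations(bset)$p == 1))
})

test_that("uniform random breakage yields ~no significant probes", {
    set.seed(62)
    panel <- make_panel(400)
    n_sig <- 0
    for (r in 1:20) {
        flags <- matrix(runif(400 * 60) < 0.005, 400, 60,
                        dimnames = list(panel$probe_id,
                                        sprintf("s%02d", 1:60)))
        bset <- structure(list(panel = panel, samples = colnames(flags),
                               flags = flags, count = rowSums(flags),
                               rate = sum(flags) / (400 * 60),
                               bp_score = colSums(flags)),
                          class = "breakpoint_set")
        n_sig <- n_sig + sum(test_breakpoint_locations(bset)$significant)
    }
    expect_lt(n_sig / 20, 0.5)
})

test_that("genes map to probes and pool on identical probe sets", {
    panel <- make_panel(100)   # positions 1000, 2000, ..., 100000
    flags <- matrix(FALSE, 100, 10,
                    dimnames = list(panel$probe_id, sprintf("s%02d", 1:10)))
    flags[51, 1:3] <- TRUE
    bset <- structure(list(panel = panel, samples = colnames(flags),
                           flags = flags, count = rowSums(flags),
                           rate = sum(flags) / 1000,
                           bp_score = colSums(flags)),
                      class = "breakpoint_set")
    genes <- data.frame(
        gene_name = c("HIT", "TWIN", "EMPTYSPAN", "FARAWAY"),
        chrom = "1",
        start = c(50500L, 50900L, 55001L, 90100L),
        end = c(51500L, 51200L, 55999L, 95000L))
    expect_message(gbt <- map_genes(bset, genes), "no associated probes")
    # HIT and TWIN both cover exactly probe 51: pooled
    pooled <- gbt$table[gbt$table$n_members == 2, ]
    expect_identical(nrow(pooled), 1L)
    expect_identical(pooled$pool_name, "HIT*")
    expect_identical(pooled$member_genes, "HIT;TWIN")
    expect_equal(pooled$frequency, 0.3)
    # every mapped gene is in exactly one pool
    members <- unlist(strsplit(gbt$table$member_genes, ";"))
    expect_identical(sort(members), sort(c("HIT", "TWIN", "FARAWAY")))
    # FARAWAY has no breakpoints: frequency 0, p = 1, never significant
    far <- gbt$table[gbt$table$pool_name == "FARAWAY", ]
    expect_equal(far$frequency, 0)
    tested <- test_recurrent_genes(gbt)
    expect_equal(tested$table$p[tested$table$pool_name == "FARAWAY"], 1)
    expect_false(tested$table$significant[
        tested$table$pool_name == "FARAWAY"])
})

test_that("recurrent-gene p-values match the binomial oracle", {
    # n = 100 samples, m_g = 5 probes, r = 0.002, k = 4 affected
    r <- 0.002; n <- 100; m_g <- 5; k <- 4
    q <- 1 - (1 - r)^m_g
    brute <- sum(dbinom(k:n, n, q))
    panel <- make_panel(50)
    flags <- matrix(FALSE, 50, n,
                    dimnames = list(panel$probe_id, sprintf("s%03d", 1:n)))
    flags[10, 1:k] <- TRUE
    bset <- structure(list(panel = panel, samples = colnames(flags),
                           flags = flags, count = rowSums(flags),
                           rate = r, bp_score = colSums(flags)),
                      class = "breakpoint_set")
    genes <- data.frame(gene_name = "G", chrom = "1",
                        start = 6000L, end = 10999L)  # probes 6..10
    gbt <- test_recurrent_genes(map_genes(bset, genes))
    expect_identical(gbt$table$n_probes, 5L)
    expect_equal(gbt$table$p, brute, tolerance = 1e-12)
})

test_that("the Gilbert correction never flags fewer genes than plain BH", {
    set.seed(63)
    for (rep in 1:20) {
        n_gene <- 50; n_samp <- 80
        r <- runif(1, 0.001, 0.01)
        m <- sample(1:10, n_gene, replace = TRUE)
        q <- 1 - (1 - r)^m
        k <- rbinom(n_gene, n_samp, q * sample(c(1, 1, 5), n_gene,
                                               replace = TRUE))
        k <- pmin(k, n_samp)
        p <- pbinom(k - 1, n_samp, q, lower.tail = FALSE)
        plain_bh <- sum(p.adjust(p, "BH") < 0.1)
        minp <- q^n_samp
        testable <- minp <= 0.1
        gilbert <- numeric(n_gene) + 1
        if (any(testable))
            gilbert[testable] <- p.adjust(p[testable], "BH")
        expect_gte(sum(gilbert < 0.1), plain_bh)
    }
})

test_that("a fragile site hit in 35% of samples is recovered cohort-wide", {
    sim <- simulate_cohort(sim_config(seed = 64))
    seg <- segment_cohort(sim$cohort, n_perm = 300)
    bps <- detect_breakpoints(seg)
    # the 8p-like archetype ends mid-chromosome 4 at 35% frequency;
    # a gene spanning the boundary probe emulates a fragile-site gene
    frac30 <- as.integer(round(0.3 * 400))
    b <- which(sim$cohort$panel$chrom == "4")[frac30 + 1L]
    pos <- sim$cohort$panel$pos[b]
    genes <- data.frame(gene_name = c("FRAGILE", "CONTROL"),
                        chrom = c("4", "2"),
                        start = c(pos - 20000L, 1000L),
                        end = c(pos + 20000L, 50000L))
    gbt <- test_recurrent_genes(map_genes(bps, genes), fdr_cut = 0.1)
    frag <- gbt$table[gbt$table$pool_name == "FRAGILE", ]
    expect_true(frag$significant)
    expect_gt(frag$frequency, 0.25)
})
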
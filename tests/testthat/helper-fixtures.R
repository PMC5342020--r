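# shared fixtures, built in code

make_panel <- function(n = 100, chrom = "1", spacing = 1000L,
                       enrichment = logical(n)) {
    probe_panel(data.frame(
        probe_id = sprintf("P%s_%04d", chrom, seq_len(n)),
        chrom = chrom, pos = spacing * seq_len(n),
        is_enrichment = enrichment))
}

make_multi_panel <- function(n_per = 100, chroms = c("1", "2")) {
    do.call(rbind, lapply(chroms, function(ch)
        data.frame(probe_id = sprintf("P%s_%04d", ch, seq_len(n_per)),
                   chrom = ch, pos = 1000L * seq_len(n_per),
                   is_enrichment = FALSE))) |> probe_panel()
}

# tiny deterministic cohort: one chromosome, a loss block in half the samples
make_toy_cohort <- function(n_probes = 60, n_samples = 6, seed = 99) {
    set.seed(seed)
    panel <- make_panel(n_probes)
    m <- matrix(rnorm(n_probes * n_samples, 0, 0.1), n_probes, n_samples,
                dimnames = list(NULL, sprintf("S%02d", seq_len(n_samples))))
    carriers <- seq_len(n_samples) <= n_samples / 2
    m[21:40, carriers] <- m[21:40, carriers] - 0.6
    cna_cohort(panel, m)
}

# small simulated cohort used by several modules
small_sim <- function(n_samples = 20, seed = 123, ...) {
    simulate_cohort(sim_config(n_samples = n_samples, seed = seed, ...))
}

truth_state_matrix <- function(sim) {
    m <- matrix(match(sim$truth$state_mat,
                      c("loss", "neutral", "gain", "amplification")) - 2L,
                nrow(sim$truth$state_mat),
                dimnames = dimnames(sim$truth$state_mat))
    m
}

# breakpoint (sample, probe) keys for recall/precision comparisons
truth_bp_keys <- function(sim) {
    paste(rep(names(sim$truth$breakpoints),
              lengths(sim$truth$breakpoints)),
          unlist(sim$truth$breakpoints))
}

detected_bp_keys <- function(bps) {
    hit <- which(bps$flags, arr.ind = TRUE)
    paste(colnames(bps$flags)[hit[, 2]], hit[, 1])
}
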
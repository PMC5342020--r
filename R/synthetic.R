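#' Simulation configuration for a synthetic array-CGH cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' emulate a stage II/III microsatellite-stable colon-cancer series: two
#' equal-sized stage strata with relapse fractions 22/57 and 27/57, a
#' scaled-down genome of 5 chromosomes x 400 evenly spaced probes, segmental
#' archetype aberrations at colorectal-cancer-typical population frequencies
#' (whole- and arm-level losses and gains plus one focal amplification), a
#' relapse-enriched loss region (present in 98% of relapsed versus 74.5% of
#' relapse-free tumors), gene mutation frequencies matching published colon
#' cancer rates (APC 45%, near-exclusive KRAS/NRAS/BRAF), mutation-coupled
#' chromosomal instability (TP53 and APC mutants receive extra random
#' aberrant segments), and Gaussian probe noise of SD 0.1 log2 units.
#'
#' Archetype regions are given in probe coordinates `(chrom, start_probe,
#' end_probe, state, freq)`; defaults are derived from chromosome-length
#' fractions so they rescale with `n_probes_per_chrom`.
#'
#' @param n_samples cohort size; split across stages in proportion to
#'   `stage_design`.
#' @param n_chromosomes,n_probes_per_chrom genome size.
#' @param probe_spacing basepairs between adjacent probes.
#' @param noise_sd Gaussian probe noise SD in log2-ratio units (> 0).
#' @param wave_amplitude amplitude of a per-sample, per-chromosome sinusoidal
#'   wave artifact (0 disables).
#' @param wave_cycles sinusoid cycles per chromosome.
#' @param state_offsets named log2-ratio offsets for the four copy-number
#'   states.
#' @param archetype_regions data.frame of population-level aberrations
#'   (columns chrom, start_probe, end_probe, state, freq); regions on one
#'   chromosome must not overlap.
#' @param relapse_region list with `chrom`, `start_probe`, `end_probe`,
#'   `state`, `penetrance_relapse`, `penetrance_nonrelapse` — a region whose
#'   carrier probability depends on relapse status. `"auto"` (default)
#'   places the default region on chromosome 2; `NULL` disables.
#' @param stage_design named vector of target stage sizes (relative weights).
#' @param relapse_frac named per-stage relapse probabilities (deterministic
#'   counts: `round(frac * n_stage)` samples per stage relapse).
#' @param mutation_models data.frame (gene, freq, extra_segments): mutation
#'   frequency and the number of additional random CNA segments a mutated
#'   sample receives (chromosomal-instability coupling).
#' @param mapk_exclusive draw KRAS/NRAS/BRAF mutations mutually exclusively.
#' @param survival_model list: `relapse_hazard` (events/month for relapsed
#'   stage II samples), `hr_stage3` (hazard ratio of stage III vs II event
#'   times), `horizon` (months; event times truncated here), `censor_min`,
#'   `censor_max` (uniform censoring window for relapse-free samples).
#' @param enrichment_frac fraction of probes flagged as enrichment probes.
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 114,
                       n_chromosomes = 5,
                       n_probes_per_chrom = 400,
                       probe_spacing = 17000,
                       noise_sd = 0.1,
                       wave_amplitude = 0,
                       wave_cycles = 1.5,
                       state_offsets = c(loss = -0.6, neutral = 0,
                                         gain = 0.45, amplification = 1.2),
                       archetype_regions = NULL,
                       relapse_region = "auto",
                       stage_design = c(II = 57, III = 57),
                       relapse_frac = c(II = 22 / 57, III = 27 / 57),
                       mutation_models = NULL,
                       mapk_exclusive = TRUE,
                       survival_model = list(relapse_hazard = 0.03,
                                             hr_stage3 = 1,
                                             horizon = 91.3,
                                             censor_min = 28.5,
                                             censor_max = 91.3),
                       enrichment_frac = 0,
                       seed = 1L) {
    np <- n_probes_per_chrom
    frac <- function(f) max(1L, min(np, as.integer(round(f * np))))
    if (is.null(archetype_regions) && n_chromosomes >= 5) {
        archetype_regions <- data.frame(
            chrom = c("1", "1", "3", "4", "4", "5", "5"),
            start_probe = c(1L, frac(0.70), 1L, 1L, frac(0.50) + 1L,
                            frac(0.125), frac(0.75)),
            end_probe = c(frac(0.50), np, np, frac(0.30), np,
                          frac(0.375), frac(0.80)),
            state = c("loss", "gain", "gain", "loss", "gain", "loss",
                      "amplification"),
            freq = c(0.40, 0.30, 0.50, 0.35, 0.45, 0.35, 0.10),
            stringsAsFactors = FALSE)
    } else if (is.null(archetype_regions)) {
        archetype_regions <- data.frame(chrom = character(),
                                        start_probe = integer(),
                                        end_probe = integer(),
                                        state = character(),
                                        freq = numeric())
    }
    if (identical(relapse_region, "auto")) {
        relapse_region <- if (n_chromosomes < 2) NULL else list(chrom = "2",
                               start_probe = frac(0.375),
                               end_probe = frac(0.625),
                               state = "loss",
                               penetrance_relapse = 0.98,
                               penetrance_nonrelapse = 0.745)
    }
    if (is.null(mutation_models)) {
        mutation_models <- data.frame(
            gene = c("APC", "TP53", "KRAS", "PIK3CA", "FBXW7", "SMAD4",
                     "BRAF", "NRAS"),
            freq = c(0.45, 0.55, 0.35, 0.15, 0.10, 0.10, 0.08, 0.05),
            extra_segments = c(2L, 4L, 0L, 0L, 0L, 0L, 0L, 0L),
            stringsAsFactors = FALSE)
    }
    cfg <- structure(list(
        n_samples = as.integer(n_samples),
        n_chromosomes = as.integer(n_chromosomes),
        n_probes_per_chrom = as.integer(n_probes_per_chrom),
        probe_spacing = as.integer(probe_spacing),
        noise_sd = noise_sd, wave_amplitude = wave_amplitude,
        wave_cycles = wave_cycles, state_offsets = state_offsets,
        archetype_regions = archetype_regions,
        relapse_region = relapse_region,
        stage_design = stage_design, relapse_frac = relapse_frac,
        mutation_models = mutation_models, mapk_exclusive = mapk_exclusive,
        survival_model = survival_model,
        enrichment_frac = enrichment_frac, seed = as.integer(seed)),
        class = "sim_config")
    validate_sim_config(cfg)
    cfg
}

validate_sim_config <- function(cfg) {
    states <- c("loss", "neutral", "gain", "amplification")
    if (cfg$n_samples < 1) stop("n_samples must be >= 1")
    if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
    if (!all(states %in% names(cfg$state_offsets)))
        stop("state_offsets must name loss, neutral, gain, amplification")
    chroms <- as.character(seq_len(cfg$n_chromosomes))
    ar <- cfg$archetype_regions
    rr <- cfg$relapse_region
    all_regions <- ar[c("chrom", "start_probe", "end_probe")]
    if (!is.null(rr)) {
        if (rr$penetrance_relapse < 0 || rr$penetrance_relapse > 1 ||
            rr$penetrance_nonrelapse < 0 || rr$penetrance_nonrelapse > 1)
            stop("relapse-region penetrances must lie in [0, 1]")
        all_regions <- rbind(all_regions,
                             data.frame(chrom = rr$chrom,
                                        start_probe = rr$start_probe,
                                        end_probe = rr$end_probe))
    }
    if (nrow(all_regions)) {
        if (!all(all_regions$chrom %in% chroms))
            stop("archetype region on unknown chromosome")
        if (any(all_regions$start_probe < 1) ||
            any(all_regions$end_probe > cfg$n_probes_per_chrom) ||
            any(all_regions$start_probe > all_regions$end_probe))
            stop("archetype region bounds outside chromosome")
        for (ch in unique(all_regions$chrom)) {
            r <- all_regions[all_regions$chrom == ch, , drop = FALSE]
            r <- r[order(r$start_probe), , drop = FALSE]
            if (nrow(r) > 1 &&
                any(r$start_probe[-1] <= r$end_probe[-nrow(r)]))
                stop("overlapping archetype regions on chromosome ", ch)
        }
    }
    if (nrow(ar) && !all(ar$state %in% states))
        stop("unknown archetype state")
    if (nrow(ar) && (any(ar$freq < 0) || any(ar$freq > 1)))
        stop("archetype frequencies must lie in [0, 1]")
    sm <- cfg$survival_model
    if (sm$relapse_hazard <= 0 || sm$hr_stage3 <= 0)
        stop("survival hazards and hazard ratios must be > 0")
    mm <- cfg$mutation_models
    if (nrow(mm) && (any(mm$freq < 0) || any(mm$freq > 1)))
        stop("mutation frequencies must lie in [0, 1]")
    invisible(cfg)
}

# internal: per-sample x probe state matrix -> truth segments / breakpoints
states_to_truth <- function(state_mat, panel) {
    chroms <- unique(panel$chrom)
    segs <- vector("list", ncol(state_mat))
    bps <- vector("list", ncol(state_mat))
    for (s in seq_len(ncol(state_mat))) {
        seg_rows <- list()
        bp <- integer()
        for (ch in chroms) {
            idx <- which(panel$chrom == ch)
            r <- rle(state_mat[idx, s])
            last <- cumsum(r$lengths)
            first <- c(1L, head(last, -1) + 1L)
            seg_rows[[ch]] <- data.frame(
                sample = colnames(state_mat)[s], chrom = ch,
                start_probe = idx[first], end_probe = idx[last],
                state = r$values, stringsAsFactors = FALSE)
            if (length(first) > 1) bp <- c(bp, idx[first[-1]])
        }
        segs[[s]] <- do.call(rbind, seg_rows)
        bps[[s]] <- bp
    }
    list(segments = do.call(rbind, segs), breakpoints = bps)
}

#' Simulate a synthetic array-CGH cohort with ground truth
#'
#' Draws per-sample copy-number states (archetype aberrations, a
#' relapse-linked region, mutation-coupled random extra segments), converts
#' them to probe-level log2 ratios (state offset + optional sinusoidal wave +
#' Gaussian noise), and generates a matching clinical table (stage, relapse,
#' DFS time/event, adjuvant flag) and mutation matrix. The relapse label is
#' the DFS event: relapsed samples receive truncated-exponential event times,
#' relapse-free samples uniform censoring times.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` ([cna_cohort()]), `clinical`
#'   ([clinical_table()]), `mutations` (sample x gene binary matrix) and
#'   `truth` (true segments, per-sample breakpoint probe indices, labels).
#' @export
simulate_cohort <- function(config) {
    validate_sim_config(config)
    set.seed(config$seed)
    np <- config$n_probes_per_chrom
    chroms <- as.character(seq_len(config$n_chromosomes))
    n_probes <- np * config$n_chromosomes
    panel <- data.frame(
        probe_id = sprintf("P%s_%04d", rep(chroms, each = np),
                           rep(seq_len(np), config$n_chromosomes)),
        chrom = rep(chroms, each = np),
        pos = rep(config$probe_spacing * seq_len(np), config$n_chromosomes),
        is_enrichment = FALSE, stringsAsFactors = FALSE)
    if (config$enrichment_frac > 0) {
        k <- floor(config$enrichment_frac * n_probes)
        panel$is_enrichment[sample.int(n_probes, k)] <- TRUE
    }
    panel <- probe_panel(panel)

    n <- config$n_samples
    samples <- sprintf("S%03d", seq_len(n))
    w <- config$stage_design / sum(config$stage_design)
    n2 <- round(n * w[["II"]])
    stage <- c(rep("II", n2), rep("III", n - n2))
    relapse <- logical(n)
    for (st in c("II", "III")) {
        idx <- which(stage == st)
        k <- round(config$relapse_frac[[st]] * length(idx))
        if (k > 0) relapse[sample(idx, k)] <- TRUE
    }

    # per-sample probe states
    state_mat <- matrix("neutral", n_probes, n,
                        dimnames = list(panel$probe_id, samples))
    chrom_offset <- setNames((seq_along(chroms) - 1L) * np, chroms)
    apply_region <- function(mat, chrom, a, b, state, carriers) {
        idx <- chrom_offset[[chrom]] + (a:b)
        mat[idx, carriers] <- state
        mat
    }
    ar <- config$archetype_regions
    for (i in seq_len(nrow(ar))) {
        carriers <- runif(n) < ar$freq[i]
        state_mat <- apply_region(state_mat, ar$chrom[i], ar$start_probe[i],
                                  ar$end_probe[i], ar$state[i], carriers)
    }
    rr <- config$relapse_region
    relapse_carrier <- rep(NA, n)
    if (!is.null(rr)) {
        pen <- ifelse(relapse, rr$penetrance_relapse, rr$penetrance_nonrelapse)
        relapse_carrier <- runif(n) < pen
        state_mat <- apply_region(state_mat, rr$chrom, rr$start_probe,
                                  rr$end_probe, rr$state, relapse_carrier)
    }

    # mutations, with optional MAPK mutual exclusivity
    mm <- config$mutation_models
    mut <- matrix(0L, n, nrow(mm), dimnames = list(samples, mm$gene))
    mapk <- intersect(c("KRAS", "NRAS", "BRAF"), mm$gene)
    indep <- setdiff(mm$gene, if (config$mapk_exclusive) mapk else character())
    for (g in indep)
        mut[, g] <- as.integer(runif(n) < mm$freq[mm$gene == g])
    if (config$mapk_exclusive && length(mapk)) {
        f <- mm$freq[match(mapk, mm$gene)]
        if (sum(f) > 1) stop("MAPK frequencies sum to > 1 under exclusivity")
        pick <- apply(rmultinom(n, 1, c(f, 1 - sum(f))), 2, which.max)
        for (j in seq_along(mapk)) mut[pick == j, mapk[j]] <- 1L
    }

    # mutation-coupled instability: extra random aberrant segments
    extra_per_sample <- as.vector(mut %*% mm$extra_segments)
    for (s in which(extra_per_sample > 0)) {
        for (k in seq_len(extra_per_sample[s])) {
            ch <- sample(chroms, 1)
            len <- sample(20:min(80, np), 1)
            a <- sample.int(np - len + 1L, 1)
            st <- sample(c("loss", "gain"), 1)
            state_mat <- apply_region(state_mat, ch, a, a + len - 1L, st, s)
        }
    }

    truth_seg <- states_to_truth(state_mat, panel)

    # ratios = offset + optional wave + noise
    off <- config$state_offsets
    ratios <- matrix(off[state_mat], n_probes, n,
                     dimnames = list(panel$probe_id, samples))
    if (config$wave_amplitude > 0) {
        t_chr <- seq_len(np) / np
        for (s in seq_len(n)) for (ch in chroms) {
            idx <- chrom_offset[[ch]] + seq_len(np)
            phase <- runif(1, 0, 2 * pi)
            ratios[idx, s] <- ratios[idx, s] + config$wave_amplitude *
                sin(2 * pi * config$wave_cycles * t_chr + phase)
        }
    }
    ratios <- ratios + matrix(rnorm(n_probes * n, 0, config$noise_sd),
                              n_probes, n)

    # DFS: relapse == event; truncated-exponential event times,
    # uniform censoring for relapse-free samples
    sm <- config$survival_model
    h <- sm$relapse_hazard * ifelse(stage == "III", sm$hr_stage3, 1)
    u <- runif(n)
    t_event <- -log(1 - u * (1 - exp(-h * sm$horizon))) / h
    dfs_time <- ifelse(relapse, t_event,
                       runif(n, sm$censor_min, sm$censor_max))
    dfs_time <- pmax(dfs_time, 0.1)
    adjuvant <- stage == "III"
    if (any(adjuvant)) adjuvant[sample(which(adjuvant), 1)] <- FALSE

    clinical <- clinical_table(data.frame(
        sample_id = samples, stage = stage, relapse = relapse,
        dfs_time = dfs_time, event = relapse, adjuvant = adjuvant,
        stringsAsFactors = FALSE))

    truth <- structure(list(
        segments = truth_seg$segments,
        breakpoints = setNames(truth_seg$breakpoints, samples),
        state_mat = state_mat,
        relapse = setNames(relapse, samples),
        stage = setNames(stage, samples),
        relapse_carrier = setNames(relapse_carrier, samples),
        dfs_time = setNames(dfs_time, samples),
        event = setNames(relapse, samples),
        mutations = mut), class = "sim_truth")

    list(cohort = cna_cohort(panel, ratios), clinical = clinical,
         mutations = mut, truth = truth, config = config)
}

#' Simulate exponential survival times for labelled strata
#'
#' Event times are exponential with hazard `baseline_hazard * hazard_ratio ^
#' stratum` and administratively censored at `horizon` months.
#'
#' @param labels integer/logical stratum per sample (0 = baseline).
#' @param model list with `baseline_hazard` (> 0, events per month),
#'   `hazard_ratio` (> 0) and `horizon` (months).
#' @param seed optional RNG seed.
#' @return data.frame (dfs_time, event).
#' @export
simulate_survival <- function(labels, model, seed = NULL) {
    if (length(labels) == 0) stop("empty cohort")
    if (model$baseline_hazard <= 0 || model$hazard_ratio <= 0)
        stop("baseline hazard and hazard ratio must be > 0")
    if (!is.null(seed)) set.seed(seed)
    z <- as.numeric(labels)
    h <- model$baseline_hazard * model$hazard_ratio^z
    t_event <- rexp(length(z), rate = h)
    event <- t_event <= model$horizon
    data.frame(dfs_time = pmin(t_event, model$horizon), event = event)
}
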
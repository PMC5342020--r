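# cnacohort

Cohort-level analysis of somatic copy-number aberrations (CNAs) from
array-CGH log2 ratios, aimed at tumor-cohort studies that ask which
chromosomal gains, losses and breakpoints recur across samples and whether
they associate with clinical outcome (relapse, disease-free survival,
mutation status). The package covers the full path from probe-level ratios
to cohort statistics:

* **Segmentation** — circular binary segmentation per sample: the maximal
  standardized arc contrast `|S_j − S_i − (m/n) S_n| / sqrt(m(n−m)/n)` is
  located recursively (C++ inner loop), splits are kept at a within-window
  permutation p < α, and adjacent segments are re-merged when their mean
  difference falls below `undo_sd × σ` ("SD-undo": multiplier 2 for short,
  3 for long segments), with median, optional wave, and post-segmental
  mode normalization.
* **Calling** — a probe-count-weighted four-component Gaussian mixture
  (loss / neutral / gain / amplification) fitted by constrained EM;
  per-segment class posteriors by Bayes' rule with the state assigned by
  the posterior > 0.5 rule.
* **Regions** — greedy reduction of the probe × sample call matrix into
  co-aberrant regions under an average call-disagreement budget
  (`averror = 0.015`).
* **Breakpoints** — per-sample breakpoints at segment starts; per-probe
  recurrence against a Binomial(n, r) random-breakage null with BH
  correction; gene mapping with pooling of indistinguishable genes and a
  Tarone-Gilbert discrete FDR for recurrent breakpoint genes
  (`q_g = 1 − (1 − r)^{m_g}`).
* **Cohort statistics** — 2×2 chi-square association tests per region and
  aberration type with permutation p-values and a permutation-based FDR
  (averaged exceedance over a pooled gain/loss family); per-sample
  CNA-score and BP-score instability measures; Mann-Whitney, Fisher exact
  and Ward clustering on call posteriors (total-variation distance).
* **Survival** — Kaplan-Meier, log-rank (O−E with hypergeometric
  variance, vectorized over regions for permutation screening), and Cox
  hazard ratios with Breslow ties.
* **Mutations** — sample × gene matrix from variant records (VAF ≥ 0.20,
  non-synonymous, not a known polymorphism), pathway pooling
  (KRAS/NRAS/BRAF → MAPK), co-occurrence tests, oncoprint export.
* **Synthetic cohorts** — a generator that emulates a stage II/III
  microsatellite-stable colon-cancer series (57 + 57 samples, stage-wise
  relapse rates 39%/47%, CRC-typical aberration frequencies, a
  relapse-enriched loss region at 98% vs 74.5% penetrance,
  mutation-coupled instability, exponential DFS) with complete ground
  truth, so every stage of the pipeline is testable offline.

See `vignettes/cna-cohort-methods.Rmd` for the models, parameter choices
and their rationale.

## Worked example

```r
library(cnacohort)

sim <- simulate_cohort(sim_config(seed = 7))   # default 114-sample cohort
seg <- segment_cohort(sim$cohort)
seg
#> seg_cohort: 114 samples, 1617 segments, 0 QC failures

mix <- fit_call_mixture(seg)
mix
#> cna_mixture (4 effective components)
#>       loss neutral   gain amplification
#> pi  0.1488  0.6617 0.1885        0.0010
#> mu -0.5997  0.0000 0.4505        1.1937
#> sd  0.0300  0.0300 0.0300        0.0300

calls <- call_states(seg, mix)
regions <- reduce_regions(calls)
regions
#> cna_regions: 257 regions x 114 samples (averror 0.015)

bps <- test_breakpoint_locations(detect_breakpoints(seg))
sum(bps$significant)
#> [1] 10

res <- compare_groups(regions,
                      factor(ifelse(sim$clinical$relapse,
                                    "relapse", "relapse_free")),
                      n_perm = 10000, seed = 7)
head(res[order(res$p), c("region", "chrom", "type", "stat", "p", "fdr",
                         "freq_pct_group1", "freq_pct_group2")], 3)
#>     region chrom type     stat         p          fdr freq_pct_group1 freq_pct_group2
#> 114     84     2 loss 14.89218 9.999e-05 0.0014777778        95.91837        66.15385
#> 116     86     2 loss 17.54871 9.999e-05 0.0005166667        97.95918        66.15385
#> 117     87     2 loss 17.54871 9.999e-05 0.0005166667        97.95918        66.15385
```

The mixture recovers the generator's planted state offsets (−0.6 / 0 /
+0.45 / +1.2 log2 units). The breakpoint screen flags the probes at the
planted archetype boundaries. The association screen's top regions are the
loss planted on synthetic chromosome 2, carried by ~98% of relapsed versus
~66% of relapse-free samples in this realization, at a permutation p of
1e-4 (the resolution of 10,000 permutations) and permutation FDR well
below the 0.2 cutoff.

Per-sample instability scores and survival screens follow the same
pattern:

```r
sco <- instability_scores(calls, bps)
head(sco, 3)
#>      sample cna_score bp_score
#> S001   S001       348        6
#> S002   S002       917       12
#> S003   S003       856       11

surv <- logrank_permutation_regions(regions, sim$clinical,
                                    n_perm = 10000, seed = 7)
```

A thin command-line front end over the same functions is installed at
`inst/scripts/cna-pipeline.R` (subcommands `simulate`, `segment`, `call`,
`regions`, `breakpoints`, `group-test`, `survival-test`, `scores`,
`mutation-test`).

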
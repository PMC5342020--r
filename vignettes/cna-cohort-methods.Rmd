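---
title: "Methods: cohort-level copy-number aberration and breakpoint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-level copy-number aberration and breakpoint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnacohort)
```

# Scope and model

`cnacohort` analyses somatic copy-number aberrations (CNAs) across a tumor
cohort profiled by array-CGH. The input is a probe panel (chromosome,
position, enrichment flag) and a probe × sample matrix of log2 tumor/normal
intensity ratios. The pipeline proceeds per sample from ratios to segments
to four-state copy-number calls, then cohort-wide from calls to co-aberrant
regions, CNA-associated breakpoints, recurrent breakpoint genes,
association and survival screens, and chromosomal-instability scores. A
synthetic-cohort generator with full ground truth makes every stage
testable without external data.

The statistical model underlying calling is simple and explicit: after
normalization, a sample's log2 ratios are piecewise constant over
chromosome segments plus Gaussian probe noise; segment means across the
cohort arise from a four-component Gaussian mixture whose components
correspond to loss, neutral, gain and amplification states. Breakpoint
recurrence is judged against a uniform random-breakage null: every usable
probe collects breakpoints independently at the genome-wide per-probe rate.

# The synthetic cohort generator

`simulate_cohort()` emulates a two-stratum stage II/III microsatellite-stable
colon-cancer series. Its defaults are the study conditions, not tuning
knobs:

* **Design**: 114 samples split 57/57 across stages, with 22 and 27
  relapses drawn deterministically per stratum (relapse fractions 39% and
  47%). The relapse label *is* the disease-free-survival event.
* **Genome**: 5 synthetic chromosomes × 400 evenly spaced probes (17 kb
  spacing). This scaled-down genome keeps a full pipeline run in seconds;
  the ~180K-probe scale of real arrays is a configuration choice.
* **Aberrations**: archetype regions at colorectal-typical population
  frequencies — arm-level and whole-chromosome losses and gains (30–50%)
  plus one focal amplification (10%) — mirroring the canonical CRC pattern
  of losses on 1p/4/8p/17p/18 and gains on 7/8q/13q/20q, mapped onto the
  synthetic chromosomes. One boundary (end of the 8p-like loss, carried by
  35% of samples) doubles as a fragile-site emulation for
  recurrent-breakpoint-gene recovery tests.
* **Relapse-linked region**: a loss on synthetic chromosome 2 carried by
  98% of relapsed and 74.5% of relapse-free samples, reproducing the
  18q12-type association structure.
* **State offsets**: loss −0.6, neutral 0, gain +0.45, amplification +1.2
  log2 units — typical values for tumor-content-diluted aCGH; configurable.
* **Noise and waves**: Gaussian probe noise (SD 0.1) and an optional
  per-sample, per-chromosome sinusoid with random phase (1.5 cycles,
  default off) standing in for the low-frequency "genomic wave" artifact.
* **Mutations**: gene frequencies follow published colon-cancer rates (APC
  45%, TP53 55%, KRAS 35%, ...); KRAS/NRAS/BRAF are drawn mutually
  exclusively. TP53 (+4) and APC (+2) mutants receive extra random aberrant
  segments of 20–80 probes — the chromosomal-instability coupling that
  downstream score comparisons must recover.
* **Survival**: relapsed samples receive truncated-exponential event times
  (hazard 0.03/month, truncated at the 91.3-month follow-up maximum);
  relapse-free samples are censored uniformly over the observed follow-up
  range (28.5–91.3 months, median near 57 months). The generic
  `simulate_survival()` uses a plain exponential-with-horizon model and is
  the tool for hazard-ratio recovery simulations.

Ground truth (true segments, breakpoint probes, labels, mutation status) is
derived from the final per-probe state matrix, so overlapping extra
segments are handled consistently: truth is whatever piecewise-constant
profile was actually generated.

What the generator does **not** model: FFPE fragmentation, dye bias,
GC-content waves with realistic autocorrelation, probe-specific response,
tumor-cell-fraction dilution (available as a configuration, off by
default), or read-level sequencing error. Passing recovery tests therefore
demonstrates correctness of the algorithms under idealized piecewise
Gaussian data, not robustness to every artifact of archival material.

# Segmentation

`cbs_segment()` implements circular binary segmentation: within each
chromosome window it scans all arcs (probe intervals, including those
anchored at window edges) for the maximal standardized mean contrast of the
arc against the rest of the window, and keeps the split only if a
within-window permutation p-value falls below `alpha` (default 0.01,
`n_perm = 1000`). An interior arc contributes two change points at once,
which is what gives the circular statistic its power on short interior
segments; a plain binary max-t splitter misses them or mislocalizes their
edges, which is why the full arc scan was adopted. The scan is O(n²) per
window and implemented in C++ with early termination of the permutation
loop once significance is no longer attainable.

After splitting, "SD-undo" pruning re-merges adjacent segments whose mean
difference falls below `undo_sd × σ`, with σ the sample's residual SD
estimated as MAD of lag-1 differences divided by √2. The multiplier is 2
for short segments and 3 when both neighbours exceed 30 probes; the length
threshold separating the two regimes is not defined by the conventions this
follows, so 30 probes is a documented choice exposed as `undo_len`.

Preprocessing: per-sample median normalization (median exactly 0), optional
wave detrending, and post-segmental mode normalization, which re-centers
each sample at the mode of the probe-weighted kernel density of its segment
means — the dominant state is assumed neutral. Mode normalization is
reliable only while the neutral state covers the plurality of the genome;
a sample aberrant over half its genome can be re-centered on the wrong
state, a known limitation shared by all mode-centring callers.

Per-sample QC is the MAD of lag-1 differences / √2 with a failure threshold
of 0.4 log2 units.

## Wave detrending

`detrend_waves()` removes smooth per-chromosome trends in two stages. Stage
one captures the bulk of the wave with a running median (window
`span·n/1.2` probes, large enough that copy-number segments cannot
dominate it) followed by loess, applied twice because a running median
attenuates sinusoid amplitude. Stage two protects genuine steps: the
residual is segmented, each boundary's jump height is estimated from local
mean differences of the raw signal — a local difference is trend-free, so
boundaries induced by stage-one artifacts receive near-zero jumps — jumps
below `min_jump = 0.25` log2 units are attributed to trend drift and
dropped, the cumulative step function is subtracted, and the trend is
re-fit by plain loess on the step-free remainder. Detrending is off by
default; the generator's default cohorts contain no waves.

# Calling

`fit_call_mixture()` fits the four-component Gaussian mixture to all
segment means, weighting each mean by its probe count. EM is initialized by
quantile seeding (2.5/50/90/99th percentiles) with 10 deterministically
seeded jittered restarts, keeping the best weighted likelihood. Component
means are constrained to per-class boxes — loss ≤ −0.15, neutral within
±0.1, gain in [0.15, 0.75], amplification ≥ 0.8 — which act as calibration
priors on what the four labels mean in log2 space. The neutral constraint
and the mean ordering follow directly; the outer boxes were added because
an unconstrained fit occasionally parks a broad component inside the
neutral mass when amplifications are rare, scrambling the label-to-position
correspondence. Component SDs are bounded to [0.03, 0.5]. If the
amplification component's weight degenerates below 1e-4 the model is refit
with three components and amplification retained at zero weight.

`call_states()` computes per-segment class posteriors by Bayes' rule with
the log-likelihood multiplied by the segment's probe count, so long
segments get near-certain posteriors while short ones stay soft. The state
is the class whose posterior exceeds 0.5; if none does, the segment is
neutral. Probes inherit their segment's state and posterior vector.

`reduce_regions()` compresses the probe × sample call matrix into
co-aberrant regions by a greedy left-to-right merge: a probe joins the
current region while every member probe disagrees with the region's
consensus signature (per-sample modal state, ties resolved toward the more
negative state) in at most `averror = 0.015` of samples on average. With
`averror = 0` the regions are exactly maximal runs of identical call
columns. Region-level posteriors are probe averages, and region calls are
per-sample modal states.

# Breakpoints and recurrent breakpoint genes

A CNA-associated breakpoint is anchored to the first probe of every
segment except each chromosome's first — a unique probe address consistent
with probe-level testing. Enrichment probes (extra probes densifying
cancer-gene loci) must be removed before segmentation for breakpoint
analysis so the genome-wide rate r = breakpoints / (probes × samples)
refers to evenly spaced probes; `detect_breakpoints()` refuses panels that
still contain them.

Per-probe recurrence is tested against Binomial(n_samples, r) with BH
correction over all usable probes (significance at FDR < 0.1). Genes (read
from BED, converted to 1-based inclusive coordinates) associate with the
probes inside their span; genes containing no probe are excluded and a
break between two flanking probes is not attributed to the gene between
them (a resolution-driven choice: attribution would be ambiguous at array
scale). Genes with identical probe sets are indistinguishable and are
pooled into one entry whose affected-sample set is the union over members.
A sample counts once per gene regardless of how many of its probes break.

Per-gene testing uses the null q_g = 1 − (1 − r)^{m_g} for a gene with m_g
probes and the binomial tail p-value at the observed number of affected
samples. Multiple testing is a Tarone-Gilbert discrete FDR: genes whose
minimum achievable p-value (every sample affected, q_g^n) exceeds the
significance threshold can never be rejected, and excluding them before BH
shrinks the denominator; the procedure provably never flags fewer genes
than plain BH on the same p-values.

# Cohort statistics

`compare_groups()` tests each region × aberration type (gain vs no-gain
counting amplification as gain; loss vs no-loss) with the 2×2 chi-square
statistic without continuity correction. Inference is by permutation
(default 10,000 label shuffles): the permutation p-value is
(1 + #{null ≥ observed}) / (1 + B), and the FDR is the averaged-exceedance
estimator — the mean count of null statistics anywhere in the family
reaching a region's observed statistic, divided by the number of observed
statistics reaching it. The family pools both aberration types with shared
permutations; running the two types as separate FDR families doubles the
chance of a spurious discovery under the complete null, which the pooled
family avoids (the package's null-calibration test measures this). Regions
aberrant in fewer than 10% of samples are excluded per type before
testing; significance is FDR < 0.2. The continuity correction is omitted
deliberately: the permutation distribution, not the asymptotic χ², is the
inferential reference.

Chromosomal instability is summarized per sample by the CNA-score (probes
in a non-neutral state) and BP-score (breakpoint count on the
enrichment-free panel); score comparisons between mutation-defined strata
use the two-sided Mann-Whitney U test, exact by enumeration when the
combined n ≤ 20 without ties and normal-approximated with tie correction
otherwise. Fisher's exact test (conditional two-sided) serves mutation
co-occurrence; the sample odds ratio is reported raw, with Haldane's 0.5
correction only for display.

Unsupervised clustering operates on region-level posteriors, not hard
calls: the dissimilarity between two samples is the mean over regions of
the total-variation distance between their four-class posterior vectors (a
metric on [0, 1]), agglomerated with classic Ward linkage ('ward.D').
`hclust`'s deterministic merge order provides reproducibility. This is a
documented stand-in for ordinal posterior-weighted clustering; it preserves
the intent (soft calls drive the dendrogram) without reproducing an
unpublished weighting scheme.

# Survival

Kaplan-Meier estimation and Cox regression are delegated to the `survival`
package; the log-rank statistic is computed natively (O−E with
hypergeometric variance at each event time) because the per-region
permutation screen needs it vectorized over hundreds of regions — a single
pass of cumulative sums evaluates all regions at once, making 10,000
permutations practical. With untied event times the statistic equals the
Cox partial-likelihood score test at β = 0 with Breslow tie handling to
machine precision, and the test suite asserts this identity; with tied
times the hypergeometric variance carries a finite-population correction
that the Breslow score variance omits, so the native statistic then agrees
with `survival::survdiff`, not with the score test.

`logrank_permutation_regions()` shuffles the (time, event) tuples against
the call columns and applies the same pooled-family permutation FDR as the
association screen. `cox_hr()` fits the binary-covariate Cox model with
Breslow ties (Efron behind a flag), reports HR with a 95% Wald interval,
and flags monotone partial likelihoods (complete separation) instead of
reporting a spurious finite estimate.

# Mutations

A gene is mutated in a sample when at least one variant record has a
variant allele fraction of at least 0.20 (strict ≥), is not synonymous, and
is not a known polymorphism; the polymorphism status is an input flag, not
a database lookup. Derived pathway columns (MAPK = KRAS ∨ NRAS ∨ BRAF;
APC-or-MAPK) are recomputed by `pathway_combine()` rather than stored.
`oncoprint_export()` writes a canonical gene × sample 0/1 layout ordered by
gene frequency and sample burden.

# Numerical choices and problem sizes

Fixed seeds govern every stochastic component: the generator takes an
explicit seed, EM restarts use fixed internal seeds, permutation engines
accept a seed, and the C++ permutation loop draws from R's RNG so
`set.seed()` controls it. Degenerate inputs are handled explicitly:
single-probe chromosomes yield trivial segments, all-zero cohorts call
neutral everywhere, zero breakage rates give unit p-values, zero-margin
tables are flagged, and a zero censoring horizon produces inputs that
downstream survival functions refuse.

The test suite runs the full pipeline on cohorts of 15–40 samples
(2,000 probes) with 200–500 permutations per split, and the
recurrent-gene power check on ten 114-sample cohorts; these sizes were
chosen so a complete run finishes in minutes on one core while leaving all
recovery margins (breakpoint recall, calling accuracy, FDR calibration)
comfortably measurable. The acceptance script uses the full 114-sample
default cohort with 1,000 permutations.

# Known limitations

* Mode normalization assumes a dominant neutral state (see above).
* The mixture's class boxes encode typical tumor-content-diluted offsets;
  cohorts with unusual dilution need adjusted boxes and state offsets.
* The random-breakage null treats probes as exchangeable; real genomes
  have non-uniform fragility, so the per-gene null is a screening device,
  not a mechanistic model.
* The region reduction is a greedy single pass; it guarantees the
  heterogeneity budget but not a globally minimal region count.
* Association and survival screens are univariate two-group procedures by
  design; no covariate adjustment is offered.
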
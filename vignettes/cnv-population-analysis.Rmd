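---
title: "Population analysis of SNP-array CNV: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of SNP-array CNV: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvherd)
```

# What the package computes

`cnvherd` analyses copy number variation (CNV) called from SNP genotyping
arrays at the population level. The inputs are per-sample CNV calls in the
PennCNV text dialect, probe-level log R ratio (LRR) and B-allele frequency
(BAF) matrices, sample metadata (breed, breed group, sex), and optional
annotation interval sets (genes, segmental duplications, published CNVR
sets). The outputs are: a per-sample QC report, a population B-allele
frequency (PFB) track, CNV regions (CNVRs) with class and cohort frequency,
per-sample burden summaries with a group-comparison test battery, V~st~
differentiation scans with a sex-dosage artifact filter, a UPGMA tree over
Jaccard distances on CNVR presence/absence, and overlap accounting against
reference interval sets. A synthetic-cohort generator with known truth makes
every stage testable without access to any external data set.

# Signal model and quality control

LRR is normalized total probe intensity (0 at two copies; negative under
loss, positive under gain) and BAF is the normalized allelic ratio, which at
normal copy number clusters in bands near 0, 0.5 and 1. Three per-sample QC
statistics are computed by `sample_qc()`:

* **LRR standard deviation** over all probes; default cut 0.30. Samples with
  noisy total intensity generate excess spurious calls.
* **BAF drift**: the fraction of probes with BAF in the open intervals
  (0.2, 0.25) or (0.75, 0.8), i.e. stray points between the canonical
  genotype bands; default cut 0.002. Published QC rules for this data type
  quote a "standard deviation of BAF > 0.001" cut, but the SD of raw BAF
  cannot be meant: the tri-modal BAF distribution puts it near 0.4 for every
  sample, clean or not. We therefore use the drift fraction (the metric
  PennCNV itself reports for this purpose) and additionally report the raw
  `baf_sd` so users can apply either; the threshold is configurable.
* **Wave factor**: long-range "waviness" of LRR. It is not given a formula
  in the array-CNV QC literature we follow, so we define it as a simple,
  auditable statistic: the SD of per-window median LRR over non-overlapping
  1 Mb windows per chromosome; default cut 0.05. Medians rather than means
  keep real CNVs from inflating the statistic.

A sample passes QC iff all three statistics are at or below their cuts.

**PFB** (`compute_pfb()`) is the arithmetic mean BAF of each probe across the
cohort — the standard companion track for HMM-based CNV callers.

**GC-wave adjustment** (`gc_adjust_lrr()`): genomic waves track the GC
fraction of the megabase-scale neighbourhood of each probe. Per sample we fit
an ordinary least-squares regression of LRR on the probe's 1 Mb-window GC
fraction and subtract the mean-centred fitted component, preserving each
sample's mean LRR exactly. The published pipelines delegate this step to
PennCNV's `gcmodel` regression, whose exact implementation is not specified
in the sources we follow; a per-sample linear fit is the transparent
equivalent. The operation is idempotent (residuals are uncorrelated with GC)
and is skipped when GC is constant (degenerate regression).

# CNV calls, CNVRs and burden

Calls are 1-based inclusive autosomal (chromosomes 1–29) events with copy
state in {0, 1, 3, 4}; `cn = 2` records are rejected. Calls spanning fewer
than 3 probes are dropped (`filter_calls()`, configurable).

A **CNVR** (`build_cnvrs()`) is the union of overlapping CNVs detected in at
least two different samples. We implement this as transitive
connected-component merging of the ≥1 bp overlap graph per chromosome:
components whose calls come from ≥2 distinct samples become CNVRs (span =
min start to max end), single-sample components are kept separately as
singleton clusters. Overlapping calls from the same sample may share a
component but count once for support. Adjacent calls (zero shared bases) are
*not* merged. This yields genome-tiling CNVRs whose spans per chromosome are
pairwise disjoint. The class is *loss* if all member copy states are < 2,
*gain* if all are > 2, *complex* otherwise. Whether same-sample overlapping
calls are pre-merged before construction makes no difference to the
resulting spans under this definition.

CNVR **frequency** is `100 * supporters / cohort size`. Display values are
*truncated* (not rounded) to two decimals — 145 of 149 supporters is
97.3154…%, displayed as 97.31 — matching how such frequencies are
conventionally printed; thresholding (e.g. "frequency > 5%") always uses the
raw value.

**Burden** (`per_sample_burden()`) counts per sample: calls, cumulative
length (`end − start + 1`), genic calls (≥1 bp overlap with a gene), genic
deletions (genic with copy state < 2), percentage genic, and cumulative genic
length.

**Outlier removal** (`remove_outlier_samples()`): within each breed with more
than five samples, a sample is dropped when its call count or cumulative
length is more than 3 SD from the breed mean, in either metric. The
reference mean and SD for each sample are computed from the *other* members
of its breed (leave-one-out). This choice is forced by arithmetic: with the
small per-breed sample sizes these cohorts have (say n = 6), a contaminated
sample included in its own reference statistics can never exceed
`(n − 1)/√n ≈ 2.04` SDs, so an included-sample rule would be a no-op at the
3 SD cut.

**Group comparison** (`group_burden_tests()`): a tie-corrected
Kruskal–Wallis test on per-sample counts and a one-way ANOVA on cumulative
lengths; when an omnibus test is significant at 0.05, all pairwise
Mann–Whitney (counts) and Welch t-tests (lengths) follow with Bonferroni
correction (raw p × number of pairs, capped at 1). Rank-sum tests use exact
enumeration when both groups have ≤ 8 samples and no ties, the
continuity-corrected normal approximation otherwise.

# V~st~ differentiation scan

For a probe and two groups A and B, `per_probe_vst()` computes

$$V_{st} = \frac{V_T - V_S}{V_T}, \qquad
  V_S = \frac{n_A V_A + n_B V_B}{n_A + n_B}$$

where $V_T$ is the variance of LRR over the pooled samples and $V_A$, $V_B$
are within-group variances. $V_{st}$ is 0 for no differentiation and 1 for
complete differentiation. Some descriptions print the numerator reversed
($(V_S - V_T)/V_T$), which contradicts the statistic's stated 0–1 range; we
implement the standard orientation. Two numerical choices matter and are
exposed as options:

* **Population variances** (denominator $n$) are the default so that two
  groups with identical value multisets give exactly $V_{st} = 0$ on finite
  samples ($V_S = V_T$ holds only with denominator-$n$ variances).
* **Size-weighted $V_S$** follows the original V~st~ literature; an
  unweighted mean is available.

Negative values (within-group variance exceeding total) are retained
unclamped; $V_T = 0$ defines $V_{st} = 0$. V~st~ is computed on GC-adjusted
LRR in the pipeline so that shared waves do not masquerade as
differentiation.

`scan_differentiated_runs()` reports maximal runs of ≥ 3 consecutive
same-chromosome probes with $V_{st}$ strictly above 0.35 (both
configurable), equivalent to a 3-probe sliding window with single-probe
shift whose significant windows are merged. A CNV or CNVR is flagged
*population differentiated* (`map_runs_to_cnvs()`) only when its span fully
contains a run.

**Sex-dosage artifact filter** (`sex_artifact_filter()`): sex-chromosome
sequence mis-assembled onto autosomes distorts the male/female dosage ratio,
producing spurious differentiation whenever group sex ratios differ. For
each run, each sample's mean LRR over the run's probes is compared between
sexes with a two-sided Wilcoxon rank-sum test, Bonferroni-adjusted across
the runs tested; a run is flagged at adjusted p < 0.05, and is *untestable*
when either sex has fewer than two known-sex samples. The original analyses
judged this male–female LRR difference from per-locus inspection; the rank
test is this package's formalization of that check, chosen over a t-test
because run-mean LRR distributions are mixtures (carriers and
non-carriers), not Gaussian.

# Clustering

Each sample is encoded as a binary presence/absence vector over CNVRs
(`binary_cnvr_matrix()`). Distances are Jaccard: $d = 1 - |V_i \cap V_j| /
|V_i \cup V_j|$; two samples with no CNVRs at all are defined to be
identical ($d = 0$; the Jaccard index is undefined there). `upgma()` is the
textbook unweighted pair-group method with arithmetic mean — join the
closest pair, new distances are size-weighted averages, node height is half
the joining distance — so the result is ultrametric by construction. Tied
minima are broken by the lexicographically smallest pair of cluster
representatives (each cluster represented by its smallest member id), making
the tree invariant to input order; reference implementations of UPGMA do not
document their tie behaviour, so we fixed one deterministically. Trees are
exported as Newick with branch lengths.

# The synthetic cohort generator

`simulate_cohort()` emulates the data model the analysis consumes, with
known truth:

* **Probe map**: by default 5 chromosomes × 400 probes at 20 kb spacing,
  with a sinusoidal GC track (fraction 0.45 ± 0.08, 8 Mb period). The 20 kb
  spacing puts 50 probes in each 1 Mb QC window so that windowed medians are
  estimated with a precision comparable to dense commercial arrays; at much
  sparser spacing the wave factor of a perfectly clean sample is dominated
  by the sampling error of the window medians rather than by waviness.
* **Cohort**: five breed groups (BAI, BRI, IBR, NLD, ALP), two breeds each,
  four samples per breed, balanced sexes — a desk-scale image of a
  multi-breed European cattle cohort.
* **CNV catalog**: each polymorphism is a probe span (≥ 3 probes, so planted
  truth survives the call filter), a copy state, and per-group carrier
  frequencies; carriers are independent Bernoulli draws. The default
  catalog is mostly deletions with a few gains and one loss/gain pair
  sharing a locus (producing a complex CNVR), at frequencies between 0.05
  and 0.8 that differ between groups.
* **Signal**: carrier LRR means by copy state are 0 → −3.0, 1 → −0.66,
  2 → 0, 3 → +0.40, 4 → +0.68 (standard array-CNV working values;
  overridable). BAF band structure follows the copy state: one copy has no
  heterozygous band; three copies band near {0, 1/3, 2/3, 1}; four near
  {0, 1/4, 1/2, 3/4, 1}; zero copies carry no allelic information (uniform
  BAF). Per-probe LRR noise SD is 0.15 and BAF noise SD 0.03 for clean
  samples; designated noisy samples get LRR noise SD 0.5. Every sample's
  LRR carries a GC-tracking wave with amplitude ~0.02 (per-sample strength
  varies ±25%).
* **Artifacts**: configured probe ranges add a fixed +0.3 LRR offset in
  males only (the sex-dosage mis-assembly signature); an optional jitter
  mode perturbs emitted call boundaries by ±1 probe to test robustness of
  downstream interval logic.
* **Truth**: planted events are emitted directly as the call set (the HMM
  calling step is an external tool outside this package's scope), so
  downstream stages are tested against exact truth.

What the generator deliberately does **not** emulate: raw X/Y intensity
channels, genotype clustering, linkage disequilibrium between probes,
probe-specific bias, batch effects, or realistic chromosome lengths. Passing
tests therefore demonstrate the correctness of the analysis logic under a
faithful signal model, not calling performance on real arrays.

# Pipeline, determinism and problem sizes

`run_pipeline()` runs simulate/load → QC → PFB/GC-adjust → filter →
singletons → burden and group tests → CNVRs → reference overlap → V~st~
scans (all group pairs, or one configured pair) → clustering, and writes a
JSON manifest with the seed, package version, input checksums, per-stage
record counts and per-file MD5 checksums. All randomness flows from the
single seed in `pipeline_config()`; reruns with the same configuration are
byte-identical. Defaults in `pipeline_config()` are the field-standard
values quoted above.

The test suite and the acceptance script exercise the pipeline at sizes
chosen to characterize behaviour well while staying desk-scale: 1,000 random
toy instances against a base-pair bitmap oracle for CNVR construction; 100
seeded replicates for V~st~ recovery (2 groups × 20 samples, a 10-probe
deletion at carrier frequencies 0.9 vs 0.0, noise SD 0.15) and for the null
case; 100 replicates for UPGMA group separation; 500–1,000 null replicates
for the Kruskal–Wallis calibration check.

# Known limitations

* The package consumes CNV calls; it does not re-call CNVs from intensities
  (no HMM), and it consumes segmental-duplication interval sets rather than
  discovering them from sequence.
* The "overlapped cumulative length %" in reference comparisons is defined
  as intersection length over the *reference* set's cumulative length; the
  reciprocal definition can be obtained by swapping the arguments.
* Singleton identification defaults to running after QC but before outlier
  removal; both orders are possible by composing the functions.
* No permutation-based significance for V~st~ — the fixed 0.35 cutoff is
  the field's convention for this statistic on LRR.
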
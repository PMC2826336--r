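---
title: "Inferring a phase-structured regulatory network from chilling-stress time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a phase-structured regulatory network from chilling-stress time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chillregnet)
```

## The problem

Japonica rice seedlings survive transient chilling (around 10 °C) but not
prolonged exposure. A large part of the early chilling-induced
transcriptome behaves like an oxidative-stress response: intracellular
H~2~O~2~ spikes within the first hours, and many chilling-induced genes are
also induced by exogenous H~2~O~2~ applied at optimal temperature.
`chillregnet` implements the inference chain that turns two two-channel
expression time courses — a chilling series sampled at 0.5, 2, 4, 6, 12,
18, 24, 36, 48 and 96 h and an H~2~O~2~ (oxidative mimic) series sampled at
1, 3 and 6 h — plus promoter sequences, a cis-element catalog and a QTL map
into a phase-structured transcriptional regulatory network:

1. induction/repression calling,
2. induction-wave segmentation and phase assignment,
3. k-means co-expression clustering of upregulated non-TF genes,
4. per-cluster de novo promoter motif discovery,
5. cis-element class enrichment scoring,
6. ranked TF-class-to-cluster network edges with oxidative-mediation
   labels, and
7. Fisher-exact QTL co-localization of upregulated TFs.

A synthetic-data generator with full ground truth makes every stage
testable without any external download.

## Calling rules

All cells carry a log~2~(treated/control) ratio and a p-value from a
two-sided one-sample t-test over biological replicates. The rules are:

* **Induced time point**: ratio ≥ 1.8 (log~2~ units) with p < 0.05. Both
  thresholds are `call_config()` parameters.
* **Upregulated gene**: at least two *consecutive samples* induced, and —
  for the chilling call — no sample with ratio ≤ −1.8 at p < 0.05.
  "Consecutive" means adjacent positions in the sampled series (6 h then
  12 h are consecutive samples), because the time grid is non-uniform.
* **Downregulated gene**: at least one sample with ratio ≤ −1.8 at
  p < 0.05 and *no* sample whose ratio reaches +1.8. The up-exclusion is
  applied on the ratio alone, without a p filter, mirroring the asymmetric
  phrasing of the calling rule it reproduces; both guards are
  config-switchable (`down_excludes_by_ratio_only`, `require_never_down`).
* **H~2~O~2~-responsive gene**: the single-time-point variant (one induced
  sample suffices, no never-down guard).
* Whether significance is required at every induced time point or only
  somewhere in the profile is genuinely open; we require it per time point
  (`per_timepoint_alpha = TRUE`), the stricter reading.

**Waves** are maximal runs of consecutive induced samples; a gene with
more than one wave is flagged *interrupted* (multiphasic). **Phases**
follow the earliest induced hour *t*: phase 1 ("early rapid") when
*t* ≤ 6 h, phase 2 ("early slow") when 6 < *t* ≤ 24 h, phase 3 ("late")
when *t* > 24 h. The upper bounds are inclusive.

## Co-expression clustering

Upregulated non-TF genes are clustered on their raw log~2~ profiles by
k-means (Euclidean; a Pearson-distance flag standardizes rows first).
The default k = 18 mirrors the emulated study, which does not report how
its cluster count was chosen; no model-selection step is implemented and
this is a documented limitation. The implementation is Lloyd's algorithm
with k-means++ seeding, 20 restarts scored by within-cluster sum of
squares, farthest-point re-seeding of empty clusters, and an internal
assertion that the SSE never increases across iterations. k-means++ was
chosen after plain random seeding showed occasional merge/split local
optima on well-separated planted templates.

Each cluster's **consensus profile** binarizes the centroid at the
induction threshold (1.8); an all-zero consensus marks the cluster
degenerate. The cluster phase is the phase of the first consensus 1. The
cluster's **H~2~O~2~ fraction** is the share of members in the
H~2~O~2~-responsive set. Tightness (mean distance to centroid) is reported
but not used as a filter.

## Motif discovery

Promoter windows span −1,000 to +200 relative to the TSS (minus-strand
genes are reverse-complemented; windows clipped at contig ends are flagged
truncated). Per cluster, `discover_motifs()` extracts up to `n_motifs`
(default 30) motifs of width 8–10 nt:

* Each slot is seeded from the most frequent w-mers among the unmasked
  windows, screened with a 3-iteration EM, and the best seed is refined by
  a full EM under a zero-or-one-occurrence-per-sequence (ZOOPS) model
  against the sequence-set base composition.
* Candidate widths are fitted independently; the slot keeps the width
  with the best EM objective (the ZOOPS log-likelihood ratio). An e-value
  cannot drive this choice because e-values are only defined once the
  background set enters, a later stage.
* A **site** is any window whose PWM log-odds score reaches
  `site_threshold` (default 0.875) times the maximal achievable score.
  The original analysis tool is proprietary and does not document what its
  0.875 threshold applies to; interpreting it as a fraction of the maximal
  log-odds score is this package's reconstruction, and the parameter is
  exposed. Sites of a recorded motif are masked before the next slot.
* Motifs with total information content below `tic_floor` (default 6
  bits) are discarded as uninformative. TIC is
  $\sum_j (2 - H_j)$ bits, with $H_j$ the Shannon entropy of PWM column
  $j$ against a uniform background, so $0 \le \mathrm{TIC} \le 2w$.
* PWMs use a pseudocount of 0.25 per base per column. The IUPAC consensus
  letter of a column covers all bases with probability ≥ 0.30.
* Strands: both by default (cis-elements are orientation-ambiguous); the
  reported consensus is the model's own orientation.

**Background subtraction** (`background_filter()`) scans promoters of
non-responsive genes and computes, per motif, a Bonferroni-scaled
one-sided binomial tail probability of the foreground site-carrying count
given the background per-sequence site probability; motifs with e-value
above 10^−3^ (the magnitude of the published per-motif e-values) are
removed. This e-value is a reconstruction; any monotone enrichment
statistic agreeing with the binomial oracle would serve.

## Element classes and enrichment scores

The packaged catalog maps fine element classes (as1/ocs/TGA-like,
ABRE-like, DRE/CRT-like, rav1-like, GCC-box-like, JAre-like,
MYB2-box-like, GARE-like, pyrimidine-box-like, W-box-like, MYC2-box-like)
to one IUPAC core pattern and one binding TF family each. A motif
consensus is assigned to the best-matching class by ungapped IUPAC-aware
alignment over both orientations and all offsets; a position is
compatible when the base sets intersect, the fraction is taken over the
shorter length, and the default acceptance threshold is 0.75 — a
reconstruction of the unstated "significant database match" criterion,
exposed in config. A motif that also reaches the threshold for other
classes is dual-reported (`also_matches`), which captures the known
W-box/as1 ambiguity.

Scoring pools fine classes into the broad categories used for graphing
(e.g. DRE/CRT-like + rav1-like → "DRE/CRT/rav1-like"; MYB1- and MYB2-box
labels pool together, as the source material itself treats TAGTTTTT as
MYB2-like). The **total enrichment score** of a category in a cluster is
the sum of occurrence percentages of all its motif species occurring in
≥ 50 % of the cluster's promoters; categories without a qualifying motif
are omitted. `dominant_classes()` ranks categories by score, breaking
ties by species count and then name.

## Network inference

An edge links a TF class (broad category + binding family) to a cluster
when the category is enriched in the cluster's promoters *and* at least
one upregulated TF of the family satisfies temporal precedence (TF phase ≤
cluster phase) — the operationalization of "coordinate expression". The
top three candidates become primary/secondary/tertiary edges (matching the
three line styles of the reference network figure); further candidates are
reported unranked, and clusters without candidates carry a no-regulator
flag. Mediation labels use the cluster H~2~O~2~ fraction: ≥ 0.50
oxidative, 0.25–0.50 mixed, < 0.25 independent (left-inclusive). The
bounds are reconstructed from the reported 50–79 % range of
oxidative-mediated clusters versus the 39 % and 16 % outliers, and are
config-exposed.

## QTL co-localization

A gene is QTL-associated when its interval shares ≥ 1 bp with a QTL
interval on the same chromosome (partial-overlap handling is not defined
by the source; ≥ 1 bp is the permissive choice). Enrichment of a subset
(upregulated TFs) uses the one-sided "greater" Fisher exact test — the
hypergeometric tail on the 2×2 table — with enrichment declared when the
subset ratio exceeds the genome-wide ratio *and* p < 0.25. Traits may be
tested pooled (default) or per trait; no multiple-testing correction is
applied across traits, matching the emulated procedure.

## The synthetic-data generator

`generate_study()` emulates the statistical structure of the study design;
its defaults *are* the study conditions:

* 10 chilling hours, 3 H~2~O~2~ hours, 2 biological replicates.
* Phase mixture 71/22/7 % of upregulated non-TF genes; 18 clusters
  allocated 12/5/1 to phases 1/2/3 (the observed configuration; for other
  k a largest-remainder apportionment of the mixture is used).
* Up and down fractions default to 0.30 each, following the roughly
  1 : 2.3 up : down split of the responsive gene set.
* Induced cells have a noise-free log~2~ ratio of 3.0 (comfortably above
  the 1.8 threshold, as published induced profiles typically are), with
  i.i.d. Gaussian replicate noise of SD 0.25; the noise distribution is
  not stated by the source, so Gaussian is assumed and is a config choice
  (`noise_sd`, `n_replicates`). P-values come from the same one-sample
  t-test a practitioner would run; with two replicates this test is
  deliberately weak (df = 1), which is why the up-call recall at default
  noise sits below 1 — real profiles face the same penalty.
* Cluster H~2~O~2~-responsive fractions default to 0.65/0.30/0.15 for
  phase-1/2/3 clusters — midpoints of the reported 50–79 % (phase 1) and
  12–49 % (phases 2–3) ranges, with phase 3 placed at the low end.
* Promoters are 1,200-nt windows of i.i.d. uniform background (an
  optional first-order chain adds mild self-transition bias); each
  cluster's planted element pattern is realized per member with
  probability 0.7 at a uniform position and strand. One catalog class is
  planted per cluster, cycling through the catalog, and one phase-1
  upregulated TF per family is guaranteed so that planted regulators
  always satisfy precedence.
* The QTL map draws 46 intervals of 500 kb across five 30-Mb chromosomes
  (trait symbols COLDTL, SDLVIG, OSADJCAP, SALTSN, CHLCN, LFRL, GERMSP);
  upregulated TFs are relocated to lie entirely inside the QTL union with
  probability min(1, factor × coverage), which makes factor 1 an exact
  null and factor 5 (the default) a strong planted enrichment.
* The H~2~O~2~ experiment's recovery sample is not simulated: it
  contributes nothing to the single-time-point call.

What the generator does **not** emulate: dye bias and spatial array
artifacts, correlated or heavy-tailed noise, realistic promoter base
composition and repeat structure, TF-to-target dynamical coupling (truth
regulators are planted as promoter elements, not simulated kinetically),
and the downregulated network's regulators. Passing recovery tests on
these bundles therefore demonstrates the correctness of the inference
chain under its own model assumptions, not performance on real arrays.

## Numerical choices and degenerate inputs

* Deterministic seeds everywhere: every stochastic stage derives its seed
  from one integer; fixed seed ⇒ byte-identical bundles, motif lists and
  reports.
* k-means ties in assignment break toward the lower cluster index; empty
  clusters re-seed from the globally farthest point.
* EM convergence: relative log-likelihood change below `tol` (default
  10^−4^) or `max_iter`. Columns renormalize to 1 ± 10^−9^ each M-step.
* All-N promoter input, widths exceeding sequence length, and fewer than
  5 sequences are errors; homopolymer input yields no motif above the
  information floor.
* A zero-replicate-variance cell gets p = 0 for a non-zero mean and p = 1
  otherwise, which makes the noise-free limit exact.
* Fisher p-values use `stats::phyper` directly; the suite cross-checks
  them against `stats::fisher.test` and an exhaustive enumeration oracle.

## Problem sizes used in validation

The shipped validation suite runs the generator at 2,000 genes with 18
clusters for end-to-end network-recovery checks (20 seeds; discovery
scaled to width 8, 4 motif slots, 2 seeds per slot, at most 40 promoters
per cluster — the planted elements are 8-mers, and the scaled search
recovers them at the same rate as the full one), 1,000 random profiles
for the call-rule oracle, all 46,375 2×2 tables with N ≤ 30 for the
Fisher oracle, 10 seeds of 100 × 1,200-nt promoters for planted-motif
recovery, and 500 null QTL maps at 250 genes for the calibration check.
The full-width (8–10 nt, 30-slot) search remains the default of
`discovery_config()` for analysis use.

## Known limitations

* The cluster count k is not selected from data.
* The EM reconstruction of the original proprietary motif finder
  reproduces its role (top-N motifs, 8–10 nt, thresholded site calls,
  background subtraction), not its internals; printed per-motif e-values
  are therefore not comparable digit-for-digit.
* Published per-cluster motif tables list only a subset of the motif
  species behind the graphed category scores, so category totals
  recomputed from those tables alone underestimate some graphed ranges.
* Cluster labels are arbitrary (`K01`…); the source's historical labels
  (C78…C100A) can only be carried via config aliases.
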
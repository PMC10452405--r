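---
title: "Methods: subtyping and dose-response analysis of CRC preclinical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtyping and dose-response analysis of CRC preclinical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcsubtype)
```

`crcsubtype` characterizes colorectal cancer (CRC) preclinical model
systems — 2D monolayer cultures, 3D spheroids and xenograft tumors — at two
levels: molecularly, by assigning the intrinsic epithelial consensus
molecular subtypes iCMS2/iCMS3 and by mapping how gene expression travels
across the three model systems; and pharmacologically, by dose–response
analysis of bioluminescence spheroid cytotoxicity assays. This vignette
documents the models, their assumptions, the tunable parameters and the
numerical choices, and what the synthetic validation does and does not
establish.

## Quantile-rank scoring of the iCMS dichotomy

The iCMS2 and iCMS3 epithelial states are defined by four marker gene
classes: iCMS2_up, iCMS2_down, iCMS3_up and iCMS3_down. Scoring is a
single-sample procedure on gene-level log2 expression:

1. Probe-level data are mean-collapsed to genes (`collapse_probes()`):
   each gene's row is the arithmetic mean of its probes' rows. Probes
   mapping to several genes contribute to each — the common collapse
   behavior; unmapped probes are dropped with a reported count.
2. Within each sample the quantile ranks of **all** genes are computed:
   ascending ranks, ties averaged, divided by the gene count, so values lie
   in (0, 1]. Ranking over all measured genes (not just marker genes) is the
   default; `icms_scores()` accepts any rank matrix, so a restricted-gene
   analysis is a one-line variation.
3. Per class the mean (`Mq`) and sum (`Sq`) of quantile ranks are formed
   over the class genes present in the matrix, and

   $$A = \frac{Mq_{2U}}{Mq_{2D}} - \frac{Mq_{3U}}{Mq_{3D}}, \qquad
     B = (Sq_{2U} - Sq_{2D}) - (Sq_{3U} - Sq_{3D}).$$

Positive values point to iCMS2, negative to iCMS3; the consensus is the
shared call, else `discordant` — mirroring how samples with conflicting
scores are reported rather than forced into a class.

Choices worth making explicit:

* **Rank convention.** Average-tie ranks divided by $n$ keep every $Mq$
  strictly positive, so the ratios in $A$ are always defined. Any strictly
  increasing per-sample transform of the data leaves both scores
  bit-identical (a tested invariant) — the scores are rank statistics.
* **Zero scores.** A score of exactly 0 (e.g., a fully tied degenerate
  sample) is treated as evidence for neither class: the consensus is forced
  to `discordant` and flagged `zero_score`. Silent assignment would
  fabricate a call.
* **Score B and class sizes.** $B$ uses raw rank sums exactly as defined,
  which makes it scale with class sizes when the four classes differ in
  size. A normalized variant (sums divided by class size) is available via
  `normalize_b = TRUE` but is never the default.
* **Missing marker genes** are dropped per class with the coverage fraction
  recorded (attribute `coverage`); an entirely absent class is an error, not
  a silent degenerate score.

## Nearest-template prediction

`ntp_cohort()` complements the scores with a template classifier. The
template space is the union of the four marker classes (intersected with
the matrix, lexicographic order); each class is an indicator template. The
sample profile over these genes is mean-centered — making the distance
invariant to additive shifts in a sample's overall intensity — and compared
by cosine distance $d = 1 - \cos(x, t) \in [0, 2]$, the metric of the
original nearest-template-prediction method; a Euclidean option exists. The
call rule is

* iCMS2 if $D_{2U} < D_{2D}$ and $D_{3U} > D_{3D}$,
* iCMS3 if $D_{2U} > D_{2D}$ and $D_{3U} < D_{3D}$,
* `unstable` otherwise.

The procedure this rule descends from states its second comparison as
$D_{3U}$ against itself — an evident typo read here as $D_{3D}$ on both
lines, the only reading that makes the two constellations symmetric; the
documentation of `ntp_call()` notes this rather than hiding it. All inequalities are strict, so any
equality yields `unstable` — perturbing a tie flips between a class call
and `unstable`, never directly between classes (a tested property). No
permutation-based confidence is attached: the rule is purely
distance-ordering based.

On cohorts where only the sample's own label classes are shifted (see the
generator below), the off-label distance pair is a noise-driven tie, so
roughly half of such samples are — correctly — `unstable`. The agreement
statistic with the score consensus is therefore computed over samples that
both methods classify.

## Model-system analysis

**Filtering.** `anova_filter()` computes a per-feature one-way ANOVA F
across sample groups (vectorized sums of squares; groups need ≥ 2 samples),
Benjamini–Hochberg adjustment across features, and per-contrast log2 fold
changes as differences of group means on log2 data. A feature passes when
`q < fdr` and its |log2FC| exceeds the cut in at least one contrast
(`lfc_rule = "any"`, the default; `"all"` is stricter — the published
phrasing of joint spheroid-vs-2D and xenograft-vs-2D cuts is ambiguous
between the two, so the rule is exposed). The F-test + BH combination is
stated explicitly because the microarray suite originally used for this
filtering documents only "FDR F-test". Passing-set size is monotone
non-increasing in the fold-change cut — the structural analogue of a
152-gene set shrinking to 51 genes under a cut of 2 instead of 1.5.

**Pattern taxonomy.** `pattern_classify()` reduces each gene to its three
system means and two steps (2D→spheroid, spheroid→xenograft) and
thresholds both steps at δ (default 0.25 log2, i.e., ~19% linear change —
small enough to respect genuine plateaus, large enough to ignore replicate
noise; no numeric criterion is published, so δ is a parameter). Categories:
increasing, decreasing, increase-then-plateau, decrease-then-plateau, none;
the "characteristic fraction" is the share of non-`none` genes.

**Similarity and clustering.** `model_similarity()` computes per cell line
the Pearson correlations r(spheroid, xenograft) and r(2D, xenograft) over a
gene set (replicates averaged) and verdicts which in vitro system is closer
to the xenograft. `hierarchical_cluster()` defaults to 1 − Pearson distance
with average linkage (explicit, configurable defaults, since the original
tool's are undocumented) and makes leaf order deterministic by ordering
each merge's subtrees by smallest label; the sample dendrogram is exported
as newick text.

**Marker screen.** `rank_two_group_markers()` ranks genes by
log2FC = mean(A) − mean(B) with the linear fold 2^log2FC alongside, ties
broken by gene id; antisymmetric under group exchange.

## Dose–response analysis

The bioluminescence spheroid assay presumes signal ∝ viable cell mass;
`growth_linearity()` checks this on a day-0 seeded-cell dilution series
(least-squares line, R² gate, default 0.9; at least 3 distinct amounts).

`fit_4pl()` fits the four-parameter logistic
$$R(d) = bottom + \frac{top - bottom}
  {1 + 10^{\,hill\,(\log_{10} d - \log_{10} IC_{50})}}$$
to responses normalized to the untreated (dose 0) mean. IC50 is the
**relative** convention — the curve midpoint, $R(IC_{50}) = (top+bottom)/2$
identically — matching the inflection-point IC50 of common dose–response
software. Numerics: Levenberg–Marquardt least squares (`minpack.lm`) from 7
starting values on a log10-IC50 grid spanning the dose range, best SSE
wins; hill is bounded to [0.05, 10] and log10 IC50 to the dose range ± 3
decades; with fewer than 4 distinct doses, top/bottom are fixed at 1/0.
Dose-0 wells anchor the normalization but cannot enter the logistic (log
dose undefined) and are excluded from the fit. A response that *increases*
with dose triggers a "no inhibition" warning.

The IC50 SD comes from per-replicate curve refits — not from the pooled
fit's covariance — because the replicate-level dispersion is what the
downstream Welch test needs. `compare_ic50()` runs Welch's
unequal-variance t-test on log10 per-replicate IC50s (IC50s are positive
and roughly log-normal) with Welch–Satterthwaite df and a two-sided p; the
default α is 0.05. 2D monolayer IC50s are treated as externally supplied or
simulated curves — the monolayer raw data path is identical.

## The synthetic-data generator

Every stage is validated against generated data with planted truth:

* `simulate_cohort()` — gene-level log2 matrix = baseline (8) + planted
  shift + N(0, σ²). An iCMS2-labelled sample gets +Δ on iCMS2_up genes and
  −Δ on iCMS2_down genes (analogously for iCMS3). Defaults Δ = 1 log2,
  σ = 0.5 log2: a clear but noisy two-fold marker shift, the regime where
  rank scoring is expected to work; Δ = 0 gives the label-blind null.
* `simulate_model_systems()` — a 10-line panel × 3 systems with 152 genes
  planted as 64 increasing / 25 decreasing / 3 increase-plateau /
  18 decrease-plateau / 42 none (characteristic fraction 110/152 = 72.4%),
  step 2 log2 units, plus per-line gene baselines that place spheroids
  between monolayers and xenografts.
* `simulate_two_group()` — a background cohort plus one marker planted at
  8.64 log2 (≈ 400-fold), the magnitude of a dominant resistance marker.
* `simulate_plate()` — 4PL signals with multiplicative Gaussian noise
  (CV 5% default), 8 doses by serial 3-fold dilution from 10 µM plus
  controls, 8 replicate wells, and a day-0 growth series over 150–20,000
  seeded cells. The default truth plants a 0.08 → 0.49 µM IC50 shift
  between the 2D and spheroid condition of one model — the ~6-fold
  magnitude typical of a monolayer-sensitive line losing response as
  spheroids.

Noise is Gaussian on the log2 scale (microarray-like), not count noise.
What passing these tests shows: the formulas, decision rules and fits are
implemented correctly and are recoverable under realistic effect/noise
ratios. What it does not show: performance on real arrays with correlated
genes, batch effects, probe-annotation drift, or murine stromal
contamination of xenograft samples — none of which the generator emulates.

## Pipeline and reproducibility

`run_pipeline()` executes io → scoring → NTP → model-system →
dose–response from one config (R list or YAML), writing per-stage TSVs, a
newick dendrogram and a JSON summary. The single config seed fans out to
stage seeds by fixed offsets; a rerun with the same config is
byte-identical. Existing outputs are not overwritten unless `force`. A
stage failure aborts with the stage name; earlier outputs are retained.

Problem sizes used in the validation suite: 100 random 50×10 matrices for
the scoring oracle, 200-sample planted cohorts, 1000 random p-vectors for
the BH oracle, a 25-point 4PL parameter grid plus 500–1000 noisy-curve
simulations, and 5000–10,000 Welch null replicates — sizes at which every
Monte-Carlo margin in the tests is comfortably stable.

## Known limitations

* The published 749/152/51 probe-set lists and measured IC50 table derive
  from unreleased microarray and plate data; the package reproduces the
  procedures and their structural behavior, not those specific lists.
* Scores attach no significance measure (none is defined for them), and
  NTP confidence is ordering-based only.
* The probe→gene mapping is user input; no annotation database is bundled.
* RMA/CEL preprocessing is upstream and out of scope — inputs are log2
  matrices.
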
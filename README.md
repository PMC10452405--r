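# crcsubtype

Molecular subtyping and dose–response analysis for colorectal cancer (CRC)
preclinical model systems.

Preclinical CRC research increasingly relies on panels of cell lines grown as
2D monolayers, 3D spheroids and mouse xenograft tumors. To know which patient
population such a panel represents, the models must be placed within the
molecular taxonomy of CRC — in particular the two intrinsic epithelial tumor
cell states, iCMS2 and iCMS3, that refine the consensus molecular subtypes
(CMS). And to use the panel for drug testing, spheroid viability must be
quantified with dose–response curves in analogy to classic monolayer assays.
`crcsubtype` implements this full characterization workflow for
transcriptomics (log2 expression matrices) and bioluminescence plate
readouts, plus a synthetic-data generator with planted ground truth so every
stage can be exercised and validated without external data.

## Methods at a glance

**iCMS scoring.** Probe sets are mean-collapsed to genes, and per sample the
quantile ranks `q ∈ (0, 1]` of all genes are computed (average ranks on ties,
divided by the gene count). With `Mq`/`Sq` the mean/sum of quantile ranks
over the four marker classes iCMS2_up (2U), iCMS2_down (2D), iCMS3_up (3U),
iCMS3_down (3D):

    A = Mq2U/Mq2D − Mq3U/Mq3D
    B = (Sq2U − Sq2D) − (Sq3U − Sq3D)

Positive scores indicate iCMS2, negative iCMS3; the consensus is reported
when both scores agree, otherwise the sample is `discordant`.

**Nearest-template prediction (NTP).** Each sample's mean-centered profile
over the union of marker genes is compared, by cosine distance, to the four
class indicator templates, giving distances D2U, D2D, D3U, D3D. The call is
iCMS2 if `D2U < D2D` and `D3U > D3D`, iCMS3 if `D2U > D2D` and `D3U < D3D`,
and `unstable` in every other constellation (including ties).

**Model-system analysis.** Per-feature one-way F-tests across sample groups
with Benjamini–Hochberg FDR and log2-fold-change cuts select
model-system-dependent genes; each gene's trajectory across
2D → spheroid → xenograft means is classified as increasing, decreasing,
increase-then-plateau, decrease-then-plateau or none; Pearson correlations
per cell line decide whether spheroids or monolayers better resemble the
xenograft; hierarchical clustering (1 − Pearson distance, average linkage)
orders samples and genes, with newick export. A two-group fold-change
ranking screens for resistance markers.

**Dose–response.** Bioluminescence signals are normalized to untreated
controls and fitted with the four-parameter logistic
`R(d) = bottom + (top − bottom) / (1 + 10^(hill·(log10 d − log10 IC50)))`
(relative-IC50 convention: `R(IC50) = (top+bottom)/2`), with multi-start
Levenberg–Marquardt least squares; per-replicate refits give the IC50 SD,
and 2D vs spheroid IC50s are compared with Welch's t-test on log10 IC50s.

## Worked example

```r
library(crcsubtype)

sim    <- simulate_cohort(n_genes = 500, class_size = 40, n_per_label = 5, seed = 42)
scores <- score_cohort(sim$matrix, sim$sets)
scores
#> iCMS scoring of 10 sample(s)
#> consensus calls:  iCMS2=5, iCMS3=5, discordant=0
#>     sample_id   score_A score_B consensus
#> 1  s001_iCMS2  7.919847  27.744     iCMS2
#> 2  s002_iCMS2  6.769662  30.562     iCMS2
#> ...
#> 10 s010_iCMS3 -7.728876 -33.112     iCMS3

ntp_cohort(sim$matrix, sim$sets, scores = scores)
#> nearest-template prediction, 10 sample(s)
#> calls:  iCMS2=2, iCMS3=4, unstable=4
#> agreement with score consensus: 1.000

plate <- simulate_plate(cv = 0.05, seed = 42)
fit_plate(plate$plate)
#> dose-response summary (IC50 in uM):
#>   model_id ic50_2D   sd_2D ic50_3D   sd_3D   p_value shifted
#> 1     SW48 0.08711 0.01289  0.4956 0.03416 6.934e-11    TRUE
```

The scores separate the planted iCMS2 and iCMS3 samples with the expected
signs, NTP confirms every sample it classifies (samples whose
off-label distances tie are reported `unstable` rather than guessed), and
the plate fit recovers the planted six-fold IC50 shift (0.08 → 0.49 µM)
between the monolayer and spheroid assay, flagged as significant by the
Welch test.

End-to-end runs are available through `run_pipeline()`, which executes
io → scoring → NTP → model-system analysis → dose–response from a single
(YAML-able) config with one seed, writes per-stage TSVs plus a JSON summary,
and is byte-reproducible for a fixed config.

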
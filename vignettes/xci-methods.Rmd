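---
title: "Methods: XCI status inference and its downstream comparisons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: XCI status inference and its downstream comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

In female somatic cells one X chromosome is silenced (the inactive X,
Xi). The silenced state has two measurable signatures: CpG islands on the
Xi are methylated — so a tumor retaining its Xi shows X-linked island
beta values averaging near one half, the methylated Xi allele diluted by
the unmethylated active-X (Xa) allele — and the Xi is coated by the
*XIST* long noncoding RNA, so *XIST* expression is high whenever an Xi is
present. Copy number supplies a third, disambiguating signal: X-wide
island hypomethylation with low *XIST* can mean either two active X
chromosomes (a segregation-error state that doubles Xa dosage) or a
deletion of the whole Xi (which does not change Xa dosage); only the
segment-level copy-number profile separates these.

`xci_classify()` operationalizes this as a rule-based classifier over
three evidence classes per sample:

* **Methylation class** — mean beta over X-linked CpG-island probes:
  `hyper` (>= `t_hyper`, default 0.35), `hypo` (<= `t_hypo`, default
  0.18), else `partial`.
* **XIST class** — log2(RSEM + 1) of *XIST* against `t_xist` (default
  6.5): `high`, `low`, or `unknown` when expression is unavailable.
* **Arm calls** — per arm (p/q, split at a configurable centromere), a
  copy-number call from the length-weighted mean SEG log2 ratio
  (deleted <= -0.3, gained >= +0.3) and a methylation call (`hypo` when
  the arm's island mean is <= `t_hypo`, requiring >= 5 probes).

The assignment rules: `hyper` evidence is a preserved Xi; `partial` with
high *XIST* is a partially reactivated Xi (Xa+); `hypo` is two Xa —
unless both arms are deleted, which is a whole-Xi loss ("Xa-only") and
reported as preserved-Xi-equivalent with a distinguishing flag because X
dosage is unchanged. A sample whose *selective* arm hypomethylation
(exactly one arm hypomethylated) coincides with a deletion call on the
same arm lost that arm of its **Xi**; its remaining Xi is intact, so it
is reassigned to `preserved_Xi` with `override_applied = TRUE`.
Conflicting evidence (hypo methylation with high *XIST*, or hyper with
low) is resolved by the methylation class and flagged; samples without
expression data are classified by methylation and copy number alone and
flagged low-confidence, since cohorts routinely lack expression for a
large fraction of samples.

Samples are always stratified by histology (endometrioid / serous)
before clustering, because the two histologies occupy different regions
of methylation space and would otherwise dominate the dendrogram.

## Cluster-level versus sample-level assignment

Within each stratum the X-island betas are median-imputed per probe and
clustered by agglomerative hierarchical clustering with complete linkage
on Euclidean distances, cut at `k = 3` — the three expected states. The
clusters are profiled (median member mean-beta, median member *XIST*)
and reported in every fit.

Two assignment modes share the identical rule set:

* `assignment = "cluster"`: the methylation and XIST classes entering
  the rules are the *cluster's*, so all members of a cluster receive the
  same base call and only the arm-deletion override acts per sample.
* `assignment = "sample"` (default): the classes are the *sample's own*.

The default is sample-level, and the reason is geometric. Xi-arm-deleted
tumors sit between the preserved-Xi and Xa+ centroids in methylation
space: one arm at preserved-level methylation, the other at two-Xa
level. For any centromere position, the Euclidean distance from such a
sample to the Xa+ centroid exceeds the distance between the Xa+ and
two-Xa centroids whenever the state means are ordered as here
(0.45 / 0.25 / 0.10). Under complete linkage with `k = 3`, the deletion
cases therefore claim a cluster of their own and force the Xa+ and
two-Xa states to merge; a cluster-level base call then mislabels an
entire state, with a median profile that sits exactly on the
partial/hypo boundary. Sample-level classes are immune to this failure
while producing identical calls whenever the clusters are clean — which
the tests verify by running cluster-level assignment on deletion-free
cohorts. Cluster ids and profiles remain part of every call's evidence
trail in both modes, and every call can be re-derived from its stored
evidence fields alone.

## Thresholds and their defaults

All cutoffs are exposed in `xci_thresholds()` and `xci_arm_def()`; they
are calibration choices (the original group boundaries in this kind of
analysis are drawn by visual inspection of heatmaps), set once against
the synthetic generator's state means and not tuned per dataset:

| parameter | default | units | role |
|---|---|---|---|
| `t_hyper` | 0.35 | beta | mean X-island beta at/above which a sample or cluster is `hyper` |
| `t_hypo` | 0.18 | beta | at/below which `hypo`; also the arm-hypomethylation cutoff |
| `t_xist` | 6.5 | log2(RSEM+1) | high/low XIST split |
| `arm_cnv_cut` | 0.3 | log2 ratio | arm deleted/gained beyond this weighted mean |
| `k` | 3 | clusters | one per expected state, per histology stratum |
| `centromere` | 60 Mb | bp | p/q split of the synthetic chrX |
| `chrom_length` | 155 Mb | bp | chrX extent |

`t_hyper` sits midway between the Xa+ mean (0.25) and the preserved-Xi
mean (0.45); `t_hypo` midway between two-Xa (0.10) and Xa+ (0.25);
`t_xist` midway between the two-Xa *XIST* mean (5.4) and the preserved
mean (7.9). The +-0.3 copy-number cutoff is the conventional arm-level
loss/gain boundary for log2 tumor/normal ratios and is inclusive, so a
weighted mean of exactly -0.3 is called deleted.

## What the synthetic generator emulates

`simulate_xci_cohort()` generates the full input set with known truth:

* **X-island methylation**: per state, probe betas drawn from
  Beta(m·c, (1-m)·c) with state means m = 0.45 / 0.25 / 0.10 and
  concentration c = 50. The Beta family is the natural bounded model for
  beta values and makes state separation a single tunable quantity.
* **Xi arm deletions**: 5% of preserved-Xi samples get one arm (chosen
  at random) re-drawn at the two-Xa mean plus a SEG segment at
  log2 ratio -0.8 spanning that arm, while *XIST* stays high. These
  samples are generated inside the preserved-Xi truth state, so the
  override rule is directly scored.
* **XIST**: log2 expression Normal with state means 7.9 / 8.3 / 5.4 and
  sd 1.0, back-transformed to RSEM.
* **Autosomal islands and CTAs**: autosomal island means decline mildly
  with XCI loss (0.35 / 0.28 / 0.25), and CTA log2 expression is linear
  in (1 - sample mean autosomal beta) with slope 6 and sd 0.5 — CTA
  expression is deliberately coupled to *global* methylation only, not
  to XCI state, so the association stage exhibits exactly the
  confounding structure the classification is meant to expose.
* **Survival**: exponential event times; stage distributions differ by
  state (XCI-loss states skew to higher stage), stage hazard ratios
  4.24 (III) and 7.31 (IV), and a loss-of-XCI hazard ratio of 1.6
  applied to both loss states; administrative censoring uniform on
  1000–4000 days. Stage acts as the confounder, so the stage-adjusted
  Cox model attenuates the marginal XCI effect.
* **Clinical covariates**: age Normal per state (62.2 / 69.8 / 68.9,
  sd ~ 9–11), plus menopause/race/ethnicity/residual drawn from fixed
  cohort-realistic frequencies.

The generator does **not** model per-probe baseline heterogeneity,
array batch effects, probe cross-reactivity, tumor purity, or
allele-specific signals. Passing recovery tests therefore demonstrates
that the pipeline's logic is correct under its stated model of the
three states, not that the thresholds transfer untouched to any real
450K cohort; on real data the thresholds are the knobs a user should
inspect first (e.g. against the `plot()` method's evidence scatter).

## Numerical and degenerate-input choices

* Missing betas are imputed with the per-probe median within the
  histology stratum; probes with no observed value in a stratum are
  dropped with a logged count.
* Clustering sorts samples by id before linkage, so results are
  invariant to input column order; exact merge-distance ties (measure
  zero for continuous betas, but possible in degenerate fixtures) are
  broken by the agglomeration order of the sorted input.
* Arms with less than 50% segment coverage — and samples with no chrX
  segments — are called copy-neutral with a logged warning: absence of
  evidence is not evidence of loss.
* Group comparisons with zero overall variance return p = 1 with a
  degenerate flag rather than dividing by zero; contingency tables with
  a zero margin likewise return p = 1 flagged degenerate.
* The exact r-by-c test uses the conditional (fixed-margins)
  probability-ordering criterion; computation attempts the exact
  network algorithm whenever the total count is at most 1000 or the
  enumerable-table bound is below `mc_threshold`, and otherwise falls
  back to conditional Monte Carlo with a mandatory seed, recording the
  method used. Welch's t-test is used for two-group comparisons
  because group sizes in this setting differ several-fold; classical
  one-way ANOVA for three or more. No multiplicity correction is
  applied by default (per-comparison reporting); `p.adjust` can be
  applied downstream by the user.
* Cox models use Efron tie handling; extreme coefficients (|beta| > 15)
  are flagged as possible separation.

## Problem sizes used in the test suite

The recovery tests run 20 default cohorts (60 samples per
histology-by-state cell, 360 samples, 2600 probes each); the survival
calibration uses 200 replicates of n = 400 with the recovery interval
[1.45, 1.80] for a true hazard ratio of 1.6 (pre-computed empirically
from the same generator) and a null-coverage band of [0.90, 0.99]; test
calibration uses 2000 null replicates against a 0.05 +- 0.02 band. The
exact-test oracle sweep covers every 2x2 and 2x3 table with total count
at most 12.

## Known limitations

* The three-state model assumes female karyotype and a single dominant
  clone; subclonal mixtures of states will land between thresholds and
  surface as conflict flags rather than fractional calls.
* Arm-level copy-number calls use a single weighted mean per arm; focal
  deletions within an otherwise neutral arm are invisible at this
  resolution.
* The override treats p- and q-arm events symmetrically.
* Histology stratification is taken from the clinical table as given;
  mislabeled histology propagates into the stratified clustering.
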
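---
title: "Methods: scoring fibroblast miRNA screens and their downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring fibroblast miRNA screens and their downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirstroma)
```

## Overview

`mirstroma` implements the computational pipeline of an arrayed miRNA-mimic
co-culture screen for fibroblast pro-tumorigenic activity, together with the
downstream analyses such a screen feeds. The biological setting: lung
fibroblasts (cancer-associated or normal) are transfected well-by-well with a
genome-scale library of miRNA mimics, GFP-labelled cancer cells are added,
and automated fluorescence imaging counts nuclei in two channels per well —
GFP-negative fibroblasts and GFP-positive cancer cells. A miRNA that changes
the fibroblasts' paracrine output (secreted growth factors such as HGF)
changes the growth of the co-cultured cancer cells; the screen reads that out
as a per-miRNA relative growth score. Candidate miRNAs are then grouped by
their predicted target genes, the fibroblast secretome is profiled as
percent of control, and functional readouts (dual-luciferase reporters,
wound-closure kinetics, ELISA, cohort statistics) quantify the mechanism.

The pipeline starts from counts: image segmentation is upstream and out of
scope, as are microarray preprocessing and any survival analysis.

## Screen scoring

**Normalization.** Each channel is normalized per plate and screen replicate
relative to the median of the sample wells on that plate:
\(\tilde c_{w} = c_{w} / \mathrm{median}\{c_{w'} : w' \text{ eligible}\}\).
Control wells (non-targeting mimic `miR-C`, `mock`, `untransfected`) are
excluded from the median by default — the median is over *samples* — but a
flag includes them, since the original convention is not fully determined.
For an even number of eligible wells the median is the midpoint of the two
central order statistics, the standard convention. A zero or non-finite
plate median is an error naming the plate and channel; zero counts in
individual wells are allowed and propagate (a well can genuinely kill all
cells). After normalization, the median of eligible normalized values on
every plate is exactly 1 — the suite asserts this at `1e-12`.

**Aggregation.** Libraries carry more entries than unique mature sequences
(the simulated default mirrors 988 entries over 875 sequences), so scores
are aggregated per unique sequence. The default is a flat arithmetic mean
over all wells of all entries sharing the sequence across both screen
replicates — equal weight per measurement. A mean-of-replicate-means option
exists because the original combination rule is not stated.

**Candidate selection and classification.** The `k = 60` smallest and
largest cancer-channel scores form the inhibitory and stimulatory candidate
lists. Ties are broken by effect magnitude \(|\log(\text{score})|\)
(descending) then lexicographic miRNA id, so selection is deterministic and
invariant to row order. Cross-channel classes use strict thresholds
(fold < 0.9 down, > 1.3 up, per channel); boundary values are non-hits.
Channel concordance is a Spearman correlation (average ranks; exact
permutation p for n ≤ 9 without ties, t approximation otherwise).

## Consensus targets and Jaccard clustering

Predicted miRNA–target interactions from six algorithms (DIANA-microT-CDS,
microrna.org, miRDB, PITA, RNA22, TargetScan by default) are integrated by
consensus: a gene is kept for a miRNA iff at least `k_min = 5` distinct
algorithms predict it. Gene identifiers are opaque strings; no cross-database
identifier mapping is attempted. Raising `k_min` can only shrink sets
(tested property). miRNAs with empty consensus are retained, not dropped.

Similarity between two miRNAs is the Jaccard index of their consensus sets,
\(J = |A \cap B| / |A \cup B|\), with \(J(\varnothing, \cdot) = 0\) off the
diagonal and a diagonal fixed at 1 by convention. Hierarchical clustering
uses average linkage. Two row metrics are provided because the source
convention is ambiguous: the default treats the Jaccard matrix itself as the
feature matrix and takes Euclidean distances between its rows; the
alternative uses the \(1 - J\) dissimilarity directly (a metric on finite
sets — the triangle inequality is property-tested). Neither is asserted to
be the original study's exact choice. The flat cut is user-specified
(`n_clusters` or `height`) since no cut criterion is stated for the
published six stimulatory plus five inhibitory clusters; clustering is
applied to candidate lists by convention, with all miRNAs available via the
same functions. Seed families — identical nucleotides 2–8 of the mature
sequence — can be annotated from sequences or a precomputed map, and the
tree exports to Newick with merge heights as branch lengths.

## Secretome percent-of-control

For each of the panel's factors (91 by default: cytokines/chemokines,
MMP/TIMPs, angiogenesis factors), percent of control is
\(100 \times \bar x_{\text{treated}} / \bar x_{\text{control}}\) with means
over biological replicates (triplicates by default). Means rather than
medians: with n = 3 the median discards a third of the information and is
less stable. Whether the original percentages were per-replicate ratios or
this ratio of means is unstated; the ratio of means is the implemented
convention. Factors are flagged `down` below 75% and `up` above 125%,
strictly — a factor at exactly 75% is unchanged. A control mean of zero
makes the factor indeterminate rather than failing the run; factors with no
control arm go to an exceptions report. Below-LOD values substitute LOD/2 by
default (drop and zero policies available); the LOD policy is configurable
because no convention is given upstream.

## Phenotype metrics

**Dual-luciferase.** Per-well firefly/Renilla ratios (Renilla controls for
transfection efficiency) are averaged per condition and divided by the
reference condition's mean ratio, so the reference is 1. Wells with
non-positive Renilla are excluded and logged. The statistic is invariant to
rescaling either channel globally (tested).

**ELISA standard-curve correction.** Standards are fitted with a
four-parameter logistic \(A(x) = d + (a-d)/(1 + (x/c)^b)\) by bounded
Levenberg–Marquardt least squares (`minpack.lm::nls.lm`), initialized from
the standards' extreme absorbances, the geometric-mean concentration, and
slope 1, with \(b > 0\) enforced so the fitted curve is strictly monotone.
Sample concentrations come from inverse evaluation; duplicates are averaged
*after* inversion by default (the 4PL is nonlinear, so the order matters; an
average-absorbance-first option exists). Absorbances outside the standards'
fitted range are flagged and never extrapolated.

**Wound-closure half-time.** T1/2 is the time at which the gap area first
falls to half its initial value, located by linear interpolation between the
bracketing observations. First crossing, not smoothed crossing: it is the
simplest defensible reading of "time at which the gap is reduced to half",
and under noise it errs toward earlier times symmetrically for all
conditions. A series that never reaches half closure is censored at its last
time point, with one carve-out: when the final segment is still decreasing
and its linear projection reaches half within one further sampling interval,
the projected time is reported and marked `extrapolated`. This carve-out
reconciles two natural conventions — short, clearly-closing series should
yield an estimate (a two-point series 100 → 60 over 10 h projects to
12.5 h), while a plateau at 60% of baseline should censor. Censored series
are excluded from downstream regressions by default, with a logged count.

**Linear associations.** Associations such as T1/2 versus HGF concentration
in conditioned medium, or HGF versus FGFR-1 expression restricted to
high-expressing fibroblasts, are ordinary least squares reported as
"R², slope ± SE". The threshold subset rule (`x > threshold`, strict) is a
free parameter since the original units of such thresholds are not given. A
constant response is defined to have R² = 0 (the usual formula is 0/0).

## Cohort statistics

Subgroup summaries are median [IQR] with the linear-interpolation quantile
convention (R type 7), overall and within strata, the layout of a clinical
characteristics table (e.g. miR-16 intensity by smoking status, overall and
within CAF/NF). Two-group comparisons use the Wilcoxon rank-sum test with
average ranks: exact enumeration when both arms have ≤ 8 observations and no
ties, otherwise the normal approximation with tie and continuity
corrections; the mode used is recorded. The switchover at 8 keeps exact
enumeration cheap while covering the subgroup sizes such tables contain.
P-values are reported unadjusted, matching the convention of reporting each
row's test on its own; Benjamini–Hochberg can be applied by the user
(`stats::p.adjust`) and is deliberately not a default. Exposure–analyte
associations use the shared Spearman core with significance reported at the
two-sided 0.05 level.

## The synthetic-data generator

Every pipeline input can be generated with known ground truth, so each stage
is testable without any external download. The generators' defaults are the
study conditions.

* **Screen** (`sim_screen`): 875 unique sequences, 113 duplicate entries
  (988 entries per screen), duplicate screens, 96-well plates with 80 sample
  wells and 4 control wells each (the true plate layout is unpublished, so
  capacity and control placement are free parameters), baselines of 8000
  fibroblast and 3500 cancer nuclei per well. 10% of miRNAs are planted
  inhibitory (fold 0.6–0.9) and 10% stimulatory (1.1–1.4); the two channels'
  effect magnitudes are coupled through a Gaussian copula (correlation 0.35,
  the concordance scale observed in such screens). Well noise is
  multiplicative lognormal with CV 0.1, the scale of imaging-count
  variability — lognormal because counts are strictly positive and the CV
  parameterization is scale-free. Counts are rounded to integers, so a
  noise-free run reproduces planted folds up to count quantization (about 1
  part in 8000), which is why the end-to-end identity test asserts scores at
  `1e-3` and everything unrounded exactly. Duplicate entries are modelled as
  extra wells carrying the parent sequence's true effect, with the mapping
  exposed in the truth table.
* **Predictions** (`sim_predictions`): miRNAs partition into families;
  each family shares a disjoint core target set (30 genes) and each miRNA
  adds 10 private targets; each of 6 algorithms reports true targets with
  probability 1 − dropout and non-targets at the false-positive rate. The
  expected consensus-set size has the closed form
  \(|T| \cdot P[\mathrm{Bin}(6, 1-d) \ge 5]\), which the suite checks to
  within 3 Monte-Carlo standard errors.
* **Secretome** (`sim_secretome`): 91 factors, triplicates per condition,
  26 planted perturbations. A single `effect_range` cannot lie below 75%
  and above 125% simultaneously, so it is interpreted as the envelope:
  perturbed effects are drawn uniformly from [min, 0.75) or (1.25, max],
  half each, and the first perturbed factor is an HGF-like near-depletion
  pinned at the lower bound. Unperturbed factors have effect exactly 1.
* **Wound** (`sim_wound`): linear or logistic gap-closure shapes anchored so
  the noise-free area halves exactly at the planted T1/2 (the logistic uses
  scale T1/2 / 4 with the offset solved in closed form). A horizon shorter
  than the planted T1/2 produces a censored series, flagged rather than
  forbidden — real assays do not always close.
* **Cohort** (`sim_cohort`): two-arm lognormal analyte with specified
  medians; a pack-years-like exposure coupled through a Gaussian copula with
  latent Pearson correlation \(2\sin(\pi\rho_s/6)\), so the planted Spearman
  target is exact for the population. Note the target applies to the latent
  coupling: when the arms' medians differ strongly, the marginal
  exposure–analyte Spearman in the pooled cohort is attenuated by the
  between-arm shift.

What the generator does *not* emulate: spatial plate effects (edge wells),
imaging segmentation errors, correlated prediction-algorithm errors (the six
algorithms err independently here, while real tools share training data),
heavy-tailed analyte outliers, and batch structure across plates. Passing
recovery tests therefore demonstrates the pipeline's correctness and
calibration under the stated noise model, not robustness to those real-data
pathologies.

## Numerical choices and problem sizes

Determinism: every generator is bit-reproducible under a fixed seed; every
selection and merge step has an explicit tie-break. Average-linkage trees are
verified against a naive O(n³) agglomeration oracle; Jaccard entries against
brute-force set arithmetic; exact Wilcoxon and Spearman p-values against
exhaustive enumeration; OLS against the closed-form normal equations at
`1e-10`. Calibration checks run at desk scale chosen to keep the full suite
around a minute of simulation per property: 100 screens of 875 miRNAs for
hit recovery (≥ 50 of the planted inhibitors in the top 60, in ≥ 95% of
runs), 200 prediction universes of 120 miRNAs in 11 families for cluster
recovery (adjusted Rand index ≥ 0.9 in ≥ 90% of runs), 2000 null Wilcoxon
draws (rejection rate in [0.03, 0.07] at α = 0.05), and 500 null secretome
panels (false-flag rate ≤ 5% at CV 5%).

## Known limitations

* The clustering metric that exactly reproduces the published cluster tables
  cannot be determined from the text; both implemented metrics are exposed
  and the default is documented, not asserted.
* Published headline values (candidate tables, the 26/91 perturbed factors,
  the reported correlation and regression coefficients) were computed on
  raw screen, multiplex and cohort data that are not distributed; this
  package reproduces the *procedures* and validates them on planted
  synthetic truth, using those published values as shape references only.
* `percent_of_control` treats replicates as exchangeable; paired designs
  would need a per-replicate-ratio variant (exposed as an open option, not
  implemented).
* The 4PL inversion averages duplicates after inversion; absorbance-first
  averaging changes results for curved regions and is available explicitly.
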
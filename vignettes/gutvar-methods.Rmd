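---
title: "Methods: variability analysis of defined gut communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variability analysis of defined gut communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutvar)
```

This vignette documents the models and procedures implemented in
`gutvar`, the assumptions behind them, the tunable parameters and their
defaults, and the design decisions taken where more than one reasonable
choice existed.

## The measurement problem

A defined community of gut anaerobes is grown in six replicate
microbioreactor vessels: 12 h of batch growth, then an emulated chemostat
in which continuous feed replaces the medium completely in 24 h, giving a
dilution rate D = 1/24 h⁻¹. Samples at 12, 25, 37, 49, 61 and 67 h are
measured three ways: HPLC for metabolites, flow cytometry for total cell
densities and (via supervised classification) species-resolved counts,
and 16S rRNA gene sequencing in three technical replicates.

Vessel-to-vessel spread conflates biological variability with the noise
of each assay. The package's core statistic is the coefficient of
variation across vessels, computed per timepoint and variable, organised
into tables, aggregated, and compared between methods with a paired
test. If a method's CV distribution sits systematically above another's
on the same cells, that excess is technical.

## Event classification

Flow events carry 23 parameters (forward/side scatter area, height and
width, plus fluorescence detectors). Two gating variants separate cells
from debris:

* threshold gating: keep events with FL1-A strictly above 3.5·10³ — the
  gate used for total counts of SYBR-stained samples against a medium
  blank;
* machine gating: six binary random forests trained on monoculture
  (cell) versus blank (debris) events; an event is kept when a majority
  (⌈6/2⌉ = 3) votes "cell". The vote cut-off is configurable because the
  combination rule for the six gating classifiers is not prescribed
  anywhere; majority is the neutral choice.

Species assignment uses ten multiclass random forests, each trained on an
independent random draw of 5000 events per gated monoculture, split
6/7 : 1/7 into training and test (5000 → 4286/714; the general rule
`n_test = floor(n/7)` reproduces those printed sizes). Members differ
only in their sampling/training seed. An event is assigned to the modal
species of the ten votes when that species has at least 7 votes,
otherwise it is `unknown`. With a threshold above half the members a tie
at or above threshold is impossible; for configured thresholds ≤ 5 a tie
yields `unknown`. Forests default to 100 trees, unlimited depth, and raw
channel values (no transform) — trees are invariant to monotone
per-channel transforms, so a log transform is offered only as a
convenience and is off by default.

Accuracy is reported two ways: excluding unknowns (correct / classified)
and strictly (correct / total). The in-silico community assembler mixes
gated monoculture events at chosen proportions (`floor(p·n)` per species,
remainder to the largest proportion) and keeps the hidden truth labels so
both numbers and the full confusion matrix can be computed.

## From counts to abundances

Total density is volumetric: N = (events/μl) · dilution · 1000 cells/ml,
with the acquisition volume taken from the FCS `$VOL` keyword (stored in
nl) or supplied as metadata — acquisition volumes are sample-specific
and are therefore never defaulted silently.

Sequencing counts pass through three steps, in this order: contaminant
filtering, copy-number correction, scaling. In a defined community,
non-member taxa are assumed to be pipeline contaminants and dropped —
unless they appear (count > 0) in two or more samples across the
experiment, in which case they are kept as genuine. Filtering before
correction is assumed; the two orders only differ when a dropped taxon
lacks a copy number, and filtering first avoids demanding copy numbers
for discarded contaminants. Counts are divided by per-species 16S copy
numbers and renormalised (scale-invariant per sample), then multiplied by
N. All-zero samples are flagged and dropped rather than propagated as
NaN. The shipped copy-number table is synthetic (file name says so):
strain-exact values should come from rrnDB for real data.

## Variability statistics

`coefficientOfVariation` uses the sample SD (ddof = 1) by default. The
choice matters for cells where only one vessel had a non-zero detection
among k detected vessels: with ddof = 1 and five detected vessels the CV
is exactly √5 ≈ 2.2360680, a value that recurs in published CV tables;
with ddof = 0 the same value arises from six vessels. Since the two
readings cannot be distinguished from printed tables, ddof is a
parameter. Cells with fewer than two vessel values, or a zero mean, are
missing, and aggregation (row, column, grand means) ignores missing
cells; an exclusion list removes inconsistently detected taxa from the
margins, mirroring "average without contaminant" columns.

The paired Wilcoxon signed-rank test pairs two methods' CV tables on
their shared (timepoint, variable) cells — the intersection is used
because the exact cell set behind the published comparison is not
recoverable. Zero differences are dropped (Wilcoxon's original
treatment; Pratt's variant is a flag). Tied absolute differences get
average ranks, the standard treatment. Up to 25 non-zero pairs the null
is exact — the distribution of the positive-rank sum over all 2ⁿ sign
assignments, computed by dynamic programming over doubled (hence
integer) ranks; beyond that a normal approximation with tie-corrected
variance Var(W⁺) = Σrᵢ²/4 and a 0.5 continuity correction is used. The
two-sided p is min(1, 2·min(P(W⁺ ≤ w), P(W⁺ ≥ w))).

Population heterogeneity of a gated sample is the per-channel range
(max − min over events), averaged over channels by default; the
sum-over-channels variant — the two differ exactly by the factor 23 on
the default panel — is selectable and outputs are labelled with the
variant, because both readings of "mean range" are defensible.

## Ordination

Bray–Curtis dissimilarity d(i,j) = Σ|xᵢ−xⱼ| / Σ(xᵢ+xⱼ) feeds classical
(Torgerson) scaling: double-centre −½JD²J, eigendecompose, scale
eigenvectors by √λ. No Lingoes/Cailliez correction is applied; negative
eigenvalues are reported and their axes dropped. Environmental vectors
are least-squares fits of a variable on the ordination axes; r² is the
squared multiple correlation, the direction the normalised coefficient
vector, and significance comes from permuting the variable across
samples, p = (1 + #{r²_perm ≥ r²})/(1 + n_perm) with 999 permutations by
default. Fitting uses 2 axes by default (the plotted ones); more can be
requested.

## The synthetic-data generator

The generator exists so every stage can be tested against known ground
truth; its defaults mirror the study design.

**Event clouds.** Species are multivariate log-normal over the 23
channels with diagonal log-scale covariance (log-sd 0.3): flow data are
positive and right-skewed. Each species' mean is shifted from a common
baseline along its own pair of channels, because real species differ
strongly on a few informative detectors rather than diffusely on all;
magnitudes are set so the closest species pair sits exactly at the
nominal Mahalanobis `separation` (default 4, i.e. closest-pair optimal
error Φ(−2) ≈ 0.023) and farther pairs 15% per species index beyond it —
real panels are irregular, not perfect simplices. Debris sits 2.5 log
units below the baseline with twice the spread.

**Trajectories.** Batch phase: exponential growth at per-species rates
(0.30–0.50 h⁻¹, plausible for gut anaerobes) from an inoculation density
of 5·10⁵ cells/ml per species. Chemostat phase: exponential relaxation
towards a per-species steady state at rate D,
x(t) = K + (x(12) − K)e^(−D(t−12)). This is deliberately
phenomenological: no mechanistic growth model is published for this
system, so none is invented — except washout, which is physically
forced: a species that cannot grow in chemostat mode has K = 0 and
decays exactly as e^(−D(t−12)), i.e. to e⁻¹ of its 12 h density at 36 h.
Steady states (1.5–6·10⁸ cells/ml) give late-experiment totals around
10⁹ cells/ml, typical for dense anaerobic cultures.

**Noise structure.** Every (vessel, timepoint, species) density carries
an independent log-normal multiplier with σ_bio = 0.15 — the biological
vessel-to-vessel spread. Sequencing adds, per (sample, replicate,
taxon), an independent log-normal technical factor with σ_tech = 0.5,
plus a batch component (σ_batch = 0.25) shared by replicates 2 and 3 of
the same sample to mimic replicates processed together being more
similar. The technical factor is redrawn per sample — a factor shared
across vessels would cancel in across-vessel CVs and could not model
technical inflation of those CVs at all. σ_tech > σ_bio encodes the
qualitative finding the scenario is built to exhibit (sequencing
variability above biological variability); the magnitudes are chosen for
that ordering, not to reproduce any specific published table, whose raw
vessel data are not available. Counts are multinomial at depth 10⁴ with
expected shares ∝ density × copy number.

**Metabolites.** Three templates cover the observed shapes: substrates
depleted by the end of batch (glucose, trehalose), intermediates that
peak at 12–25 h and decay to a plateau (formate, pyruvate, succinate,
lactate), and end products rising monotonically to a plateau (acetate,
propionate, butyrate, isovalerate), each with small (σ = 0.05)
multiplicative vessel noise.

**What the generator does not emulate.** Real monoculture contamination
(the scenario's monocultures are clean, so the training-timepoint
workaround real data required is unnecessary), instrument drift,
compensation/spillover, pH and gas dynamics, mechanistic cross-feeding,
and ASV-level sequencing artefacts. Tests passing on synthetic data
therefore validate the statistical machinery and its contracts, not the
biology of any particular real dataset.

## Numerical choices and degenerate inputs

* Exact Wilcoxon null via subset-sum DP (O(n·Σr) instead of 2ⁿ); the
  test suite checks it against full enumeration for n ≤ 12.
* Permutation p-values use the add-one formula, never 0.
* CV cells: missing (never imputed) when < 2 vessels or zero mean;
  all-zero count samples are dropped with their ids recorded.
* Bray–Curtis of two all-zero samples is undefined; set to 0 with a
  warning.
* PCoA requests beyond the positive-eigenvalue rank are truncated with a
  warning.
* Vote ties at or above threshold (only possible for thresholds ≤
  members/2) are `unknown`; random-forest tie-breaking in prediction is
  given a fixed seed so classification is bit-reproducible.
* All generator functions take explicit integer seeds; the pipeline
  derives per-stage substreams from one root seed and reruns are
  byte-identical.

## Problem sizes

The default pipeline configuration trains 10 forests on 2000 events per
species and classifies 36 community samples of ~3000 events each (about
half a minute on one core); the classifier benchmark in the test suite
uses the full 5000-event draws. The envfit calibration uses 1000
simulated gradients with 99 permutations each. These sizes give
Monte-Carlo error well inside every asserted tolerance while keeping a
full check run comfortably short.

## Known limitations

Classification does not model cell-state drift between the monoculture
training data and community samples — on real data this biases
abundances in ways the synthetic scenario cannot reveal. The
contaminant rule ("seen in ≥ 2 samples") is a heuristic whose scope
(experiment-wide) is configurable but still coarse. The chemostat
relaxation model is descriptive, not predictive. And the Wilcoxon
comparison treats CV cells as exchangeable pairs, ignoring correlation
between cells that share a timepoint or species.
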
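---
title: "Predicting model-building pipeline performance from map features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting model-building pipeline performance from map features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbperf)
```

## The prediction problem

Automated model building turns an electron-density map into an atomic
protein model. Several mature pipelines exist — ARP/wARP, Buccaneer, Phenix
AutoBuild and SHELXE — and they can be run individually, chained in ordered
pairs (the first pipeline's model seeds the second), or preceded by Parrot
density modification. Their relative performance varies strongly between
data sets, and each run is expensive. `mbperf` treats pipeline choice as a
per-instance regression problem: from features of the *starting* data,
predict the quality of the structure each variant would build, and
recommend the best-predicted variant.

Three quality measures are modelled. Structure completeness is computed by
this package (see below); R\_work and R\_free are produced by refinement and
are ingested as plain numbers — recomputing them is out of scope.

## Features

Six per-dataset predictors are used, all cheap to obtain before any model
building:

| feature | units | meaning |
|---|---|---|
| resolution | Å | data-set resolution, taken from user metadata |
| r.m.s.d. | map units | `sqrt(mean((v - mean(v))^2))` over all grid samples |
| skew | map units³ | `mean((v - mean(v))^3)`, asymmetry of the density histogram |
| max density | map units | highest grid value |
| min density | map units | lowest grid value |
| sequence identity | fraction | MR search-model identity, ingested (computed upstream by superposition) |

Numerical conventions, each a deliberate choice:

* statistics run over **all grid points** of the stored map — no masking or
  asymmetric-unit reduction. No masking rule is implied by the method, and a
  consistent convention is what matters to the downstream learner, which is
  insensitive to monotone reparameterizations of its inputs;
* **population (divisor N)** moments, not the n−1 sample correction;
* skew defaults to the **scale-dependent** raw third moment; a standardized
  (divided by rmsd³) mode is available via `density_skew(standardized =
  TRUE)`, which errors on constant maps where it is undefined;
* sequence identity must be supplied exactly when `phasing_mode = "MR"`;
  supplying it for experimental phasing is rejected outright to catch
  pipeline wiring mistakes early.

Maps are read and written in CCP4/MRC format (modes 0/1/2 read, mode 2 —
32-bit float — written). Unreadable files, truncated data blocks and
header/data size mismatches raise distinct condition classes.

## Structure completeness

Completeness is the fraction of residues of the deposited (reference) model
reproduced in the built model: a deposited residue counts as reproduced when
a built residue has the same 3-letter residue type and a Cα–Cα distance
*strictly below* 1 Å (the cutoff is configurable). Matching is one-to-one,
assigned greedily in ascending distance order. Conventions and their edge
cases:

* deposited residues without a Cα are excluded from the denominator — the
  criterion is undefined for them; an empty built model scores 0 (not an
  error), while a deposited model with no Cα at all is an error;
* residue types are compared verbatim (`MSE` ≠ `MET`); no modified-residue
  table is applied;
* models are assumed to share a crystal frame: no superposition is performed
  before matching;
* altloc Cα positions collapse to the highest-occupancy location, ties going
  to file order.

Greedy matching can in principle differ from the optimal bipartite matching,
but only if some built Cα lies within the cutoff of two deposited residues,
which requires two deposited Cα less than 2 Å apart — geometrically excluded
in real protein models, where consecutive Cα sit ~3.8 Å apart. On
physically valid inputs greedy matching provably attains the optimal match
count; the test suite verifies this against an exhaustive augmenting-path
oracle on randomized protein-like instances (spacing ≥ 3.5 Å, displaced
copies straddling the cutoff, wrong-type residues, decoys and duplicate
builds). Degenerate sub-2 Å spacing is the one regime where the greedy count
could be suboptimal.

## The regressor suite

One bagged regression forest is trained per applicable (variant, measure)
cell: `fit_suite()` returns a `suite_matrix` with `print`, `summary` and
`predict` methods. Defaults follow the reference configuration: **1024
trees**, **unlimited depth**, **bagging on**; the forest engine is `ranger`,
with its regression default for per-tree feature subsampling
(`mtry = floor(sqrt(p))`) — tree internals are treated as a statistical
contract, not a bit-level one. Each cell derives its own training seed
deterministically from the suite seed, so refitting is reproducible.
Forest predictions are means of tree predictions and therefore bounded by
the training outcome range; completeness predictions are additionally
clamped to [0, 1] to document the bound.

The default experimental-phasing registry has 24 variants — 4 individual
pipelines, 12 ordered pairs, and 8 Parrot-preconditioned variants — and the
MR registry the 4 individual pipelines (pairs were only run for
experimental phasing). R\_free is inapplicable to the refinement-free
individual variants (ARP/wARP and SHELXE alone, with or without Parrot), so
the default registries yield 69 and 10 cells. Only the four individual
pipelines and the refinement rule are fixed by the method; the exact
composition of the Parrot subset is a reconstruction chosen so that exactly
three registry variants drop R\_free, and it is user-overridable — any list
of `pipeline_variant()` objects works.

The **Zero-R baseline** predicts the training median (even counts: mean of
the two middle values) regardless of features; model skill is always
reported side by side with it as MAE and RMSE. The 80/20 split
(`split_dataset`) is a plain random partition by dataset id with
`round(0.8 n)` training sets — no stratification, single split — with the
seed recorded in the suite metadata.

## Prediction intervals

Uncertainty is estimated from **out-of-bag residuals**: for each training
row, the observed outcome minus the mean prediction of only those trees
whose bootstrap excluded that row (rows never out-of-bag are skipped; with
bagging disabled the package falls back to 10-fold cross-validated
residuals and says so). A Gaussian-kernel density with Silverman's
rule-of-thumb bandwidth (`stats::bw.nrd0`) is fitted to the residual set,
and the interval is the point prediction plus the central `confidence`
quantile range of that density, obtained by numerically inverting the
mixture CDF. Choices worth recording:

* the confidence level is not fixed by the method description; **0.95** is
  the default and it is a parameter everywhere;
* one residual distribution per cell (homoscedastic): interval widths vary
  across variants and measures, not across input maps. Input-conditional
  intervals (quantile-regression forests, conformal methods) are
  deliberately out of scope;
* degenerate residual sets (zero spread) fall back to a bandwidth floor of
  1e−6, with a minimum interval width of twice the floor;
* at least 10 residuals are required — below that a kernel quantile is
  meaningless.

Intervals may be asymmetric about the point when residuals are skewed; the
invariants that do hold are positive width, monotonicity in the confidence
level, and translation equivariance in the point.

## Ranking, grouping, recommendation

Variants are sorted by ascending interval width — most trustworthy
prediction first — with ties broken by the better point prediction (higher
completeness, lower R factor), then variant id. The "no more than 5%
difference in width" grouping is interpreted as **relative to the group
anchor** (the narrowest width in the group) with **greedy anchored**
semantics: a record joins the current group while its width ≤ anchor × 1.05,
otherwise it opens a new group and becomes the anchor. Anchoring prevents
the unbounded drift transitive chaining would allow; an absolute-difference
mode is available behind `relative = FALSE`. Both readings of the rule are
implemented because the method statement does not disambiguate them.

`recommend()` uses point predictions only — the grouping communicates
confidence but does not veto the recommendation; ties go to the narrower
interval, then the id, making the result invariant to input order.

## Evaluation protocol

`compare_to_baseline()` fills per-cell MAE/RMSE for model and baseline;
`ablation()` retrains the suite with one feature removed at a time (same
seeds) and reports ΔMAE/ΔRMSE; `resolution_binned_stats()` reports per-bin
(default 0.1 Å) mean and SD — sample convention, n−1 — of predicted and
actual outcomes; `group_hit_rate()` checks whether the variant with the
lowest prediction error (|predicted − actual|; the best-actual-outcome
variant behind a flag) lands in the first group; `within_k_analysis()`
reports the cumulative fraction of datasets whose recommended variant's
actual outcome is within k of the best variant's. Rows with missing
outcomes are excluded with a logged count. Wall-clock and inference-time
comparisons are excluded as hardware-dependent.

## The synthetic data generator

All tests and the acceptance study run on synthetic fixtures with known
ground truth:

* `make_synthetic_map()` — Gaussian blobs at random positions plus white
  noise. It emulates the *statistics* a real map exhibits (positive skew
  from peaked density, rmsd tracking the noise level) but not the physics:
  no structure factors, no Fourier synthesis, no symmetry.
* `make_model_pair()` — a deposited model on a jittered path with ≥ 3.5 Å
  Cα spacing and a built model reproducing a known fraction (displaced
  copies, wrong-type residues, omissions), so the true completeness is known
  by construction. Fractions quantize to whole residues; the realized
  fraction is returned.
* `make_outcome_table()` — features sampled parametrically (resolution
  uniform on 1.0–4.0 Å; skew decaying with resolution; sequence identity
  uniform on 0.2–1.0 for MR) and per-variant outcomes as a response function
  plus Gaussian noise (default σ: 0.05 for completeness, 0.02 for R
  factors), clamped to the valid range, with the noiseless truth returned
  alongside. The default response makes completeness a per-variant logistic
  in resolution — high below ~2 Å, collapsing toward 3.5–4 Å — with
  secondary skew and sequence-identity effects, and R factors rising with
  resolution. Response functions, feature samplers and noise levels are all
  part of the generator specification, not hard-coded.

Everything is bit-reproducible given a seed. What passing tests on these
fixtures shows is that the machinery — feature extraction, training,
intervals, ranking, the evaluation protocol — is correct and calibrated
under a known generative model. What they cannot show is real-world
predictive accuracy: real maps, real pipeline behaviour and real corpora
(the published training sets comprise 1203 experimental-phasing and 1332 MR
data sets plus recent depositions) are not shipped here, and the headline
accuracy figures reported for those corpora are not reproducible from
synthetic data.

## Problem sizes

The shipped test suite and the acceptance script choose sizes that make the
statistical checks sharp while staying desk-scale: single-cell learning
checks at 200–2000 datasets, interval-calibration and learner-vs-baseline
checks at 2000, ablation at 400 × 10 seeds, the end-to-end study at 300
datasets over the full 24-variant registry (69 cells, 1024 trees each), and
map-statistics oracles at up to 10³ voxels × 100 maps.

## Known limitations

* Homoscedastic intervals: a variant's interval width is constant across
  datasets, so the ranking of variants by certainty does not react to how
  unusual an individual map is.
* The completeness metric assumes the built and deposited models share a
  frame; there is no superposition step, and origin/symmetry ambiguities
  must be resolved upstream.
* The registry beyond the four individual pipelines and the refinement rule
  is configuration, not ground truth.
* The generated per-variant shell scripts carry placeholder invocations:
  pipeline command-line syntax varies across versions, and the templates
  (`inst/templates/*.sh.in`) are data files meant to be edited, never
  executed by this package.
* Multi-task learning across measures and gradient-boosting engines are
  known directions deliberately not taken here; each cell is trained
  independently.
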
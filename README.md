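# mbperf

Performance prediction and uncertainty-aware ranking for crystallographic
model-building pipelines.

## The problem

After phasing a macromolecular crystallography data set — by experimental
phasing or molecular replacement (MR) — a crystallographer chooses among
several automated model-building pipelines (ARP/wARP, Buccaneer, Phenix
AutoBuild, SHELXE), run individually, in ordered pairs where the first
pipeline's model seeds the second, or preconditioned with Parrot density
modification. Each variant can take hours to days, and which one will build
the best model for a given map is not obvious in advance. `mbperf`
predicts, *before any pipeline is run*, how well each variant will perform,
together with a prediction interval expressing how much that prediction can
be trusted, and recommends the best-predicted variant.

## The method

Each data set is summarized by six cheap map/metadata features

> x = (resolution, r.m.s.d., skew, max density, min density, sequence identity)

where r.m.s.d. is the root-mean-square deviation of the electron density
about its mean, skew is the third moment about the mean (a peaked,
signal-bearing density histogram has positive skew), the extrema are the
highest and lowest grid values, and sequence identity (MR only) is the
ingested identity of the search model. Three evaluation measures are
predicted per variant v:

* **structure completeness** — the fraction of deposited-model residues
  reproduced in the built model (same residue type, Cα–Cα distance < 1 Å,
  one-to-one matching);
* **R_work** and **R_free** — refinement agreement statistics, ingested as
  numbers (R_free is undefined for variants whose final stage performs no
  refinement: ARP/wARP or SHELXE run individually, with or without Parrot).

For every applicable (variant, measure) cell a bagged regression forest
f_{v,m}(x) (1024 trees, unlimited depth) is trained on an 80/20 split of the
corpus — 69 regressors for the default experimental-phasing registry of 24
variants and 10 for the MR registry of 4. Accuracy is judged by MAE/RMSE
against a *Zero-R* baseline that always predicts the training median.
Prediction uncertainty comes from a Gaussian-kernel density fitted to each
cell's out-of-bag residuals: the central 95% quantile range of that density,
placed around the point prediction, is the prediction interval. Variants are
reported in increasing interval width, with variants whose widths differ by
no more than 5% grouped together, and the variant with the best predicted
value of the chosen measure is recommended.

## Worked example

```r
library(mbperf)

## map features for one data set
m  <- make_synthetic_map(n_atoms = 30, cell_edge = 25,
                         grid_shape = c(48, 48, 48), noise_sigma = 0.15,
                         seed = 7)
extract_features(m, resolution = 2.3, phasing_mode = "experimental")
#>   resolution      rmsd        skew max_density min_density
#> 1        2.3 0.1664474 0.002975368    1.456611  -0.6143867

## train the MR suite on a synthetic corpus and rank variants for a new set
reg  <- default_registry("MR")
gen  <- make_outcome_table(outcome_generator_spec("MR"), n_datasets = 200,
                           registry = reg, seed = 7)
sp    <- split_dataset(gen$data, 0.8, seed = 7)
suite <- fit_suite(sp$train, reg, "MR", forest_config(seed = 7))
suite
#> suite_matrix (MR phasing): 10 regressors over 4 variants
#>   forest: 1024 trees, bagging on; features: resolution, rmsd, skew,
#>   max_density, min_density, sequence_identity

new   <- gen$features[gen$features$dataset_id == sp$test$dataset_id[1], ]
preds <- predict(suite, new)
ranked_report(preds[preds$measure == "completeness", ])
#> ranked_report for completeness (tolerance 0.05, relative)
#>  group 1:
#>    arpwarp        point 0.986  width 0.250  <- recommended
#>  group 2:
#>    shelxe         point 0.963  width 0.267
#>  group 3:
#>    autobuild      point 0.958  width 0.284
#>    buccaneer      point 0.970  width 0.288
```

The report lists variants from most to least certain prediction (ascending
interval width); near-ties in width share a group, and the variant with the
best predicted completeness is flagged. Here all four variants are predicted
to build a nearly complete structure for this easy (high-resolution) set,
with ARP/wARP both best-predicted and most-certain.

Scoring a built model against its deposited reference:

```r
pair <- make_model_pair(n_residues = 50, match_fraction = 0.8,
                        displacement = 0.4, seed = 1)
structure_completeness(pair$built, pair$deposited)
#> structure completeness: 0.800 (40 of 50 deposited residues, cutoff 1 A)
```

A command-line front end covering the same operations
(`extract-features`, `completeness`, `train`, `predict`, `rank`,
`evaluate`, `fixtures`, `gen-scripts`) is installed at
`system.file("cli", "mbperf.R", package = "mbperf")`.

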
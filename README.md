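# otolrp

Explaining convolutional age predictions from fish otolith images, at desk
scale.

Fisheries institutes estimate fish age by reading annual growth zones in
otoliths (ear stones); convolutional networks can predict age from otolith
images, but their adoption hinges on understanding *which* image features
they use. `otolrp` is an R package for researchers who want to interrogate
such models end to end: it trains small, fully introspectable
convolutional classifiers on three variants of otolith imagery — the
original image (**baseline**), a silhouette with all structure removed
(**binary**), and a size-normalised version (**standardized**) — and then
explains and summarises their decisions.

Because no public otolith image collection with read ages exists for the
target species, the package ships a tested synthetic generator emulating
Greenland-halibut-like otolith growth: near-circular juveniles with a large
bright nucleus, increasingly asymmetric anterior growth with lobed
"fingers" at older ages, faint annual rings, and overall size increasing
with age. Real images can enter through the same PNG + CSV manifest
interface.

## The methods at the core

* **Layer-wise relevance propagation (LRP).** The logit of the explained
  class, `R_f = x_f`, is redistributed backwards layer by layer under the
  αβ-rule:

  ```
  R_i = Σ_j ( α (a_i w_ij)⁺ / Σ_i (a_i w_ij)⁺  −  β (a_i w_ij)⁻ / Σ_i (a_i w_ij)⁻ ) R_j ,   α − β = 1, β ≥ 0
  ```

  with α=1, β=0 as the default (activating contributions only). The
  relevance total is conserved at every layer boundary for bias-free
  networks, and `audit_conservation()` reports any leakage.

* **Spectral relevance analysis (SpRAy).** Relevance maps are cropped to
  the otolith contour, resized, and sum-pooled to 56×56 descriptors; a
  k-nearest-neighbour affinity graph (k = ⌈ln n⌉) feeds normalized-
  Laplacian spectral clustering into 2 clusters per pair of consecutive
  age groups (juveniles 1–4, adolescents 5–9, young adults 10–13, adults
  14–26); cluster-vs-group agreement is scored by best-matching F1 and
  visualised by a seeded t-SNE on graph distances.

* **Age-reading precision.** Model-vs-reader agreement via RMSE and the
  standard two-reading coefficient of variation
  `CV = 100·(|a−b|/√2)/((a+b)/2)`, averaged per age group after 1.5×IQR
  outlier exclusion (interpolated quartiles).

## Worked example

```r
library(otolrp)

report <- run_experiment(default_config(seed = 1), out_dir = "otolrp-run")
print(report)
```

The default configuration generates ages 1–9 (30 otoliths per age, 56 px
canvas), trains one miniature VGG-style classifier per image variant,
explains every prediction with LRP-α1β0, clusters the juvenile+adolescent
relevance maps, and summarises agreement. With seed 1 it prints:

```
<experiment_report> 810 samples, variants: baseline, binary, standardized
RMSE by variant/split:
       variant split   n      rmse
1     baseline  test  54 0.7328281
2     baseline train 216 0.2635231
3       binary  test  54 1.3810892
4       binary train 216 0.6236096
5 standardized  test  54 0.5931710
6 standardized train 216 0.2041241
Cluster-recovery F1 by pair/variant:
       variant                pair   n        f1 p_value
1     baseline juvenile+adolescent 270 0.8287293   0.005
2 standardized juvenile+adolescent 270 0.8670520   0.005
```

Reading these numbers: the silhouette-only (binary) model is roughly twice
as far from the reader as the baseline model (test RMSE 1.38 vs 0.73
years) — and the damage concentrates in juveniles, whose ageing cue is the
bright nucleus that binarisation erases (juvenile test CV: 33.3% binary
vs 0% baseline in `report$cv`). Relevance-map clusters separate juveniles
from adolescents far better than a permutation null (F1 ≈ 0.83–0.87,
p = 0.005), and the standardized variant separates slightly better than
baseline. Individual objects are inspectable throughout, with broom-style
`tidy()`/`glance()` and `autoplot()` methods:

```r
glance(report$models$baseline)      # parameters, final loss/accuracy
autoplot(report$cv)                 # CV bubble chart by group and variant

s <- generate_dataset(1, ages = 6, canvas_size = 56, seed = 2)$train[[1]]
m <- compute_relevance_map(report$models$baseline, s$image, normalize = TRUE)
autoplot(m)                         # white-to-red per-pixel relevance
```

A shell entry point with per-stage subcommands
(`generate | train | explain | cluster | metrics | report | run-all`)
lives at `inst/scripts/otolrp`:

```sh
Rscript inst/scripts/otolrp run-all --config config.yaml --out results/
```

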
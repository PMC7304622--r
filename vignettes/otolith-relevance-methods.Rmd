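---
title: "Methods: explaining convolutional age reading of otolith images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explaining convolutional age reading of otolith images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Fish age is routinely estimated by reading annual growth zones in otoliths
(ear stones). Convolutional networks can predict age directly from otolith
images, but fisheries scientists need to know *what* such a model looks at
before trusting it. `otolrp` packages the full explanation workflow at desk
scale:

1. a synthetic otolith generator emulating Greenland-halibut-like growth in
   three image variants — **baseline** (full image), **binary** (silhouette:
   all otolith pixels set to one), **standardized** (background zeroed and
   vertical size normalised);
2. a small, fully introspectable convolutional classifier over 26 possible
   age classes;
3. layer-wise relevance propagation (LRP) under the \(\alpha\beta\) rule,
   producing per-pixel relevance maps for each prediction;
4. spectral relevance analysis: 56×56 sum-pooled heatmap descriptors,
   a k-nearest-neighbour affinity graph, spectral clustering into two
   clusters per pair of consecutive age groups, t-SNE visualisation, and
   best-matching F1 to quantify how well relevance patterns separate the
   groups;
5. agreement statistics between "reader" (the generative age) and model:
   RMSE and the mean age-reading coefficient of variation
   \(\overline{CV}\) per age group, with 1.5×IQR outlier exclusion.

# The relevance model

A forward pass through a stack of conv / ReLU / max-pool / flatten / dense
layers produces logits; the logit \(x_f\) of the explained class is taken
as the total relevance \(R_f\) and redistributed backwards. Between two
layers, the message from output unit \(j\) to input unit \(i\) is

\[ R_{i \leftarrow j} = \frac{q_{ij}}{\sum_i q_{ij}} R_j, \qquad
   R_i = \sum_j R_{i \leftarrow j}, \]

where the contribution \(q_{ij}\) is formed from the positive and negative
parts of \(a_i w_{ij}\) under the \(\alpha\beta\) rule
(\(\alpha - \beta = 1\), \(\beta \ge 0\)):

\[ R_i = \sum_j \left( \alpha \frac{(a_i w_{ij})^+}{\sum_i (a_i w_{ij})^+}
   - \beta \frac{(a_i w_{ij})^-}{\sum_i (a_i w_{ij})^-} \right) R_j. \]

With \(\beta = 0\) only activating contributions propagate, and all
relevance scores inherit the sign of \(R_f\). The implementation choices
that the rule itself leaves open are:

* **Initialisation** from the pre-softmax logit of the explained class
  (default: the predicted class; the read age is selectable).
* **Biases** are excluded from numerators and denominators; a stabiliser
  \(\varepsilon = 10^{-9}\) guards empty denominators. Conservation is then
  exact for bias-free networks (verified to \(10^{-6}\) relative by
  `audit_conservation()`), and bias leakage is reported, not hidden.
* **ReLU** passes relevance through unchanged (relevance attaches to the
  post-activation unit).
* **Max-pooling** redistributes winner-take-all; tied maxima split the
  relevance equally (determinism and exact conservation).
* **Input layer**: the same \(\alpha\beta\) rule is applied at the first
  layer; no special input-domain rule is used. This is a deliberate,
  documented divergence from toolboxes that apply a box-constraint rule at
  the pixel layer.

Both the dense and the convolutional propagation use the identity
\(\sum_i (a_i w_i)^+ = a^+ \cdot w^+ + a^- \cdot w^-\) to stay fully
vectorised; the test suite checks them against a naive per-message loop on
random tiny networks to \(10^{-9}\).

# The synthetic generator

No public otolith image collection with read ages exists for this species,
so the generator is a first-class, tested module, not a fixture. It
emulates what otolith morphology offers an age-reading model:

* **Size** grows with age (base radius from 0.16 to 0.26 of the canvas),
  with substantial individual spread (log-normal, sd 0.09). The spread is
  deliberately *not* reduced by the separability knob: in real collections
  fish of the same age vary in size, so size separates broad age groups
  but not neighbouring ages — the nucleus must do that for young fish.
* **Nucleus**: a brighter central disk whose radius relative to the otolith
  decays as \(0.68 e^{-0.11(\mathrm{age}-1)}\). It is the dominant cue for
  juveniles and shrinks into irrelevance for adults.
* **Anterior growth and fingers**: juveniles (1–4) are near-circular with
  no fingers; from age 5 on, lobed fingers appear on the anterior margin
  (anterior up in every image) and lengthen with age, and the outline
  elongates anteriorly.
* **Rings**: `ring_count = age` low-contrast sinusoidal annuli between
  nucleus and edge, softened by a small Gaussian blur — mimicking annual
  zones that survive only faintly after downsampling.
* **Variants**: binary replaces the image by its mask; standardization
  rescales the foreground (aspect ratio preserved) to a fixed vertical
  extent and zeroes the background. Preserving the aspect ratio keeps the
  shape information the standardized variant is designed to retain; the
  horizontal axis is therefore scaled by the same factor.
* **Separability knob** (`contrast`): divides the stochastic spread of
  nucleus, elongation and finger length, so tests can construct easy
  (high contrast) and hard (low contrast) regimes without touching the
  age trends.

What the generator does **not** emulate: real background texture and
illumination (background is dark noise — unvalidated against real images),
daily increments, left/right otolith differences, reader bias, and the
photographic artefacts a real collection carries. Passing tests therefore
demonstrate that the *machinery* recovers planted structure, not that it
would behave identically on real material.

# The classifier and its training recipe

The default architecture is a miniature VGG-style stack — three
conv(3×3)+ReLU+max-pool(2) blocks (8, 16, 32 filters), a 64-unit dense
layer with ReLU, and a dense classification head — built by
`default_architecture()`. Every activation is stored by `forward()`, so the
relevance engine replays the pass exactly. Training uses softmax
cross-entropy with the adaptive-moment optimiser (batch size 8, learning
rate 4e-4), seeded end to end; argmax ties at prediction break toward the
lower age.

Augmentation (rotation uniform in [0°, 360°), independent horizontal and
vertical flips, vertical shifts up to ±10 px) is implemented and switchable
(`train_config(augment = )`), but the desk-scale default configuration
turns it **off**: with a few hundred training images and no pretrained
initialisation, full-rotation augmentation keeps a small network near
chance for any reasonable epoch budget, and the package's purpose is the
explanation pipeline, not augmentation-robust training. Normalisation
subtracts the training-set mean and divides by its standard deviation; the
test set is normalised with the training statistics (the natural reading of
"the same normalisation for both sets" — the alternative is flagged in the
code).

# Spectral relevance analysis choices

* **Preprocessing**: maps are cropped tightly to the otolith contour
  (removing background-noise relevance), bilinearly resized to a common
  112×112 intermediate (total mass re-normalised, since interpolation is
  not mass-conserving), then sum-pooled to 56×56 so that the total
  relevance is conserved exactly.
* **Affinity graph**: binary k-nearest-neighbour adjacency, symmetrised by
  union, with \(k = \lceil \ln n \rceil\) — the standard heuristic for
  spectral clustering on k-NN graphs; the ceiling guarantees \(k \ge 1\).
* **Clustering**: symmetric normalized Laplacian, eigenvectors of the two
  smallest eigenvalues, row-normalised, partitioned by seeded k-means
  (10 restarts) — the Ng–Jordan–Weiss construction. Disconnected graphs
  warn and proceed.
* **F1**: binary F1 under the best of the two cluster-to-group matchings,
  so relabelling cannot change the score. Group membership defaults to the
  *model-predicted* age group (the clusters are compared with what the
  model thinks), with read-age grouping as a switch.
* **Embedding**: pairwise distances are unweighted shortest-path lengths
  on the affinity graph (disconnected pairs capped at twice the largest
  finite distance), embedded by a seeded 2-D t-SNE (perplexity 30, clamped
  to \((n-1)/3\); early exaggeration 12 for 100 of 500 iterations,
  momentum 0.5→0.8, learning rate 200, adaptive gains). The t-SNE is a
  compact in-package implementation because no R t-SNE library is part of
  the package's dependency set; it follows the reference recipe and is
  exercised by determinism and locality tests.
* **Pairs**: clustering always compares two *consecutive* age groups
  (juvenile+adolescent, adolescent+young-adult, young-adult+adult),
  one experiment per pair, and skips the binary variant — silhouette maps
  vary only along the contour and carry no inner structure to cluster.

# Agreement metrics

The per-otolith precision statistic is the standard age-reading CV of two
independent estimates (human read age and model prediction):
\(CV = 100 \cdot \frac{|a-b|/\sqrt{2}}{(a+b)/2}\), i.e. the two-reading
sample standard deviation (n−1 denominator) over the two-reading mean.
The population form (n denominator) is available via `ddof = 0`. Within
each (variant, split, age-group) stratum the 1.5×IQR rule removes outlying
CVs — quartiles by linear interpolation between order statistics
(`stats::quantile` type 7), the convention that determines the fences and
is therefore stated here — and \(\overline{CV}\) is the mean of the kept
values. Strata are keyed by the read age (the group is a property of the
specimen); keying by predicted age is a switch.

# Default configuration and problem sizes

`default_config()` covers ages 1–9 (juveniles + adolescents, the pair with
the clearest morphological separation), 30 samples per age on a 56-pixel
canvas, separability contrast 6, 25 training epochs per variant. These
sizes were chosen once so that a complete three-variant experiment —
generation, training, prediction, metrics, relevance maps, clustering,
embedding, aggregation — completes in minutes on a single CPU while still
being large enough for the qualitative pattern of interest: removing inner
structure (binary variant) degrades juvenile precision most, and relevance
maps separate juveniles from adolescents far better than chance. The full
26-class setting remains one configuration edit away
(`cfg$generator$ages <- 1:26`), with canvas 112 reproducing the generator's
native scale.

Reproducibility: every stage derives its own stream from the master seed,
stages persist their state so any stage can be rerun alone, and two runs
from the same configuration produce byte-identical CSV outputs (PNG
rendering is excluded from bit-exactness; the underlying arrays are not).

# Known limitations

* Synthetic imagery only; conclusions about real otolith collections
  require real images (PNG + CSV of read ages enter through the same
  sample structure).
* The miniature network is a stand-in for large pretrained architectures;
  its exact-age accuracy at desk scale is far below production level, and
  heatmap quality inherits model quality.
* Only the \(\alpha\beta\) family of propagation rules is implemented
  (with \(\alpha_1\beta_0\) as the default); other attribution methods and
  input-layer rules are out of scope.
* The t-SNE distance derivation from the affinity graph is one reasonable
  choice among several; it is a documented substitute, not a
  reconstruction of any particular toolbox.
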
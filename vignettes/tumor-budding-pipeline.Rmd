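---
title: "Methods: automated tumor budding quantification in pan-cytokeratin IHC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tumor budding quantification in pan-cytokeratin IHC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

Tumor budding — single tumor cells or clusters of up to four or five cells
detached from the invasive front — is an established adverse prognostic
feature in colorectal carcinoma, but its manual assessment on H&E is poorly
reproducible. `budquant` implements an automated quantification pipeline for
brightfield immunohistochemistry (IHC) slides stained for pan-cytokeratin
(DAB, brown) with a hematoxylin counterstain (blue): tumor epithelium is
highlighted by the stain, and budding is quantified from the size and shape
distribution of the stained objects. This vignette documents the model, the
parameters (with units, defaults and rationale), the numerical choices, and
what the bundled synthetic-data generator does and does not emulate.

```{r setup}
library(budquant)
```

# Stain separation

An RGB pixel $I \in [0, 255]^3$ is mapped to optical density
$OD_c = -\log_{10}\!\big((I_c + 1)/256\big)$ per channel, where absorbances
of co-localized stains add linearly (Beer–Lambert). With the standard
H-DAB unit absorbance vectors (hematoxylin $(0.650, 0.704, 0.286)$, DAB
$(0.269, 0.568, 0.778)$, and their cross product as residual), the density
of each stain at a pixel is recovered by multiplying the OD vector with the
inverse stain matrix; negative densities are clipped to zero.
`renderDensities()` is the exact forward model, so
`colorDeconvolve(renderDensities(h, d, round = FALSE))` round-trips to
within $10^{-6}$ — this invertibility is what makes the synthetic ground
truth exact.

# Foreground segmentation

The DAB density map is binarized by 2-means clustering (`binarizeKmeans()`,
Lloyd's algorithm with deterministic extremal initialization): the cluster
with the higher center is foreground. Two numerical guards:

* **Constant-map guard.** If the density range is below `minRange = 0.1` OD,
  the map is treated as constant: the mask is empty and a warning is raised.
  Without this, 8-bit quantization noise on a blank slide would still be
  split into two "clusters" and half the background would be called
  foreground.
* **Mask cleanup.** Specks under 10 px are removed and holes under 50 px are
  filled, suppressing single-pixel noise without touching gate-sized
  objects.

# Objects, the size gate and two-stage clustering

8-connected components of the mask are measured (area, boundary-pixel
perimeter, centroid, bounding box). At the calibration of
0.24 µm²/px, the **bud area gate** is 300–3125 px, i.e. 72–750 µm² (about
one to five tumor-cell profiles); smaller objects are `debris`, larger ones
`islet_or_mass`. Two clustering stages then correct segmentation artifacts:

1. `mergeSimilar()` — objects with centroids within 50 px whose areas and
   perimeters agree within 20% are transitively merged and re-measured
   (recombines tumor areas split by uneven staining).
2. `absorbIntoMass()` — any non-mass object whose boundary lies within
   25 px (about one cell diameter at 0.49 µm/px) of a mass is absorbed into
   it, repeating until stable, so no "bud" is merely a fringe fragment of
   the invasive front.

A Delaunay graph over the centroids (`buildNeighborGraph()`) provides
neighbor distances; degenerate point sets fall back to the complete graph
with a warning.

# Bud classification

Every `bud_candidate` is cropped to a 100 × 100 × 3 tile centered on its
centroid (reflect-padded at the image border) and passed to a classifier:

* **Rule classifier (default).** The central DAB component must have
  solidity ≥ 0.7, moment eccentricity ≤ 0.95, mean DAB density > 0.3 OD and
  area inside the gate. It is deterministic and requires no training, which
  is why it is the pipeline default.
* **CNN.** A small convolutional network (3×3×16 conv, ReLU, 2×2 max-pool,
  3×3×32 conv, ReLU, 2×2 max-pool, FC-64, FC-2 softmax) trained with SGD +
  momentum 0.9 on cross-entropy. Inputs are centered as
  `tile/255 - 0.86` (unstained background sits near 245/255); without this
  centering the network stays at chance under a desk-scale budget. The
  package default (10 epochs, learning rate 0.005) trains in under a minute
  on a few dozen tiles; these are desk-scale choices of this package, not a
  claim about production training schedules. Checkpoints serialize to plain
  JSON (`saveBudCNN()`/`loadBudCNN()`).

```{r classifier, eval = FALSE}
dat <- generateClassifierTiles(30, 30, seed = 1)
cnn <- trainBudCNN(dat$tiles, dat$labels, epochs = 4, seed = 1)
cnn@meta$accuracy
```

# Virtual TMA grid, grading, hotspots

`makeGrid()` lays lattice points 1800 px apart over the ROI polygon's
bounding box, keeping points inside the ROI (boundary counts as inside).
Each point is the center of a square virtual core of side 3600 px — twice
the spacing, so neighboring cores overlap by 50% and a bud is generically
counted in four cores; core footprints are half-open, so a bud exactly on a
shared edge is counted once per axis. A 9000 × 9000 px square ROI yields a
5 × 5 lattice. The candidate lattice is generated from integer indices with
an explicit half-open floor: `seq()`'s internal fuzz would otherwise include
the upper boundary.

Per-core bud counts are graded by either published scheme
(`gradingScheme()`): Satoh (grades 0–4; 0, 1–5, 6–10, 10–19, ≥20) or
Harbaum (grades 1–4; [0–5], [5–17], [17–20], [20–∞]). Both published
interval lists share endpoints; by default a count equal to a shared
endpoint is assigned to the **lower** grade (conservative), switchable with
`boundary = "upper"`.

Core counts are standardized against the slide's own distribution,
$z = (x - \mu)/\sigma$ with the population (1/N) standard deviation, and
cores with $z > 1.67$ (strict, one-sided ~95%) are significant. Maximal
8-connected sets of significant cores are the **hotspots**
(`findHotspots()`); the count is also reported normalized by the number of
cores. Intratumoral heterogeneity is summarized by the normalized Shannon
entropy of the per-core grades, $H / \log_2 K$ (or $H / \log_2 n$ with
`normalize = "samples"`).

# Monte Carlo sampling adequacy

`runSubsampling()` asks how many randomly sampled virtual cores reproduce
the whole-slide statistics: for each size $n$ in 2…200 it draws 10 subsets
without replacement and records the median bud count, the median grade
(rounded half-down to an integer grade) and the normalized grade entropy,
together with their per-size min/median/max envelope. Every (size,
repetition) pair runs on its own RNG substream derived from the master
seed, so results are reproducible and independent of evaluation order, and
a full-size draw equals the whole-slide statistic exactly.

# TMA dearraying and registration

`detectCores()` segments cores on a thumbnail (cores are darker than the
background: Otsu threshold on mean RGB, hole filling, removal of fragments
below 25% of the median core area) and names them in reading order.
`registerPair()` estimates the similarity transform from a moving (IHC)
to a fixed (HE) thumbnail by an exhaustive two-point RANSAC over core
centroids (scale prefilter 0.5–2×) followed by a closed-form least-squares
(Umeyama) refinement over the inliers, then pairs cores greedily by mapped
distance within half the median core diameter. When the inlier fraction
stays below 50% it fails loudly and asks for manual control points
(`readControlPoints()`), which override the search.

# Validation metrics

`matchDetections()` matches detection and truth bounding boxes greedily by
descending IoU (acceptance at IoU ≥ 0.25): the first detection on a truth
box is a correct positive, further detections on the same box are double
detections, detections on no box are false positives. Correct-positive,
false-negative and double-detection rates are per truth box; the
false-positive rate is per detection; precision is matched detections over
all detections. `countConcordance()`/`gradeConcordance()` report OLS
R² and exact agreement per core.

# The synthetic generator: what it does and does not emulate

`generateScene()` renders scenes through the same optical-density forward
model the pipeline inverts: white background, bluish stroma patches
(hematoxylin 0.2), and brown DAB objects (density 0.9, plus 0.05
hematoxylin) of four planted classes — masses and islets above the gate,
buds as compact clusters of 1–5 cell-sized discs inside the gate, debris
below it. Supports are recorded in an integer truth mask *before* per-pixel
Gaussian density noise (default sd 0.1, floored at 40% of the object
density) is applied, so areas, centroids and boxes are exact. Objects keep
a 40 px guard gap from each other and 60 px from the edge, and generation
is byte-identical per seed.

This emulates the *geometry and stain physics* that the pipeline's
measurement steps depend on. It does **not** emulate out-of-focus blur,
stain gradients across a slide, overlapping/touching objects, necrosis,
or non-epithelial DAB-positive artifacts — so detection rates on these
scenes are upper bounds, not estimates of clinical performance.
`generateCountField()` and `generateTmaThumbnailPair()` play the same role
for the spatial statistics (planted hotspot tiles strictly above the
background mean) and the registration (cores rendered at the exact inverse
of a known similarity transform).

# Problem sizes and limitations

The test and example sizes in this package (1024 × 1024 px scenes with ~20
objects, dozens of classifier tiles, 10 × 10 count fields, 12-core
thumbnails) are this package's own desk-scale choices: large enough to
exercise every code path and small enough for a single CPU in minutes.
Known limitations:

* Performance claims are on synthetic data only; no clinical validity is
  implied.
* The rule classifier encodes fixed morphology cutoffs; the CNN at
  desk-scale budgets is a functional reference implementation, not a
  production model.
* Registration assumes a similarity transform (no shear or local
  deformation) and needs at least two well-separated cores.
* `mergeSimilar()` is O(n²) in the object count and the absorption stage
  computes one distance transform per mass per pass; both are sized for
  per-tile object counts (hundreds), not whole-slide millions.
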
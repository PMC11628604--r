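---
title: "Quantifying amyloid plaques and plaque-associated microglia with gliaQuant"
author: "gliaQuant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying amyloid plaques and plaque-associated microglia with gliaQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaQuant)
```

## Scope and model of the data

gliaQuant measures amyloid pathology and microglial organisation in 2D
multi-channel fluorescence fields of view (FOVs): an X-34-like plaque
channel, an Iba1-like microglia channel and an mCherry-like reporter channel,
each calibrated in micrometres per pixel. The package covers the full chain
from a synthetic-data generator with instance-level ground truth, through
semantic and instance segmentation, to per-object morphometry and the
statistical analyses such cohorts require. All operators work on maximum
intensity projections (2D); no 3D segmentation is attempted.

The measurement chain is:

1. **Semantic segmentation.** Either a trainable random-forest pixel
   classifier over a multi-scale filter bank, or direct intensity
   thresholding of the plaque channel.
2. **Plaque morphometry.** 8-connected instance segmentation with a ~4 um
   minimum equivalent diameter, per-plaque size and location, grey-level
   co-occurrence matrices (GLCM), and the Angular Second Moment (ASM) as a
   compactness estimate — high ASM means a homogeneous, dense plaque.
3. **Microglia instance segmentation.** Soma detection, an EDT-thickness
   split into bodies and processes, morphological closing of the process
   mask, a weighted sum of two exact Euclidean distance transforms (whole
   mask and soma mask), and a seeded watershed on the negated fused map.
4. **Spatial statistics.** Convex territory area, skeleton-based total
   process length, mean distance to the three nearest neighbouring cells,
   and the plaque-association rule: a cell is plaque-associated when its
   centroid falls inside the thresholded plaque area or within 5 um of a
   plaque's edge.
5. **SiMPull spot counting.** Difference-of-gaussians band-pass, a robust
   shared brightness threshold, size filtering and per-component maxima
   counting, aggregated frames -> technical replicates -> mice.
6. **Statistics.** Dose-response OLS, confounder-adjusted multiple
   regression, one-way ANOVA with Tukey contrasts, unpaired t-tests,
   random-intercept linear and binomial mixed models, hypergeometric and
   Fisher enrichment tests, and an exact multi-set intersection test.

## The synthetic-data generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is validated.

**Plaques** are rendered as radial profiles: a homogeneous bright core disk
of radius `core_fraction * R` at intensity 0.9, surrounded by a granular
halo whose baseline declines linearly to ~30% of the core intensity at the
rim and is multiplied by a continuous speckle field uniform on [0.3, 1].
Plaque diameters are log-normal; core fractions are Beta-distributed. Two
rendering choices matter and were made once, on first principles:

* the halo's intensity spread is scale-free in the core fraction (a linear,
  not exponential, radial decay), so ASM responds to the core share rather
  than to rim compression;
* the rim floor sits several noise SDs above background, so the stained
  extent coincides with the nominal ground-truth disk and a single shared
  brightness threshold (0.05 intensity units) recovers plaque masks at
  IoU ~1. Per-image Otsu is deliberately not used on these strongly
  unbalanced frames: it splits the core from the halo. `thresholdPlaques()`
  defaults to Otsu for generic bimodal data but carries a class-separation
  guard that returns an empty mask on unstained (noise-only) fields.

**Microglia** are somata (disks of radius 3.2-4.8 um, Gaussian-blurred) with
3-6 branch processes simulated as persistent 8-neighbour random walks of
step 1 px, so the true total process length is known exactly as the summed
polyline length. Soma centers follow a hard-core point process (12 um
minimum separation): microglia tile the parenchyma, and somata essentially
never overlap even where processes intertwine. Plaque-associated cells are
recruited onto plaque rims (from 2 um inside to 5 um outside the edge) at a
rate `pa_recruitment_coeff * area_fraction`, with `pa_recruitment_coeff`
defaulting to 731.09 cells per unit plaque area fraction. Background cells
additionally *migrate* to plaque rims with probability
`migration_coeff * area_fraction` (default coefficient 4, capped at 0.85),
so the non-plaque-associated density declines gently as plaque load grows
while the plaque-associated population rises steeply — the pattern the
plaque-load regressions are designed to detect.

**Noise** is Poisson shot noise (600 photons per intensity unit, an
accumulated-confocal-scale budget chosen so the homogeneous plaque core
stays within a couple of grey levels after 64-bin quantization) plus
additive Gaussian read noise (SD 0.01).

**Cohorts.** Each group draws per-mouse APOE levels from a log-normal and
sets guanidine-soluble A-beta-42 by a genotype-specific linear dose-response
plus Gaussian noise; a mouse's plaque density scales with its A-beta-42
relative to the group expectation. The built-in groups emulate the study
structure: dose-response slopes 0.23 (APOE4-like), 0.11 (APOE2-like), 0.005
(APOE3-like); an APOE-null group with almost no plaques and a high
soluble-aggregate spot rate; APOE3-like plaques smaller and more compact
(Beta(6, 2) core fractions) than APOE2/APOE4-like ones (Beta(3, 3)).
A `PLX3397` treatment multiplies the microglial densities by the residual
fractions 0.17/0.23/0.13 and shifts mean A-beta-42 by -148.2/-28.53/-357.1
for the APOE2/3/4-like groups. Default acquisition structure is 3 FOVs per
mouse; SiMPull frames carry Poisson-distributed diffraction-limited spots
(sigma 1.5 px) whose peak amplitude is `snr` times the noise SD.

**What the generator does not emulate.** Real tissue autofluorescence and
vascular artefacts, anisotropic PSFs, uneven illumination, plaque shapes
beyond disks, true microglial arbor geometry (walks are not space-filling
trees), and section-to-section variability. Tests passing on these
synthetics therefore validate the *operators and their contracts* — exact
distances, partitions, counts, estimator calibration — not performance on
arbitrary real histology.

## Numerical and algorithmic choices

* **Filter bank.** The plaque bank uses sigma in {1, 2, 4, 8} px with
  gaussian, difference-of-gaussians (sigma vs 1.6 sigma, the standard
  blob-detection ratio), gradient magnitude, Laplacian-of-gaussian and both
  Hessian eigenvalues (ordered, lambda1 >= lambda2): 25 planes with the
  identity. The microglia bank uses sigma in {2, ..., 64} and adds
  square-window mean and max filters (side `2*sigma + 1`): 49 planes.
  Boundaries are mirror-reflected everywhere. The random forest uses 100
  trees, sqrt(F) features per split, and a fixed seed.
* **GLCM/ASM.** 64 grey levels quantized on each plaque's min-max range
  (making ASM invariant to affine intensity rescaling), four offsets at
  distance 1 px, symmetric matrices, pairs restricted to mask-interior
  pixels, per-angle ASM averaged at the feature level. Only ASM is
  computed; other Haralick features are out of scope.
* **Fusion and watershed.** `fused = w_proc * EDT(mask) + w_soma *
  EDT(soma)` with defaults 1 and 2 (soma areas must dominate; the
  constraint `w_soma > w_proc > 0` is enforced). The seeded watershed is a
  priority flood on the negated fused map, 8-connected, with ties broken by
  (elevation, linear pixel index) — fully deterministic. Mask components
  that contain no seed are assigned the label of the nearest seeded pixel,
  so the labels always partition the mask. When external centroids replace
  the built-in soma detector, the EDT-thickness body mask stands in for the
  soma mask in the fusion.
* **Body/process split.** Body pixels are those at EDT >= 3 um (exposed as
  `bodyRadiusUm`); the process mask is closed with a 2 px disk. The split
  threshold and closing radius matter at coarse pixel grids: at 1.72 um/px
  the closing is no longer "minor", which is why instance-recovery claims
  are made at 0.86 um/px or finer.
* **Skeleton length.** Zhang-Suen thinning; length sums 8-connected
  steps (orthogonal 1 px, diagonal sqrt(2) px), skipping a diagonal step
  when an orthogonal pixel rectifies it. Thinning shortens free ends by a
  pixel or two, hence the documented +/-5% tolerance on bar fixtures.
* **Spot detection.** DoG at sigma 1.5 vs 2.4 px; mask threshold at
  `median + 5 * MAD` of the filtered frame (MAD floored at machine
  epsilon); 8-connected components restricted to areas [2, 50] px; spots
  are the component's regional maxima, deduplicated at 3 px, and validated
  at one extra MAD unit above the mask threshold (a two-stage
  detect-then-validate scheme in the ComDet/ThunderSTORM tradition, which
  suppresses near-threshold noise clusters while diffraction-limited spots,
  whose peaks sit far above threshold, are untouched). Merged spot pairs
  inside the area window therefore count as two; an oversized saturated
  blob counts as zero.
* **Multi-set intersection test.** The distribution of the common
  intersection of m uniform fixed-size subsets is computed by sequential
  exact conditioning: processing sets smallest-first, the running
  intersection size after intersecting with the next set is hypergeometric
  given the current size, so the pmf is an iterated hypergeometric
  convolution. Every term is positive — unlike the equivalent
  inclusion-exclusion expansion, which cancels catastrophically at
  transcriptome-scale backgrounds — and the computation runs in log space,
  reducing *exactly* to the hypergeometric distribution at m = 2. Bonferroni
  multiplicities are always supplied by the caller.
* **Mixed models.** Random-intercept models via lme4 (REML for gaussian,
  Laplace for binomial), two-sided Wald z p-values, residual quantiles
  exported for Q-Q checks; singular fits warn and report the degenerate
  variance.
* **Determinism.** Every generator takes an explicit seed and restores the
  caller's RNG state; the pipeline derives per-stage child seeds from the
  global seed by a stage-name hash, so stages can be rerun in isolation.

## Design decisions taken on open points

* The sigma notation of the classifier's scale sets is read as the set
  {2^n} over the stated range (n = 0..3 for plaques, 1..6 for microglia);
  the raw image is included once as an identity plane.
* The plaque-association distance is computed as the exact EDT of the mask
  complement evaluated at the centroid's pixel, i.e. pixel-center to
  pixel-center distances; signed negative inside plaques; the 5 um rule is
  applied to the unsigned outside distance.
* Convex territory uses the hull of pixel centers; collinear cells have
  zero territory.
* Border-touching plaques and cells are measured but flagged, so downstream
  comparisons can exclude them.
* Cohort-level regressions default to per-mouse means (3 FOVs averaged per
  mouse), matching the acquisition structure; per-FOV analyses remain
  available through the per-FOV tables.
* The non-plaque-associated population is generated to *decline gently*
  with plaque load (migration model above) rather than stay exactly flat:
  a flat generator makes the sign of the fitted non-PA slope a coin flip,
  whereas the observed pattern in this assay class is a steeply rising PA
  population against a slightly declining non-PA population.

## Problem sizes used by the test-suite and validation runs

These sizes are the package's own validation choices: imaging checks run on
the standard 438.88 um 40x field at a coarsened 1.72 um/px grid (255 px
frames) or at 0.86 um/px (510 px) where instance recovery is measured;
end-to-end cohort checks use 4 groups x 4 mice x 3 FOVs over 100 seeded
replicates; SiMPull group-separation checks use 4 groups x 3 mice with 3
replicates of 3 frames at 192 px; estimator-calibration checks use 1000
null replicates, and mixed-model recovery 100 replicates of 20 mice x 30
plaques (LMM) and 16 mice x 40 cells (GLMM). The generator's physical
defaults (0.43 um/px, 1021 px frames) remain those of the imaging setup it
emulates.

## A worked example

```{r example, eval = FALSE}
library(gliaQuant)

# one APOE4-like field with ground truth
g <- generateFov(groupSpec("APOE4"), seed = 1, pixelSizeUm = 1.72)

# plaque masks and per-plaque morphometry
mask <- thresholdPlaques(getChannel(g$fov, "plaque"), method = 0.05)
seg <- segmentPlaques(mask, pixelSizeUm = 1.72)
seg$records <- plaqueAsm(getChannel(g$fov, "plaque"), seg$labels, seg$records)
summarizeFovPlaques(seg$records, fovSize(g$fov)^2)

# microglia instances and the 5-um association rule
inst <- segmentMicroglia(getChannel(g$fov, "microglia"),
                         g$truth@microgliaLabels > 0, pixelSizeUm = 1.72)
cells <- measureMicroglia(inst$labels, inst$body, seg$labels > 0,
                          pixelSizeUm = 1.72)
summarizeFovMicroglia(cells, summarizeFovPlaques(seg$records, fovSize(g$fov)^2))

# a full simulated experiment with analyses and reports
res <- runPipeline(list(mice_per_group = 4, pixel_size_um = 1.72, seed = 1),
                   outDir = "gliaquant_run")
res$microglia_vs_plaque_load
```

## Known limitations

* 2D only; z-stacks must be projected first.
* The soma detector is a classical blob detector; for real data a dedicated
  cell-body segmenter's centroids can be supplied verbatim
  (`detectSomata(..., centroids = )`, seeds CSV in the I/O helpers).
* Skeleton length underestimates thick or densely branched arbors.
* Otsu-based plaque thresholding is only appropriate for roughly bimodal
  frames; use the shared fixed threshold or the trained classifier
  otherwise.
* The multi-set test assumes independent uniform fixed-size subsets of a
  common background, as in differential-expression overlap testing; it does
  not model correlated set membership.
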
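---
title: "Measuring the robustness of radiomic features to segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the robustness of radiomic features to segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

Radiomic features are computed from a region of interest, and the region
of interest comes from a segmentation algorithm. Two algorithms — or one
algorithm started twice — rarely return the same mask for the same lung
nodule, so every feature carries segmentation-induced variance on top of
biological variance. A feature that changes substantially whenever the
mask wiggles is a poor candidate for any downstream model, however
predictive it looks in a single-segmentation study. `radstab` implements
a complete, reproducible pipeline for quantifying this sensitivity, and
for the complementary question of how redundant a feature set is.

The study design it targets is a crossed repeated-measures layout: a
cohort of nodules, each segmented by `n_algorithms` distinct algorithms,
each run with `n_inits_per_algorithm` initializations. The package
defaults (52 nodules, 3 algorithms x 3 initializations, 468 segmentation
records) mirror the scale of published multi-institution robustness
studies while remaining desk-computable.

## The stability model

### Lin's concordance correlation coefficient

For paired measurements $x, y$ of one feature over nodules,

$$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

with population ($1/n$) moments, following Lin's original definition.
The CCC multiplies precision (Pearson correlation) by an accuracy factor
penalizing mean and variance shifts, so $|\mathrm{CCC}| \le |r|$ with
equality only for perfectly calibrated raters. Degenerate inputs follow
documented conventions: two identical constant vectors give 1 (perfect
agreement carries no evidence against concordance), two unequal constant
vectors give 0, and one constant vector gives 0 through the formula.

### Repeated measures

With 9 replicates per nodule there are 36 unordered replicate pairs.
Each pair yields one pairwise CCC over nodules; the repeated-measures
estimate for a stratum is the plain mean over that stratum's pairs:
same-algorithm pairs (9) give the intra-algorithm CCC, cross-algorithm
pairs (27) the inter-algorithm CCC, and all 36 the overall CCC. This
averaging form was chosen over a variance-components estimator because
it makes the three published strata (intra, inter, total) exactly three
pair sets of one estimator, it is unit-testable against hand-computed
pairs, and it needs no distributional assumptions. Two consequences are
used as invariants in the test suite: the overall CCC is the
pair-count-weighted mean of the intra and inter estimates, and all three
are invariant under a common positive affine rescaling of the feature.
Whether the published "total" estimator weighted the strata by pair
count or equally is not documented; pair-count weighting (the plain mean
over all 36 pairs) is used here. Missing feature values are dropped
pairwise per replicate pair; pairs with fewer than three complete
nodules are skipped, and a feature reports a missing CCC (with a reason)
when no pair survives.

Class-level analyses are deliberately plain: five-number summaries and
threshold fractions per feature class (`stability_summary()`), and a
fixed-effects one-way ANOVA of CCC on class (`class_anova()`), fit with
`stats::lm`. Post-hoc pairwise comparisons are out of scope.

## The redundancy model

Features are nodes of an undirected graph; the weight of edge $(i, j)$
is $|\mathrm{CC}(i, j)|$, either Pearson (linear association) or
Spearman (monotone association), computed pairwise-complete over all
segmentation records. Edges with weight *below* the threshold $T$ are
removed — the comparison is $\ge$, so an edge at exactly $T$ survives —
and connected subgroups are counted, singletons included. Undefined
correlations (constant feature columns) contribute no edges, so constant
features end as singletons; they are also reported by name on the
correlation matrix. The default grid $T \in \{0.75, 0.80, 0.85, 0.90,
0.95\}$ matches the conventional reporting grid, and counts are
non-decreasing in $T$ by edge-set monotonicity — asserted on every run.
Graphs can be exported as GraphML with feature class, pipeline and
component attributes, optionally dropping singleton components for
display.

## The synthetic cohort

The generator exists so that every downstream stage has a fully
controlled input. It emulates, rather than simulates, CT physics:

* **Volume**: 96³ voxels at 0.7 x 0.7 x 1.25 mm (anisotropic on purpose,
  so isotropic resampling is always exercised), background −800 HU
  (aerated lung) with additive white Gaussian noise, default sd 20 HU —
  a typical parenchymal noise magnitude for diagnostic chest CT.
* **Nodule**: a rotated ellipsoid whose radius is modulated by a fixed
  low-order angular perturbation (relative amplitude 0.1) — a mild
  lobulation. Intensity ramps from background to the core value along a
  logistic profile in the signed distance to the surface, with a 10–90%
  transition width (`margin_sharpness`) drawn uniformly from 0.5–3 mm
  per nodule; internal texture is Gaussian noise smoothed to a 2 mm
  correlation length and scaled to 40 HU sd. Core intensities are drawn
  uniformly from −50 to 50 HU, diameters uniformly from 6–14 mm —
  screening-scale nodules chosen to keep the default cohort
  desk-computable; all values are fixed conventions of the package, not
  fitted to any data set.
* **Segmentations**: each algorithm applies a systematic perturbation —
  a signed morphological boundary offset of −1/0/+1 voxel across the
  three algorithms plus Gaussian boundary smoothing with
  algorithm-specific sigma (0.8/1.2/1.6 voxels) — and each
  initialization adds low-frequency random boundary jitter of 0.3 voxel
  amplitude, below the one-voxel inter-algorithm offset. The
  threshold-level shift implementing the jitter is clamped to [0.15,
  0.85] so that extreme jitter values cannot spuriously admit far-field
  components; the largest 26-connected component is kept, jitter is
  redrawn (boundedly) if a mask empties, and every emitted mask is
  asserted nonempty and single-component. This construction guarantees
  by design the ordering that motivates the intra/inter strata:
  same-algorithm masks agree more than cross-algorithm masks. The
  amplitudes are conventions — the real inter- vs intra-algorithm Dice
  gap of any particular algorithm family is not modelled.

Randomness is organized as one derived stream per (nodule, algorithm,
initialization, retry), hashed from the master seed, so a single record
can be regenerated in isolation and cohorts are bit-reproducible.

What passing tests on this cohort shows — and does not show: they verify
the estimators, the feature implementations and the pipeline plumbing
under a controlled data-generating process with known ground truth. They
do not certify stability magnitudes for real CT data: real nodules have
spiculation, attached vasculature and pleural contact, scanners have
reconstruction-kernel texture, and real segmentation algorithms fail in
structured ways none of which the generator models. Accordingly the
synthetic cohort's CCC distributions are systematically harsher than
published patient-cohort values (a one-voxel systematic offset is a
large relative perturbation for a 6–14 mm nodule), and only qualitative
orderings — intra above inter, size features more stable than shape
features, counts monotone in the threshold — transfer.

## The feature set

One reference implementation per family, declared in a machine-readable
dictionary (`default_dictionary()`, 126 entries) that carries the
standard ontology: classes Size, GSD, LSD, Intensity, Margin, Texture;
texture subclasses GLCM, LoG, Law's, run-length, wavelet; per-entry
dimensionality, multiscale flag and scale count. The closed-world
ontology is enforced at validation. A counts-only fixture of a published
seven-site, 830-feature submission table (`consortium_dictionary()`) is
included for testing class-count summaries; its entry names are
synthetic placeholders.

Preprocessing crops to the mask bounding box padded by 10 mm (a 20 mm
preset exists) and resamples to 0.5 mm isotropic — trilinear for the
image, nearest-neighbour for the mask, with half-up tie rounding so that
integer-ratio resampling conserves mask volume. 2D features use the
axial slice with the largest in-plane diameter (ties: lowest index).

Family notes, including the numerical choices that were genuinely open:

* **Size**: volume as voxel count x voxel volume; surface area by the
  co-area estimator — the integral of the gradient magnitude of a
  0.7-voxel-sigma Gaussian-smoothed occupancy — which tracks the
  analytic sphere area to within ~1% where naive voxel-face counting
  overestimates by ~1.5x and would break the sphericity bound; maximal
  3D diameter as the largest pairwise surface-voxel distance (via
  directional extreme-point candidates for large masks).
* **GSD**: sphericity $\pi^{1/3}(6V)^{2/3}/A$, compactness
  $36\pi V^2/A^3$, principal-axis ratios from the voxel second-moment
  tensor, and radius statistics of surface voxels about the centroid.
* **LSD**: roughness as the signed distance from each mask surface voxel
  to the nearest surface voxel of a reference surface (Gaussian-smoothed
  occupancy, sigma 3 mm, re-thresholded at 0.5), summarized after
  subtracting the median signed deviation — so the uniform shrinkage
  that smoothing inflicts on curved surfaces does not register as
  roughness, only local irregularity does. Computed on a 1 mm grid.
* **Intensity**: nine histogram statistics at 25 HU bins; skewness and
  kurtosis are population-standardized central moments (kurtosis not
  excess) and are reported missing for constant regions rather than
  propagating division by zero.
* **Margin**: at 800 quasi-uniform surface points (deterministic
  spherical-coordinate stratification), intensity profiles sampled ±5 mm
  along outward normals from the smoothed-occupancy gradient, fit with
  the logistic edge model $b + h\,(1 - \mathrm{plogis}(t/w))$ — $h$ is
  the inside-minus-outside contrast, $w \in (0.05, 10]$ mm the
  transition width. The fit is a width grid search with closed-form
  height/offset per candidate (deterministic and vectorized across
  normals); non-finite fits are dropped and counted, and the sigmoid
  features go missing if over half drop. Gradient statistics on the
  one-voxel inner/outer boundary shells, and intensity statistics of the
  parenchyma ring (all exterior voxels within the maximum nodule radius
  of the boundary, built with octagonal-metric morphological dilation)
  complete the family; the parenchyma statistics are classed as Margin.
* **GLCM**: min–max quantization to 32 levels inside the mask, 13
  symmetric 3D offsets at distance 1, pairs restricted to in-mask
  voxels, symmetrized and normalized per offset; contrast,
  dissimilarity, homogeneity, energy, entropy aggregated as mean and
  range over offsets, recomputed at 1/2/3 mm scales; a 2D variant (8
  directions) on the maximal slice. Quantization makes the features
  exactly invariant to monotone affine intensity maps.
* **Run-length**: runs of equal quantized level (16 levels) along the 13
  directions, truncated at the mask boundary, on the 1 mm grid;
  SRE/LRE/GLN/RLN/RP/LGRE/HGRE averaged over directions. Runs are
  computed directly in the resampled mask region — no rubber-band
  straightening transform (under-specified for reimplementation) and no
  Sobel prefilter.
* **Law's**: 3D kernels as outer products of L5/E5/S5/R5/W5; energy =
  5-voxel moving average of |response|; rotation invariance by averaging
  energy maps over all distinct axis permutations of the kernel triple,
  which together with the absolute value gives exact invariance under
  the 48 signed axis permutations; five triples x four moments on the
  1 mm grid, reflective padding, thin masks flagged.
* **LoG**: scale-normalized $\sigma^2 \nabla^2 (G_\sigma * I)$ at 0.5,
  1.5, 2.5 mm on the 0.5 mm grid; the normalization makes the blob
  response peak at $\sigma \approx r/\sqrt 3$, which the tests exploit.
* **Wavelet**: one-level orthonormal 3D Haar; per sub-band energy and
  32-bin coefficient entropy restricted to the any-of-8 downsampled
  mask; orthonormality gives the Parseval identity used as an invariant.

Texture scale choices (GLCM at its preset 1/2/3 mm scales; run-length,
Law's and the parenchyma ring at 1 mm; LoG, wavelet, margin and shape on
the 0.5 mm grid) reflect each family's intrinsic scale: co-occurrence
and run statistics at sub-voxel resampling mostly measure interpolation,
while margin fits and surface geometry benefit from the fine grid. These
choices also keep the default 468-record analysis to a few minutes.

Every family is a pure function of (volume, mask, configuration);
`extract_all()` runs preprocessing once, dispatches only the families
the dictionary requests, never aborts a record on a family failure
(failures become flagged missing values), and records per-family
timings.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains simulate → extract → stability → redundancy →
report with flat CSV/JSON intermediates; each stage is skipped when its
outputs exist, so deleting a downstream file recomputes exactly that
stage and its dependents. Every CSV carries a header comment with the
master seed and an MD5 hash of the configuration; two runs with the same
configuration and seed produce byte-identical tables. Volumes are
regenerated deterministically rather than stored (optionally written as
NIfTI with spacing in the header).

Problem sizes used by the shipped checks: unit and property tests run on
digital phantoms (spheres r ≤ 10, 5³–16³ random fields) and 2–5 nodule
cohorts on 48³ grids; the end-to-end checks run the full default design
(52 nodules, 468 records, 126 features, both correlation methods, five
thresholds), which completes in a few minutes on one CPU. Brute-force
oracles back the run-length matrices (literal run walking), GLCM pair
counts, and graph components (breadth-first search) on seeded random
cases.

## Known limitations

* The repeated-measures CCC is a pair-mean estimator, not a
  variance-components or mixed-model estimator; with badly unbalanced
  missingness the pair mean can weight nodules unevenly. No bootstrap
  confidence intervals are provided (extension point).
* The co-area surface estimator under-reads the area of structures
  thinner than ~3 voxels; sphericity can then exceed 1 slightly (a 0.05
  discretization allowance is used in its tests).
* Euclidean dilation is octagonal-metric (alternating 6/26
  neighbourhoods), with up to ~8% radial error — inside the ±1 voxel
  tolerance of the parenchyma-ring checks at the radii used.
* "Local volume-invariant" shape statistics beyond roughness are not
  defined in the literature the ontology derives from and are not
  implemented; kernel/mixture aggregation of local texture maps is
  likewise replaced by plain moment summaries.
* The generator does not model real segmentation-algorithm behaviour,
  scanner physics, or nodule pathology; see the cohort section for what
  that implies about transferring magnitudes to real data.
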
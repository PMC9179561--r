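---
title: "Quantifying microglial activation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microglial activation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microgliaq` implements the three histological read-outs commonly used to
grade microglial activation in anti-IBA1 stains — cell density,
densitometric percent positive area, and the convex-hull ramification
index — together with the rank-based group statistics that accompany them,
and a synthetic scene generator that provides the ground truth against
which the whole pipeline is validated. This vignette records the models,
the tunable parameters, and the design decisions, in particular where a
choice was genuinely open.

## Images, ROIs and conventions

All quantification operates on `gray_image` objects: 8-bit-convention
intensity rasters (values 0–255) with an explicit physical pixel size in
µm/pixel. Pixel `(0, 0)` sits at the top-left corner, x runs rightward, y
downward, and pixel centres are at integer + 0.5. 16-bit inputs are
rescaled by the dtype maximum, not the image maximum — with constant
illumination this keeps intensities comparable across sections, which is
what makes a shared threshold meaningful. RGB inputs are converted with the
Rec. 601 luminance weights 0.299/0.587/0.114 (the unweighted channel mean
is available as an option); DAB's brown deposit maps to dark values under
either transform. Objective magnifications and camera pixel pitches vary
between rigs, so the pixel size is always explicit user input and never
read from file metadata.

ROIs are simple polygons in pixel coordinates. Rasterization uses the
pixel-centre-in-polygon rule (even-odd scanline; centres exactly on an edge
are included), which is deterministic and directly checkable against a
winding-number oracle. Physical ROI area — the denominator of the density
read-out — is the shoelace polygon area scaled by the squared pixel size,
not the rasterized pixel count; for convex ROIs of ≥ 100×100 px the two
agree within 2 %.

## Densitometry

A threshold splits the ROI pixels into positive and negative;
"staining intensity" is 100 × |positive ∩ ROI| / |ROI|. Decisions:

* **Comparisons are strict** (`<` / `>`; ties to background) so results are
  bit-exactly reproducible.
* **Polarity** defaults to positive-below (DAB signal is dark after
  grayscale conversion).
* **The cutoff**: manual thresholding does not automate, so the default
  rule is Otsu's between-class variance maximization over the 256-bin
  integer histogram of the *ROI pixels only* — background outside the
  evaluation region cannot bias the cutoff. A fixed user cutoff is
  available throughout.
* **Threshold scope.** Otsu's criterion assumes an informatively bimodal
  histogram. In a weakly stained section (positive fraction below roughly
  0.6 % under the default synthetic noise model) the foreground class is
  too small to dominate the criterion and the maximizer splits the
  *background* mode instead, misclassifying roughly half the ROI. Because
  sections acquired under constant illumination share one intensity scale,
  `run_pipeline()` therefore computes a **single cutoff from the pooled ROI
  histograms of the whole cohort** (`pooled_otsu_cutoff()`) and applies it
  to every scene. This is the automated analogue of setting one manual
  threshold for all comparably acquired sections, and it is robust for
  low-expression controls. Per-image Otsu remains available
  (`threshold_scope = "per_image"`).

## Cell detection and density

Positive pixels are grouped into connected components (default
8-connectivity, so thin diagonal processes stay attached to their somata;
4-connectivity available), filtered by physical area (default minimum
20 µm², which rejects noise specks smaller than any soma; no upper bound),
and counted iff their centroid lies inside the ROI. The centroid rule
counts a cell straddling an ROI border exactly once, so adjacent ROIs never
double-count, and it is unbiased for uniformly placed cells. Density is
count / ROI area (cells/mm²). No watershed splitting of merged cells and no
stereological correction is attempted; where somata merge into plaques,
component counting is a biased surrogate for manual counting, and the
statistics stage accepts externally produced per-animal counts instead.

## Morphometry: the ramification index

For each measured cell, the cell area is *A_c* = (foreground pixel count) ×
(pixel area), and the projection area *A_p* is the area of the convex hull
of **all four corner points of every foreground pixel square** (hull by
`grDevices::chull`, area by the shoelace formula). The hull of the corner
points contains the union of the pixel squares, so *A_p* ≥ *A_c* holds
structurally and RI = *A_c*/*A_p* is provably in (0, 1] — including for
one-pixel-wide straight cells, whose corner hull is still a rectangle. A
hull over pixel *centres* can violate RI ≤ 1 for thin cells and was
rejected. The implementation agrees with a brute-force gift-wrapping oracle
to < 10⁻⁹ relative error on fuzzed masks.

Cells are selected for measurement by the grid rule: a rectangular grid
with uniform spacing (default image width / 8) and random phase is
superimposed, and every cell whose pixel set intersects a grid line is
measured. A pixel `[i, i+1) × [j, j+1)` intersects the line `x = c` iff
`i ≤ c < i + 1`. Whether the grid phase should be random or fixed per
section is genuinely open; random phase (from the pipeline seed) is the
default because it makes the selection a probability sample, and fixed
offsets are supported for exact reproduction. Cells touching the image
border are excluded — truncated silhouettes lose hull area faster than
silhouette area, biasing RI upward. The silhouette here is the segmented
foreground component; with manual outlining the measured object is the
annotator's polygon instead, and this package's mask-based definition is
the stated automated surrogate (including for the hull, where using the
full mask rather than an outline's vertices is this package's convention).

## The synthetic scene generator

No raw micrographs with ground truth exist, so validation rests on
synthetic DAB-like fields. A cell is a rasterized soma disk plus processes
grown as random walks (unit-µm steps, per-step direction noise
`Normal(0, wiggle)`, default wiggle 0.25 rad), attached to the soma
boundary at quasi-uniform angles and dilated to the process thickness. One
parameter, `retraction` ∈ [0, 1], moves the family along the
resting-to-activated continuum: soma radius scales by (1 + retraction),
process length by (1 − retraction), process count by (1 − 0.99·retraction).
Defaults (soma radius 5 µm, 6 processes of 25 µm at thickness 1.5 µm,
1 µm/pixel) give mean RI ≈ 0.19 fully ramified and ≈ 0.95 fully amoeboid,
bracketing the morphologies seen in white matter and cortex. Process count
and step count are **stochastically rounded** per cell: their expectations
follow the scaling formulas exactly, and — unlike deterministic rounding,
which makes mean RI a step function of retraction (losing one of six arms
jumps it by ~0.05) — the family's mean RI becomes a continuous, invertible
function of retraction.

`calibrate_retraction()` inverts that response by bisection under common
random numbers (each evaluation draws the same 25 cells), converging to a
target mean RI within ±0.02 and reporting the achievable interval when a
target is outside it.

Scenes place cells by dart-throwing with a minimum centroid separation of
twice the maximal radial reach of a cell (soma radius at its retraction +
process length + thickness + a 2-px raster margin). This *guarantees*
masks never merge, so counts, positive fractions and per-cell RIs are
unambiguous ground truth. The price is a packing ceiling: roughly 300–470
cells/mm² depending on morphology, below the strongest microgliosis seen
in demyelinated white matter (~800–950 cells/mm²). Emulating merged
plaques is deliberately out of scope — a generator that merges cells no
longer has countable ground truth; the analysis drivers cap white-matter
densities at 420 cells/mm² and say so.

Foreground pixels draw intensities from `Normal(70, 12)` and background
from `Normal(210, 12)`, clipped to [0, 255] and rounded — a dark-on-bright
abstraction of DAB against a pale counterstain at roughly 11σ separation.
The generator does **not** emulate RGB color, color deconvolution, uneven
illumination, section artefacts, out-of-focus blur, or overlapping cells;
passing recovery tests therefore demonstrates correctness of the
measurement chain on well-posed inputs, not robustness to real-world
staining pathology.

Cohorts draw per-animal targets as truncated Normal variates around the
group targets (between-animal SDs default to published cohort SDs). Each
group is driven by exactly one of density or positive fraction (they are
coupled through the cell count: expected positive fraction ≈ density ×
mean cell area), with the mean RI target calibrated per animal. Per-animal
RNG streams derive from the root seed as
`(seed·100003 + group·1009 + animal·7) mod (2³¹ − 2) + 1`, so generation is
reproducible and order-independent.

## Group statistics

Per-animal values (one value per animal and metric) enter: optional
Grubbs' screening, Kruskal–Wallis, Dunn's comparisons, symbols.

* **Grubbs' test** is the classic two-sided single-outlier, single-pass
  variant: G = max|x−mean|/SD against
  ((n−1)/√n)·√(t²/(n−2+t²)) with t the upper α/(2n) Student-t quantile on
  n−2 df. It is applied per group at α = 0.05 and **only to the
  densitometric metric** — morphology and density values are never
  screened, mirroring the published exclusion protocol. Its null rejection
  rate is verified at ≈ 0.05 by simulation.
* **Kruskal–Wallis** uses mid-ranks, tie correction and the chi-square
  approximation on k−1 df (via `stats::kruskal.test`; exact permutation is
  impractical beyond tiny n and standard software uses the same
  approximation). At the smallest design tested (3 groups of 3) the
  chi-square p agrees with the exhaustively enumerated permutation p to
  within ±0.05 wherever the permutation p ≤ 0.25; in the mid-p range the
  approximation deviates by up to ~0.1, which is immaterial for decisions
  at α = 0.05 but worth knowing when quoting large p-values at small n.
* **Dunn's test** follows the vs-control design of common graphing
  software: z = (R̄_g − R̄_ctrl)/√((N(N+1)/12 − T)(1/n_g + 1/n_ctrl)) with
  tie term T = Σ(t³−t)/(12(N−1)), two-sided normal p, and Bonferroni-type
  adjustment over the m comparisons actually made (3 in a 4-group design);
  an all-pairs mode exists but is off by default. A structural property of
  the rank-based statistic is worth stating: with four ordered groups of 5,
  the mean-rank gap between *adjacent* fully separated groups is exactly 5,
  capping that z at 1.34 (p ≈ 0.18) regardless of effect size — only the
  more distant comparisons can reach significance, which is exactly the
  shape of the published 1-week/3-week/5-week progression.
* **SD** is reported with the n−1 denominator; symbols are `***` p ≤ 0.001,
  `**` p ≤ 0.01, `*` p ≤ 0.05, `n.s.` otherwise (boundaries inclusive).

When two evaluators' manual counts are supplied, the stats stage averages
them per animal (the combination rule used by the source counts is not
recorded anywhere; the average is this package's documented choice).

## Problem sizes and numerical choices

Validation cohorts use 640×640 px scenes at 1 µm/pixel with a rectangular
ROI inset 20 px (0.36 mm²) — large enough for 30–170 non-merging cells per
scene, small enough that a full 5-animal recovery experiment (calibration,
rendering, quantification, statistics) runs in well under a minute per
cohort. Calibration uses 25 cells per objective evaluation and ≤ 20
bisection steps. The oracle-equivalence suites fuzz 1,000 random masks in
20×20 windows. The significance-pattern experiment runs 100 replicate
cohorts at the per-animal-value level (Normal draws at the published group
means/SDs feeding the statistics stage directly) — the image chain's
contribution to per-animal mean RI error is ~0.01, an order of magnitude
below the between-animal SDs, so value-level replication tests the same
statistical claim at a fraction of the cost.

Otsu ties break toward the smallest cutoff; Otsu bins intensities by
rounding to integers; component labelling is flood-fill; hull degeneracies
do not arise because corner-point hulls of non-empty pixel sets always
span a rectangle.

## Known limitations

* Counting assumes separable somata; true microgliosis plaques violate
  this and need manual counts or stereology (supported via the CSV path).
* The synthetic benchmark validates the measurement chain, not staining
  chemistry or imaging artefacts (see the generator's non-goals above).
* Densities beyond the non-merging packing ceiling cannot be simulated;
  recovery claims are made only within it.
* Exact published p-values cannot be reproduced because per-animal raw
  values are not published; only the qualitative significance pattern is a
  reproduction target.
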
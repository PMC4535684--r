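---
title: "Quantifying differential chromatin accessibility between homologs from FISH images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying differential chromatin accessibility between homologs from FISH images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishda)
```

## The measurement problem

Short single-copy FISH probes hybridize to a metaphase chromosome in
proportion to how accessible the condensed chromatin at the target locus is.
When the two parental homologs of a chromosome differ in local compaction,
the same probe produces a reproducibly brighter signal on one homolog than
on the other — *differential accessibility* (DA). fishda quantifies this
from two-channel metaphase images: a counterstain channel (chromosomes, used
only for context) and a probe channel carrying the two homolog spots.

Per cell, the pipeline

1. locates the two probe signals (`detect_probe_peaks()`),
2. delineates each with a gradient-vector-flow (GVF) active contour
   (`compute_edge_map()`, `compute_gvf()`, `evolve_snake()`),
3. integrates background-corrected probe intensity inside each contour
   (`estimate_background()`, `integrated_intensity()`), and
4. reduces the cell to one number, the normalized inter-homolog difference

$$ d \;=\; \frac{|I_A - I_B|}{I_A + I_B} \in [0, 1], $$

where $I_A$ and $I_B$ are the background-corrected integrated intensities of
the two homolog spots. $d = 0$ means equal accessibility; $d = 1$ means the
probe bound only one homolog. $d$ is invariant to overall image scaling
(exposure, gain), symmetric in the homologs, and strictly increasing in the
intensity gap — the properties the test suite asserts.

A locus is then called DA over a cohort of cells when at least two thirds of
scored cells show DA (per-cell $d \ge 0.3$), the weaker homolog is
directionally consistent across flagged cells, and the DA fraction differs
from the 0.5 null by a two-proportion z-test at $\alpha = 0.05$
(`summarize_locus()`). Treatment effects are tested by the same z statistic
on DA-cell counts pre vs post, signed so that reductions are negative, with
$z < -2$ declaring a significant reduction, alongside the group mean
difference $\Delta\mu$ and a two-tailed Welch t-test on the per-cell $d$
values (`compare_pre_post()`).

## Segmentation: edge map, GVF, snake

The edge map is the gradient magnitude of the Gaussian-smoothed probe image,
normalized to $[0,1]$; an optional binary variant thresholds it at a
configurable fraction of its maximum (`binarize_fraction`, default 0: the
gray-scale map is used, which is the numerically gentler choice since the
binary map's discontinuity makes snake equilibria sensitive to the
threshold).

GVF diffuses the edge map's gradient $(f_x, f_y)$ into a force field
$(u, v)$ by iterating the explicit update

$$ u \leftarrow u + \gamma\left[\mu \nabla^2 u - (u - f_x)(f_x^2 + f_y^2)\right] $$

(and analogously for $v$) until the RMS Euler-equation residual falls below
`tolerance`. Defaults: $\mu = 0.1$, $\gamma = 1$, tolerance $10^{-4}$, at
most 500 iterations. Stability of the diffusion step on the unit grid
requires $\gamma\mu \le 1/4$, which the solver enforces; divergence (from a
user-supplied larger step) is reported as an error rather than clamped
silently. Boundary conditions are replicate-edge throughout. Convergence is
verified in the tests by an independently coded residual oracle.

The snake minimizes the usual tension ($\alpha$) + rigidity ($\beta$)
internal energy against the external force $\kappa \cdot (u, v)$ sampled by
bilinear interpolation, using the standard semi-implicit scheme: the
internal pentadiagonal system is solved exactly each step, vertices are
re-sampled to uniform arc length, and iteration stops when the mean vertex
displacement drops below `convergence_tol` (0.02 px). A non-converged snake
is returned flagged, not errored; a self-intersecting result is an error
that excludes the cell with a QC record. Defaults
($\alpha = \beta = 0.1$, $\kappa = 2$, 64 vertices, initial radius
$3\sigma$) put the external force one to two orders of magnitude above the
internal shrinkage near the edge ridge, so the equilibrium bias toward the
spot center is well under 0.1 px.

**Where the contour lands, and why the smoothing default matters.** For a
Gaussian spot of lateral width $\sigma$ smoothed with $\sigma_s$, the edge
ridge — where the GVF force field converges from both sides — sits at radius
$\sqrt{\sigma^2 + \sigma_s^2}$. The default `smoothing_sigma` is
$2.25\,\sigma$, which places the ridge at $2.46\,\sigma$, essentially the
radius enclosing 95% of the spot's mass ($2.448\,\sigma$). The contour
therefore approximates the spot's photometric support, and the integrated
intensity captures ~95% of the signal on *both* homologs equally, so the
ratio statistic $d$ is essentially unbiased (cohort tests bound the bias at
0.05 and the RMSE at 0.1; in practice both are an order of magnitude
smaller). The heavy smoothing also suppresses noise-driven edges around dim
spots. The cost is that very close spot pairs would merge; the generator
refuses center separations under $6\sigma$ for the same reason.

Peak detection runs on a mildly smoothed image (sigma 2 px), keeps local
maxima above median + 5 MAD (above the maxima of smoothed background noise
on these frame sizes, far below any real spot), ranks by height with
lexicographic (row, col) tie-breaking, and enforces a minimum mutual
distance. Border pixels are excluded — their clamped neighborhoods make
them degenerate maxima, and a spot centered on the frame border could not be
contoured anyway. Finding fewer peaks than expected marks the cell as a
hybridization failure; the pipeline logs it once with a reason code and
continues.

## Background and integration choices

Background is the median of an annulus (width 4 px) outside the contour
dilated by 2 px, with the partner spot's dilated contour excluded; the
median is robust to the partner's faint skirt and to counterstain
bleed-through, and the annulus keeps the estimate local. Pixel membership
is by pixel center (no partial-pixel weighting), and background-corrected
pixels are clipped at zero before summation so noise cannot drive an
integral negative. Both choices are deliberate simplifications: the
membership error is bounded by the contour perimeter, and the clipping bias
is negligible at the backgrounds used here.

One terminological decision: the per-cell "intensity ratio" reported
alongside box plots in this field is treated as the same quantity as the
normalized difference $d$ — the quantification defines only one statistic,
and both names are used for it here.

## DA calling decisions

* Per-cell threshold 0.3: reported DA loci put the statistic's medians
  between 0.53 and 1, treated/equal-accessibility loci between 0.08 and
  0.27, so 0.3 separates the regimes with margin on both sides.
  Configurable (`da_config()`).
* The locus-level criterion is the fraction 2/3 exactly, compared
  inclusively.
* The single-locus "non-random" test needs a second proportion; it is
  implemented as the two-proportion z against a pseudo-cohort of equal size
  at the null proportion 0.5 ("no preference for either homolog"). This is
  a design decision — the construction used in the original locus screens
  is not fully specified — and the pre/post use of the z-test, which is
  unambiguous, does not depend on it.
* Directional consistency: a DA call requires that more than 75% of flagged
  cells agree on which homolog is weaker; otherwise the direction is
  "mixed" and no call is made.
* No multiple-testing correction is applied across loci (per-locus
  $\alpha = 0.05$), matching how such screens are reported; a Bonferroni
  adjustment can be imposed by lowering `alpha`.
* Welch (unequal-variance) t is the default two-tailed t-test; with
  cohorts of different treatments there is no reason to assume equal
  variances.

## 3D depth and volume

Z-stacks are handled as `[section, row, col]` arrays with explicit geometry
(`zstack_geometry()`; 17 sections at 0.13 um steps by default, lateral pixel
0.04 um — the lateral scale is a configuration choice, always carried in
output, never assumed from the image). Segmentation thresholds the whole
stack — Otsu by default, or background + $3\sqrt{\text{background}}$ — and
keeps the 26-connected component containing a seed voxel. Depth is the
number of distinct sections containing mask voxels times the z step (a
contiguous-run mode exists but is off by default; with a single connected
component the two agree). Volume is exactly voxel count times
$\text{pixel}^2 \times \text{z step}$.

The global Otsu threshold assumes the stack's foreground is roughly
unimodal; with extreme inter-homolog asymmetry (one spot near the detection
floor) it locks onto the bright homolog and loses the dim one, so
asymmetric-pair analyses should use the background-based threshold — the
analysis scripts do. Otsu on a signal-free stack does not separate a
foreground at all; the segmenter detects that (foreground fraction > 25%)
and errors rather than returning a noise component.

## The synthetic-data generator

Spots are isotropic Gaussians (2D) or separable 3D Gaussians; the
point-spread function of the real instrument is unspecified, and a Gaussian
is analytically integrable, which is what makes the generator's ground
truth exact: the noise-free integrated intensity equals
$2\pi A \sigma^2$ to within discretization (< 0.5% on frames extending
beyond $5\sigma$), and the test suite checks the rendered sums against that
closed form. Noise is Poisson (optionally plus Gaussian read noise);
background is constant. A cohort draws each cell's true difference $d$ from
a DA or a null distribution, converts it to amplitudes via
$A_{bright,dim} = \tfrac{S}{2}(1 \pm d)$ at fixed amplitude sum $S$, places
the dim spot on the configured homolog for DA cells (uniformly at random
for null cells), and logs everything — per-cell seeds included — so every
scene is bit-reproducible.

Generator truth for the 3D case uses a per-voxel rule: a voxel is true
signal when its noise-free spot value exceeds $3\sqrt{\text{background}}$,
a section is in the true span when it contains at least one such voxel.
Defining truth with the generator's own fixed threshold keeps it independent
of whatever thresholding the analysis module applies.

Default study conditions (used by the tests and the acceptance script):
cohorts of 50 cells; DA regime with 85% DA cells and
$d \sim U(0.4, 0.9)$ on a consistent weaker homolog; null regime
$d \sim U(0, 0.2)$; spot sigma 2 px; pair amplitude sum 400 photons over
background 10; Poisson noise. These mirror the reported cohort sizes
(20-100 cells per target, mean 43) and the two observed regimes of the
statistic. The acquisition noise statistics of the real instruments are not
reported anywhere; Poisson shot noise over a constant background is the
conventional model and its parameters here are chosen, not derived.

What the generator does **not** emulate: structured-illumination
reconstruction artifacts, chromatic shift, uneven illumination, chromosome
banding, touching or overlapping signals, and non-Gaussian PSF tails.
Passing tests therefore demonstrate correctness of the measurement and
statistics on well-formed spot pairs, not robustness to every pathology of
real microscope data.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based (row, col)/(section, row, col) pixel-center
  coordinates, the R convention, used consistently in arrays, contours and
  output tables.
* Images are photon-count arrays in memory; TIFF export is 16-bit with the
  scale factor in a JSON sidecar, so integer counts round-trip exactly.
* A constant image yields an all-zero edge map (valid, not an error), and
  the GVF of a zero map is the zero field, converged at iteration zero.
* Equal-height peak candidates break ties lexicographically; all iterative
  solvers have explicit caps and report convergence flags.
* Both-homolog signal absence, empty contours/masks, seeds below threshold,
  and annuli fully excluded by the partner contour are errors carrying
  condition classes; the cohort driver converts them into one QC-log row
  per cell and continues.

## Problem sizes used by the shipped checks

The test suite exercises cohorts of 25-200 imaged cells (the 200-cell
cohort drives the bias/RMSE recovery check), 2,000 simulated null cohort
pairs for the z-test's size, 500 simulations for pre/post power, and
60 rendered z-stack pairs for the depth/volume pairing property; the
acceptance script re-runs a 50-cell cohort end-to-end plus three worked
depth examples. These sizes were chosen to give stable Monte-Carlo margins
for each property at desk scale.

## Known limitations

* Two spots per cell: multi-probe scenes and touching-signal splitting are
  out of scope, as are chromosome segmentation and karyotyping.
* The snake assumes a roughly convex, blob-like signal; filamentous or
  split hybridization signals would need a different initialization.
* Homolog identity is positional (lexicographic peak order); mapping to
  parental origin requires external cytogenetic markers and is metadata
  here, not computation.
* No photometric calibration, flat-field correction or deconvolution; the
  statistic's scale invariance is what makes this tolerable for ratio-based
  DA calling.
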
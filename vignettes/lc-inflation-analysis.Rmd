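---
title: "Measuring pressure-induced lamina cribrosa strain by digital volume correlation"
author: "lcstrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pressure-induced lamina cribrosa strain by digital volume correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lcstrain)
```

## The measurement problem

The lamina cribrosa (LC) is the porous collagen plate in the optic nerve
head through which retinal ganglion cell axons leave the eye. In ex vivo
inflation testing, a posterior scleral cup is pressurized (here 5, 10 and
45 mm Hg) while the collagen structure of the LC is imaged as a z-stack by
second-harmonic-generation (SHG) microscopy. The biomechanical outcome of
interest is the three-dimensional strain field the pressure step induces in
the LC, summarized per anatomical region, and how that strain response
changes after an intervention (for instance enzymatic removal of sulfated
glycosaminoglycans, or simply a second incubation).

`lcstrain` implements the full analysis chain for such experiments:

1. **Displacement recovery** between the reference-pressure and
   elevated-pressure volumes by fast-Fourier-transform based, iterative,
   subset digital volume correlation (DVC) — `runFidvc()`.
2. **Strain fields**: sixth-order trivariate polynomial smoothing of each
   displacement component, analytic gradients, the finite (Green-Lagrange)
   strain tensor, the maximum in-plane principal strain and maximum
   in-plane shear strain, and depth-averaged 2D maps — `computeStrain()`,
   `averageThroughZ()`.
3. **Regional anatomy**: a direct least-squares ellipse fit to manually
   picked LC/sclera boundary points, a 200 um exclusion disk about the
   central retinal artery and vein (CRAV), and the partition of the LC into
   eight analysis regions — `fitEllipse()`, `segmentRegions()`.
4. **Outcomes and statistics**: regional average strain magnitudes, LC
   thickness-change maps, DVC error analyses, exact Wilcoxon signed-rank
   tests of paired specimen-level outcomes and GEE linear models of the
   regional outcomes — `regionalAverageMagnitude()`, `thicknessChange()`,
   `runErrorSuite()`, `wilcoxonSignedRankExact()`, `fitGeeExchangeable()`.
5. **Synthetic ground truth**: an SHG-like phantom generator and analytic
   deformation warps, so that every stage can be validated against known
   answers — `generatePhantom()`, `deformation()`, `warpVolume()`,
   `runInflationAnalysis()`.

## Coordinates, units and conventions

The image X axis is the nasal-temporal direction, Y inferior-superior
(+Y superior), and Z anterior-posterior. Voxels default to 2.5 um in-plane
and 3 um axially (one z-slice every 3 um). Physical position is
`0-based voxel index x voxel size`; displacements are reported in
micrometres, strains are dimensionless. The nasal quadrant lies toward +X
for right eyes and toward -X for left eyes; laterality is a metadata field
of every volume. A recorded focal-depth adjustment between acquisitions is
added back to the anterior-posterior displacement component
(`applyFocalOffset()`, or automatically in `runFidvc()` from the volumes'
`focalOffset` metadata).

## The DVC engine

`runFidvc()` is a coarse-to-fine subset method. At each level of the
subset schedule (default 64 -> 32 -> 16 voxels, 50% window overlap at the
coarse levels) the deformed volume is warped by the current displacement
estimate, each reference subset is correlated with the corresponding window
of the warped volume by normalized cross-correlation computed in the
frequency domain, the integer peak is refined per axis by a three-point
Gaussian fit, and the residual offsets are accumulated. Iterations at a
level stop when the median residual falls below `tol` (default 0.02
voxels) or after `maxIterations` passes.

The final field lives on a regular node grid in the reference frame, at
half the finest subset spacing in-plane (8 voxels = 20 um by default) and
quarter spacing axially (4 slices = 12 um), so that short stacks keep at
least seven distinct axial planes — the minimum support for the
sixth-order polynomial smoothing that follows. Strain is then *evaluated*
every 4 in-plane pixels (10 um) and every 2 slices (6 um), the reporting
grid of the experimental protocol.

A node is masked invalid when any of four standard checks fails:

* **quality** — peak normalized correlation below `qualityThreshold`
  (default 0.25), the fate of dark, featureless regions;
* **zero variance** — a constant reference subset cannot be correlated;
* **peak sharpness** — if the correlation peak is flat along an axis
  (drop to its neighbours below `minPeakSharpness`), the texture does not
  constrain that displacement component. This is what masks the
  oversaturated scleral ring, which is bright but almost depth-invariant;
* **out-of-frame content** — windows whose material left the deformed
  field of view (tracked by the warp) are unobservable;

followed by a normalized-median outlier test against the 3x3x3 node
neighbourhood, the standard local-consistency filter for vector fields
from correlation methods. If fewer than `minValidFraction` (25%) of nodes
survive, the run aborts with a correlation-failure error rather than
returning an untrustworthy field. Masked fractions per stage are recorded
in the pipeline log so regional omissions are auditable.

## Strain computation

Each displacement component is fitted with one full trivariate polynomial
of total degree 6 (84 coefficients) by least squares over the valid nodes,
on coordinates affinely normalized to [-1, 1]^3. A single volumetric fit
(rather than per-slice fits) was chosen because the strain fields are
subsequently averaged through depth anyway. The displacement gradient is
the analytic derivative of the fit, and the strain tensor is the full
finite-deformation (Green-Lagrange) form

E = (grad u + grad u' + grad u' grad u) / 2,

whose quadratic term matters at the 2-10% stretches seen in inflation and
which is exactly zero under rigid rotation. From the in-plane components
the Mohr construction gives the maximum principal strain
E_max = (E_XX + E_YY)/2 + R and the maximum shear strain Gamma_max = R,
with R the Mohr radius. Gamma_max is the *tensorial* maximum shear, not
the engineering (doubled) shear; the closed forms are verified in the test
suite against a brute-force search over 1e5 in-plane orientations.

The five reported fields (E_XX, E_YY, E_XY, E_max, Gamma_max) are averaged
through Z as *signed* per-column means over valid nodes; E_max and
Gamma_max are averaged as fields rather than recomputed from averaged
components. Magnitudes are taken only at the regional-summary stage: the
regional outcome is the mean *absolute* strain over the region's valid
nodes, because signed averaging would let tensile and compressive
subregions cancel and understate how much strain the tissue experiences.

## Regional anatomy

The LC opening is described by an ellipse fitted directly (stable
Fitzgibbon constraint) to boundary points picked on a maximum-intensity
projection. The CRAV disk (radius 200 um about the manually picked vessel
center) is excluded from analysis. Along each ray from the CRAV center,
the central/peripheral boundary sits at the mid-radial distance between
the CRAV circle and the ellipse intersection of that ray — computed
per-ray rather than as a scaled ellipse, which matches the mid-radial
definition literally when the CRAV is off-center. Quadrants use the 45 and
135 degree bisectors about the CRAV center. The result is exactly eight
analysis regions (central and peripheral S/I/T/N), plus CRAV and
background labels retained for masking. On a circular test geometry the
pixel-counted region areas agree with the closed-form annulus areas to
better than 0.5% at 1 um resolution.

## Thickness change and error analyses

`thicknessChange()` correlates the volumes of two treatment states at the
same pressure and, per (X, Y) column, subtracts the mean anterior-band
axial displacement from the mean posterior-band axial displacement. The
bands are the anterior-most and posterior-most 10% (`bandFraction`) of
the imaged depth — band averages rather than single slices, for noise
robustness. Columns lacking valid nodes in either band are masked; rigid
axial motion cancels exactly.

Two error analyses mirror the experimental protocol:

* `baselineError()` correlates two nominally identical acquisitions (on
  synthetic data: two independent-noise renderings of the same phantom)
  through the full pipeline, reporting mean absolute displacement per axis
  and mean absolute in-plane strain per component. Synthetic duplicates
  contain no specimen creep, stage drift or tile-stitching seams, so these
  floors are optimistic relative to real acquisitions.
* `appliedDeformationError()` warps the reference stack by four canonical
  analytic deformations — a 10-pixel X and Y translation, a 3-slice Z
  translation, a 2% uniform in-plane stretch, and a 5% uniform Z
  compression — and reports recovered versus applied values, translations
  as mean valid displacements (pixels/slices) and stretches as 100 x the
  mean fitted displacement gradient (percent), so a 2% stretch is compared
  in stretch units rather than as its Green-Lagrange value 0.0202.

## Statistics

Specimen-level paired comparisons use the exact two-sided Wilcoxon
signed-rank test: with n <= 20 the null distribution of the positive-rank
sum is enumerated exactly (a convolution over doubled mid-ranks, handling
ties), zero differences are dropped, and the two-sided p is
2 x min(P(V <= v), P(V >= v)) capped at 1. Exactness matters at n = 6,
where the smallest attainable two-sided p is 2/64 = 0.03125 — a normal
approximation could not report it. The conventions for zeros and ties are
declared defaults; at these sample sizes they are also the only ones that
make the test exact.

Regional outcomes (eight per eye) are modelled by Gaussian GEE linear
models with identity link, clustering by eye, and an exchangeable
(compound-symmetry) working correlation — any two regions of the same eye
share one correlation; eyes are treated as independent. Four models are
fitted on the regional change in average strain magnitude: intercept-only,
change ~ baseline magnitude, change ~ central/peripheral location, and
change ~ age group. Standard errors are robust (sandwich) estimates, and
inference is Wald-normal, two-sided, at the 0.05 level with no multiplicity
correction. No GEE solver is available among the installed packages, so the
estimating equations are solved in-package (closed-form inverse of the
exchangeable working correlation, moment estimators for the scale and
correlation); tests verify exact agreement with ordinary least squares at
rho = 0, agreement of the sandwich covariance with a direct matrix
evaluation, and calibrated slope recovery on 200-cluster simulations.

## The synthetic phantom and what passing tests mean

`generatePhantom()` emulates the *appearance* of an SHG LC stack: an
elliptical LC filled with bright beam texture (thresholded, modulated
smooth Gaussian noise with an autocorrelation length of a few voxels —
broadband enough for subset correlation), an oversaturated peripapillary
scleral ring, a dark CRAV disk, optional dark non-correlating patches, and
additive Gaussian sensor noise, all deterministic for a fixed seed. It is
a texture stand-in, not a biological model: real LC beam morphology,
optical point-spread, depth attenuation and tile seams are deliberately
out of scope. Passing the synthetic benchmarks therefore demonstrates the
correctness of the *algorithms* under controlled ground truth, not the
accuracy of the method on any particular tissue.

`runInflationAnalysis()` runs the full synthetic experiment: for each
specimen a phantom, per pressure pair an analytic inflation deformation
(posterior bowing with in-plane stretch; the 5-10 mm Hg response is a
scaled-down version of the 5-45 mm Hg response), and per treatment state a
deformation amplitude — the after-treatment state multiplies amplitudes by
`effect` (default 0.8, a 20% reduction; 1 gives a null experiment).
Acquisition noise is drawn fresh for every imaging run from seeds derived
deterministically from the global seed, so a bundle is bit-reproducible.

## Problem sizes and numerical choices

* Error-protocol phantom: 256 x 256 x 64 voxels at 2.5/2.5/3 um.
* Synthetic experiment specimens: 240 x 240 x 48 voxels at 5 um in-plane
  and 3 um axially. The coarser in-plane sampling widens the field of view
  to 1.2 mm so that a realistically sized LC (semi-axes about
  500 x 450 um) surrounds the fixed 200 um CRAV disk; at 2.5 um sampling a
  desk-scale grid would leave the analysis annulus a sliver of the frame.
* Subset schedule 64/32/16, overlap 0.5, quality threshold 0.25,
  convergence 0.02 voxels: declared defaults — the experimental protocol
  delegates these to its correlation software and does not state them.
* Cubic (Catmull-Rom) interpolation for all warping; backward mapping with
  closed-form inversion for affine deformations and fixed-point iteration
  otherwise, with a sampled positive-Jacobian precheck.
* Tie-breaks and degenerate inputs: zero-variance subsets and flat
  correlation peaks are masked, not errors; all-zero paired differences
  give p = 1 with a warning; rank-deficient polynomial designs abort,
  naming the deficient axis.

## Known limitations

* The subset model assumes locally constant displacement within a window;
  strong intra-subset gradients bias the finest level slightly (visible as
  the residual few-tenths-of-a-percent error in the 5% axial compression
  case).
* Polynomial gradients are unreliable at the very boundary of the fitted
  domain; masking of out-of-frame and low-quality edge nodes keeps those
  areas out of the reported means, but a global degree-6 polynomial still
  under-resolves sharp local strain concentrations.
* Synthetic error floors omit creep, drift and stitching artefacts, so
  real-data baseline errors will be larger than the phantom's.
* The GEE treats eyes as independent clusters; paired-eye donors violate
  this mildly, and no small-sample correction is applied to the sandwich
  covariance (with 6 clusters its p-values are approximate).
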
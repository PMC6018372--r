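# lcstrain

Displacement and strain analysis for ex vivo inflation testing of the
human lamina cribrosa (LC), the collagenous plate in the optic nerve head
through which retinal ganglion cell axons exit the eye. Volumetric
second-harmonic-generation z-stacks of the same specimen at two pressures
(e.g. 5 and 45 mm Hg) are correlated to recover the 3D displacement field
the pressure step induces; strain fields derived from it quantify how
compliant the tissue is, regionally and before/after an intervention.

The package is aimed at ocular biomechanics labs running (or re-analysing)
LC inflation experiments, and at anyone who needs a tested, self-validating
R implementation of volumetric digital image correlation with strain
mapping.

## What it computes

* **Digital volume correlation (DVC)** — `runFidvc()`: fast-Fourier,
  coarse-to-fine (64 → 32 → 16 voxel subsets), iterative normalized
  cross-correlation with Gaussian subpixel peak fitting, quality /
  peak-sharpness / out-of-frame masking and a normalized-median outlier
  filter. Output: displacement components U_X, U_Y, U_Z (μm) on a regular
  node grid with per-node correlation quality.
* **Strain fields** — `computeStrain()`: sixth-order trivariate polynomial
  smoothing of each displacement component, analytic gradients, and the
  finite-deformation Green–Lagrange tensor
  E = ½(∇u + ∇uᵀ + ∇uᵀ∇u). In-plane measures follow the Mohr
  construction: E_max = (E_XX+E_YY)/2 + R, Γ_max = R with
  R = √(((E_XX−E_YY)/2)² + E_XY²). Fields are evaluated every 10 μm
  in-plane and 6 μm axially and depth-averaged (`averageThroughZ()`).
* **Regional anatomy** — `fitEllipse()` (direct least-squares conic fit of
  the LC boundary), `segmentRegions()`: a 200 μm CRAV exclusion disk,
  per-ray mid-radial central/peripheral boundary, and S/I/T/N quadrants by
  45°/135° bisectors — eight analysis regions. Regional outcomes are
  average strain *magnitudes* (`regionalAverageMagnitude()`).
* **Thickness change & error analyses** — `thicknessChange()` (posterior
  minus anterior band axial motion between treatment states),
  `baselineError()` (duplicate-stack correlation) and
  `appliedDeformationError()` (recovery of numerically applied
  translations/stretches).
* **Statistics** — `wilcoxonSignedRankExact()` (exact enumeration, valid
  with ties; at n = 6 the minimal two-sided p is 2/64 = 0.03125) and
  `fitGeeExchangeable()` (Gaussian GEE, compound-symmetry working
  correlation, cluster-robust sandwich errors) with the four standard
  regional models (`geeStrainModels()`).
* **Synthetic ground truth** — `generatePhantom()` (SHG-like LC phantom),
  `deformation()`/`warpVolume()` (analytic warps), and
  `runInflationAnalysis()` (a full seeded six-specimen experiment with a
  known treatment effect).

## Worked example: validating the DVC resolution on a phantom

```r
library(lcstrain)

cfg  <- runConfig(seed = 1)
report <- runErrorSuite(cfg, verbose = TRUE)
print(report)
```

```
Baseline DVC error (duplicate correlation):
 quantity        value  units
      U_X 5.052825e-03     um
      U_Y 4.758657e-03     um
      U_Z 1.280492e-02     um
     E_XX 9.840013e-05 strain
     E_YY 6.373874e-05 strain
     E_XY 5.913899e-05 strain
Applied-deformation recovery:
                case component applied recovered        error   units
 inplane_translation         X      10  9.992083 0.0079171736  pixels
 inplane_translation         Y      10  9.990104 0.0098956472  pixels
       z_translation         Z       3  2.999454 0.0005456016  slices
     inplane_stretch         X       2  2.034663 0.0346625517 percent
     inplane_stretch         Y       2  2.018688 0.0186875289 percent
       z_compression         Z      -5 -4.840065 0.1599354113 percent
```

Reading this: correlating two independent-noise renderings of the same
phantom (the "baseline" rows) puts the intrinsic displacement error at a
few hundredths of a micrometre and the strain error floor at about 1e-4.
Warping the stack by known deformations and re-running the pipeline (the
"applied" rows) recovers a 10-pixel in-plane translation to within 0.01 px,
a 3-slice axial translation to within 0.001 slices, a 2% in-plane stretch
to within 0.04 percentage points and a 5% axial compression to within 0.16
points — the method's resolution limits on ideal data.

An exact paired test of six same-sign specimen-level changes:

```r
wilcoxonSignedRankExact(c(-0.0063, -0.0081, -0.0036, -0.0041, -0.0050, -0.0029))
#> exact Wilcoxon signed rank: V = 0, n = 6, two-sided P = 0.03125
```

The full synthetic experiment (six specimens, 20% post-treatment
deformation reduction, DVC → strain → regions → statistics) is one call:

```r
bundle <- runInflationAnalysis(runConfig(pressurePairs = "5-45", seed = 1))
print(bundle)
```

## Layout

* `R/` — S4 classes (`ImageVolume`, `DisplacementField`, `StrainField`,
  `LcGeometry`, `PolynomialFit`) and the analysis modules.
* `src/` — Rcpp interpolation/warping kernels.
* `vignettes/lc-inflation-analysis.Rmd` — the methods vignette: model,
  assumptions, parameter choices, problem sizes, limitations.
* `inst/scripts/lc-inflation.R` — a thin CLI (`phantom`, `errors`, `dvc`,
  `all`) over the package functions.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
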
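---
title: "Methods: simulating and quantifying the beta sweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying the beta sweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling choices behind `bplquant`: what the
simulator emulates, how the reconstruction is optimized, how each metric is
operationalized, and where the package's behaviour is expected to differ
from a clinical scanner.

## The estimation problem

Penalized-likelihood ("BPL") reconstruction maximizes the Poisson
log-likelihood of the measured coincidence counts minus `beta` times the
relative difference penalty (RDP),

$$R(x) = \sum_j \sum_{k \in N_j} w_{jk}\,
  \frac{(x_j - x_k)^2}{x_j + x_k + \gamma\,|x_j - x_k|},$$

summed over ordered neighbor pairs. The penalty is zero on constant
images, positively 1-homogeneous (so its weight scales with the image's
count level), and its $\gamma |x_j-x_k|$ term shrinks the penalty on
large differences, preserving edges. Pairs with $x_j = x_k = 0$ are a
removable singularity and contribute zero. The gradient used by the
optimizer is the analytic derivative of this expression; both value and
gradient are implemented in compiled code and verified in the test suite
against a brute-force double loop and central finite differences.

**Tunable penalty parameters.**

* `beta` — dimensionless penalty weight, swept over 100–1000 in steps of
  50 (19 values) as in clinical practice.
* `gamma` (default 2) — edge preservation. The RDP literature's
  conventional value; exposed, not hidden.
* `neighborhood` (default 18-connectivity, i.e. 8 neighbors in a single
  slice) with weights $w_{jk}$ set to inverse Euclidean center distance in
  mm, normalized so a nearest neighbor has weight 1.
* `beta_scale` (default 3e-4) — the mapping from the conventional beta
  magnitudes onto *this* simulator's count level; the effective penalty
  weight is `beta * beta_scale`. Penalty strength relative to the
  likelihood depends on absolute counts, which differ between a clinical
  scanner and a desk-scale simulation, so the nominal grid is kept for
  interface parity and the scale factor was set once, by inspecting
  reconstructions of the image-quality phantom: at `3e-4` the sweep spans
  light-to-heavy smoothing while converging within a few dozen
  EM-equivalent iterations. Absolute beta values are therefore *not*
  comparable with any vendor implementation; only trends across the sweep
  are meaningful.

## The acquisition model

The simulator is deliberately minimal: slice-by-slice parallel-beam line
integrals (pixel-driven sparse matrix with linear interpolation onto
radial bins; 96 angles over 180 degrees, 128 bins of 2.73 mm by default),
an image-space Gaussian point-spread function (default FWHM 4.5 mm)
applied *before* projection, a global `count_scale` converting line
integrals to expected counts, and independent Poisson sampling per bin.
Attenuation and scatter are not simulated: the emulated data are
attenuation- and scatter-corrected, so the simulator generates the
corrected data directly. There is no time-of-flight and no detector
geometry beyond parallel-beam.

The PSF is the sole source of partial-volume effect. The reconstruction's
own system model *omits* the PSF by default, so resolution losses remain
in the image and recovery coefficients fall below one for small spheres —
without this the partial-volume-correction stage would have nothing to
correct. Resolution modelling inside the reconstruction is available as
`model_psf = TRUE` (the blur kernel is symmetric, hence self-adjoint in
the gradient); note that with it enabled the contrast-versus-noise
behaviour of the sweep changes qualitatively (lesion contrast is highest
at low beta), which is expected but differs from the package's default
study conditions.

The default `count_scale = 0.05` yields roughly 2–4 million expected
counts per phantom (about 10^5 per slice), and phantom concentrations are
on the absolute scale of an FDG study (background 3.3 kBq/mL in the
image-quality phantom; lung 2.5 / soft tissue and liver 5 kBq/mL in the
clinical phantom), which puts the simulated noise texture in a clinically
plausible range.

## Phantoms

**Image-quality phantom.** Six spheres (10, 13, 17, 22, 28, 37 mm) at
13.2 kBq/mL on a 57.2 mm ring, background 3.3 kBq/mL (4:1 contrast),
inside an elliptical body of 125 x 100 mm semi-axes — a desk-scale body
that still hosts twelve 37 mm background ROIs. Voxelization uses
corner-subsampled fractional fill (3^3 subsamples per voxel) to reduce
staircase bias on the 10 mm sphere; the summed voxel volume of a 37 mm
sphere is within 1% of $\pi d^3/6$.

**Clinical-lesion phantom.** A thorax-like body containing two low-uptake
lung fields (2.5 kBq/mL), a uniform liver-like reference sphere (5
kBq/mL) used only for noise measurement, and spherical lesions at 4:1
lesion-to-lung contrast placed by seeded rejection sampling with a 5 mm
clearance. The default lesion mix mirrors the study design: 7
sub-centimeter lesions drawn uniformly from [5.7, 9.9] mm and 16 medium
lesions from [10, 29.4] mm. With the default SUV context (300 MBq
decay-corrected dose, 60 kg body weight) the liver sits at SUV 1.0, lung
at 0.5, lesions at 2.0.

## Optimizer

BSREM-style subsetized preconditioned gradient ascent with the EM
preconditioner `x / sensitivity` and relaxation schedule
`alpha_n = alpha0 / (1 + decay n)` (defaults `alpha0 = 1`, `decay = 0`).
With one subset and `beta = 0` one update *is* one ML-EM iteration, which
makes the unpenalized limit exactly testable (count preservation, fixed
point, point-source recovery). For `beta > 0` with one subset, a monotone
safeguard halves the step if a full iteration would decrease the
penalized objective; an unrepairable decrease is flagged in the result
status, never silent. With multiple subsets the full objective is not
guaranteed monotone per pass (the classic OSEM-style limit cycle), so the
safeguard is bypassed and the trace still records the objective.
A nonnegativity floor of 1e-9 kBq/mL keeps the RDP denominator and the
log terms defined. Iteration stops early when the relative objective
change drops below `stop_tol` (1e-6).

Sweeps default to 12 full iterations of 4 subsets, which reproduces the
40-iteration single-subset objective to ~1e-5 relative on the default
problem at a fraction of the cost.

## Quantification choices

* **Sphere uptake $A_M$ (RC and CR)** is measured in the sphere's known
  physical volume — the simulation's equivalent of a VOI delineated on CT,
  which is how the image-quality protocol defines it. A
  42%-of-maximum isocontour drawn on the reference-beta image and
  propagated would be several times larger than the smallest sphere (the
  42% level of a PSF-blurred 10 mm object lies well outside it), and the
  mean over such a region is nearly invariant under extra smoothing, which
  would erase exactly the small-sphere beta sensitivity the study is
  about.
* **Lesion VOIs** use the clinical workflow: a 42% SUVmax isocontour
  segmented on the reference-beta image (default 350) and propagated
  unchanged to every other beta. Segmentation hill-climbs from the seed to
  the local maximum and takes the 26-connected suprathreshold component,
  bounded to 30 mm around the peak (`max_radius_mm`) so that a component
  cannot leak through suprathreshold noise into neighboring structures.
  Per-sphere/lesion seeding uses the known centers.
* **Background ROIs** (NEMA scheme): 12 circles of the analyzed sphere's
  diameter on the central sphere slice and at slice offsets ±1, ±2 — 60
  ROIs total. Placement is deterministic (2 mm candidate lattice, greedy
  from the periphery inward) with 4 mm clearance from sphere surfaces and
  8 mm from the body edge; those margins are what a 262 mm desk-scale
  field can host for twelve 37 mm ROIs. BV is the SD over the 60 ROI
  means divided by their mean.
* **SUVpeak**: the maximum mean over a 1 mL spherical kernel (~12.4 mm
  diameter) centered at each VOI voxel; kernel voxels outside the grid are
  dropped from the mean; ties break to the smallest linear index (scan
  order). Verified against exhaustive search.
* **SNR**: lesion SUVmax over the SUV standard deviation of a 1.0 cm
  spherical VOI at the liver-reference center. **CNR**: (lesion VOI mean −
  lung background mean) / lung background SD, with the background sampled
  in a shell annulus between 1.5x and 2.5x the VOI-equivalent radius,
  clipped to the lung compartment and excluding all (dilated) lesions —
  the simulation's rendering of "neighboring lung tissue".
* **Reference beta** for VOI definition defaults to 350 and is
  configurable.

## Partial-volume correction

Per beta, RC (%) is regressed on sphere diameter (mm) by ordinary least
squares over the six spheres at the single 4:1 contrast (multi-contrast
lookup tables are out of scope). A lesion's RC is predicted from its
truth-catalog diameter (standing in for a CT measurement), converted to a
fraction, clamped to (0.05, 1] with a warning, and flagged as extrapolated
outside the fitted 10–37 mm range — notably for every sub-centimeter
lesion. Corrected SUV = uncorrected / RC, so the correction never
decreases an SUV. Whether the original analysis regressed percent or
fraction is not stated anywhere we could find; percent-vs-mm is used here
and recorded as a package decision.

## Study statistics

Pearson correlations and paired t-tests wrap the standard R
implementations and are cross-checked in the tests against textbook
formulas; Cohen's kappa treats the 1–5 ratings (halves allowed) as
unweighted nominal categories. SUV-versus-beta correlations are computed
on per-beta group means (the curves a reader sees in the study's figures):
pooled per-lesion pairs are dominated by between-lesion size variance in a
23-lesion sample and attenuate every correlation toward zero. Statistical
endpoints on simulation are sign/trend statements only — p-values from 23
real nodules are not reproducible from synthetic data, and the published
inter-reader kappas cannot be recomputed because the per-reader ratings
behind them are only partially printed; the packaged score table supports
the score aggregation and best-beta selection endpoints.

## Problem sizes and determinism

The default study runs on a 96 x 96 in-plane grid at 2.73 mm with 32
slices of 2.8 mm (the clinical pixel/slice spacing on a reduced matrix;
256 x 256 is available by configuration), 19 betas, and 3 noise
replicates; one sampled sinogram per replicate is reused across all betas,
matching a design where one acquisition is reconstructed repeatedly. All
randomness flows through explicit integer seeds (placement and noise seeds
are separate), reconstruction is deterministic given counts and
parameters, and identical configurations reproduce byte-identical metric
tables.

## Known limitations

* Absolute RC/SUV levels, and the beta magnitudes themselves, are not
  comparable with any specific scanner or vendor reconstruction; only
  directions and orderings across the sweep are.
* On *noiseless* (expectation) data the background-variability metric
  loses its meaning as a noise measure: the residual variability across
  background ROI means is deterministic spill from the spheres plus
  body-edge rolloff, and since higher beta smooths the sphere edges
  further, noiseless BV *increases* slightly with beta (fractions of a
  percent) instead of decreasing. The decrease of BV with beta is a
  noise-driven effect and is reproduced by the noisy replicate sweeps.
* For sub-centimeter lesions the 1 mL SUVpeak kernel is larger than the
  lesion, so raw SUVpeak is nearly conserved under extra smoothing, while
  the RC regression extrapolated below 10 mm falls steeply with beta;
  dividing by it over-corrects, leaving a small but systematic upward
  drift of PVC-corrected SUVpeak across the sweep (its coefficient of
  variation stays small, but its correlation with beta is positive rather
  than near zero). This is the regime the original analysis itself flags
  as uncovered by the phantom model (no sphere below 10 mm); a correction
  scheme designed for sub-resolution lesions would need either smaller
  calibration objects or an image-domain method, both out of scope.
* Lesions are spheres in uniform lung; spill-in from adjacent hot
  structures, respiratory motion, and CT-vs-PET misregistration are not
  emulated, so passing trend tests here says nothing about those effects
  in real data.
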
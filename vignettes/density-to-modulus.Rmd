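---
title: "From CT grayscale to voxel-wise Young's modulus: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From CT grayscale to voxel-wise Young's modulus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qct2e)
```

## The problem

Finite-element models of bone need a Young's modulus per element, but a CT
scan delivers integer grayscale values on a scanner-specific scale. `qct2e`
implements the standard QCT route from one to the other: calibrate the
grayscale scale against a phantom of known densities, convert the calibrated
bone-mineral density to wet apparent density, and map apparent density to
modulus with a law that treats air, trabecular bone and cortical bone as
distinct materials. This vignette explains each stage, the tunable
parameters, and the design decisions taken where conventions genuinely
diverge.

## Stored values, Hounsfield units, and why calibration uses stored values

DICOM CT pixels are stored integers; the modality rescale
`HU = m * stored + b` (slope/intercept tags (0028,1053)/(0028,1052))
recovers Hounsfield units, with water at 0 HU and air at −1000 HU.
`read_dicom_series()` never rescales: the volume keeps raw stored values
plus `m` and `b` as metadata. When the tags are absent the DICOM default
`m = 1, b = 0` is assumed with a loud warning, because the calibration
depends on stored-value consistency rather than on the absolute unit.

The calibration regression itself operates on **stored** grayscale values,
not HU. Scanner software typically measures in HU and converts back to the
stored scale; since both scales are affine images of each other, only
internal consistency matters, and stored values are what the voxel data
actually contain. Functions that accept HU (`hu_to_stored()`) convert
through `m`, `b` first.

## Phantom sampling

Two estimators of an insert's mean grayscale are provided:

* `sample_profile_line()` — uniform steps along a user-drawn line with
  trilinear interpolation. The default step is half the smallest voxel
  spacing: fine enough that the line mean is close to the continuous line
  integral, coarse enough to stay cheap. The interpolation scheme of the
  original measurement tools is unspecified in general; trilinear is the
  common default and is exactly reproduced by the tests on affine fields,
  where trilinear interpolation is error-free.
* `sample_cylinder_roi()` — the mean over all voxel centres inside a
  cylinder. Volume averaging suppresses noise by `1/sqrt(n)` and is the
  recommended estimator; the profile line exists because it mirrors how
  operators actually measure.

Both return mean, SD and count, so the regression can be audited.

## The calibration fit

`fit_calibration()` is ordinary least squares with density as the response
and grayscale as the predictor ("grayscale relates to density", so density
is predicted from grayscale; no weighting is applied because insert
variances are near-identical by construction). Phantom density scales are
linear by design, so R² below 0.99 (configurable) triggers a warning — in
practice a low R² means a mis-measured insert, not a nonlinear scanner.

With five inserts the fit has three residual degrees of freedom. Users
propagating the reported `slope_se`/`intercept_se` should use t₃ quantiles,
not normal ones: a ±3·SE interval covers the truth only ~94% of the time at
n = 5, a direct consequence of estimating the residual variance from three
degrees of freedom.

## Density conversions and the material law

Calibrated QCT density (mg/cm³) becomes wet apparent density (g/cm³) by the
Lotz linear relation `rho_app = 0.0012 * rho_CT + 0.17`; the slope's units
(g/cm³ per mg/cm³) fix the unit convention throughout the package. Negative
densities are deliberately retained at every stage — they are what drives
the air branch.

The modulus map is piecewise:

| branch | condition | modulus |
|---|---|---|
| air | ρ ≤ 0 | 1 MPa |
| trabecular | 0 < ρ ≤ cutoff | max(11417.6 · ρ^1.89, floor) MPa |
| cortical | ρ > cutoff | 17,000 MPa |

Three decisions here were genuinely open:

* **Boundary assignment.** The defining inequalities (ρ < 0, 0 < ρ < 1,
  ρ > 1) leave ρ = 0 and ρ = cutoff unassigned. We assign ρ ≤ 0 to air and
  0 < ρ ≤ cutoff to trabecular. The choice is measure-zero for continuous
  data; putting the cutoff itself on the trabecular side avoids applying the
  upward jump to 17,000 MPa one floating-point ulp early.
* **Trabecular floor.** `modulus_floor` (default 1 MPa, the air modulus)
  clamps the power law so that vanishing positive densities cannot produce
  moduli below air — sub-air stiffness is unphysical and ill-conditions FE
  solves. Setting `modulus_floor = 0` disables the clamp for users who want
  the raw power law.
* **The 1.28 transverse factor.** The default trabecular coefficient
  11,417.6 MPa already includes the 1.28 transverse-stiffness adjustment to
  the underlying Morgan-type power law. `material_law()` also accepts a
  `base_trab_coefficient`, to which it applies the factor explicitly, for
  users starting from an unadjusted coefficient.

The law is non-decreasing with the default constants but discontinuous at
the cutoff: E jumps from 11,417.6 to 17,000 MPa. `convert_volume()` reports
this jump (`cutoff_jump_MPa`) in its summary because it is a modelling
artifact users should be aware of, and `validate_material_law()` warns if a
custom cutoff makes the trabecular branch exceed the cortical constant
(a non-monotone law).

`convert_volume()` composes the three stages voxel-for-voxel and returns the
modulus volume, per-branch voxel counts (which always partition the volume),
and optionally the intermediate density volumes with their unit tags
(mg/cm³ → g/cm³ → MPa).

## Synthetic data: what it emulates and what it does not

`make_phantom_volume()` emulates a calibration acquisition: insert cylinders
of known density in a water-equivalent background, stored values produced by
inverting a known density line and rounding to integers, then additive
Gaussian noise on the stored scale, clipped to signed 16-bit with clip
events counted. The default design uses five inserts of 0, 100, 200, 400
and 800 mg/cm³ — a typical solid-phantom range — about 390 voxels per
insert, a line of slope 0.8 mg/cm³ per stored unit (chosen so the default
densities sit on exact integer stored values, making the noise-free design
invertible to machine precision), and noise SD 20 stored units,
representative of clinical CT noise in soft-tissue-equivalent material.

`make_bone_volume()` builds a long-bone cross-section: a cortical shell
(everything outside the interior radius), a trabecular interior with integer
densities drawn uniformly from 100–500 mg/cm³, and an optional air pocket.
Stored values equal the densities (identity calibration), and the generator
carries the modulus volume computed by the same closed-form law — so the
pipeline can be checked bit-for-bit against ground truth, all three branches
exercised.

All randomness uses R's Mersenne-Twister generator with inversion sampling
under a recorded seed; identical seeds reproduce volumes (and the DICOM
series written from them) byte-for-byte.

What the generators do **not** model: beam hardening, scatter, partial
volume, spatial noise correlation, scanner transfer functions, or metal
artifacts. Passing tests therefore demonstrate the correctness of the
calibration and conversion arithmetic under idealized acquisitions, not
robustness to scanner physics; on real scans, phantom placement and artifact
avoidance remain the user's responsibility.

## I/O formats and numerical tolerances

* **DICOM** (own minimal codec): single-frame CT slices, Explicit VR Little
  Endian, 16-bit pixels. Slices are ordered by the projection of
  ImagePositionPatient onto the slice normal — never by filename. Geometry
  and integer values round-trip exactly. Floating-point volumes are
  re-encoded to unsigned 16-bit with intercept 0 and slope
  `max(value)/(2^16 − 1)` recorded in the rescale tags, preserving relative
  precision across the range; values return within one encoding step.
* **NIfTI-1** (via RNifti): float64 payload, lossless values. The NIfTI-1
  header stores the affine as float32, so geometry round-trips to single
  precision (~1e-7 relative), the format's own limit.
* **MetaImage** (own codec): float64 or int16 payload; header and values
  round-trip exactly.

Internal world coordinates follow the DICOM patient system (LPS); NIfTI's
RAS convention is converted at the boundary by negating the first two affine
rows. Arrays are ordered (slice, row, column) with 0-based indices in the
index↔world maps.

## Material binning for FE export

`bin_materials()` reduces the continuous trabecular modulus range to
`n_bins` materials (default 10), either equal-width in modulus or equal-width
in apparent density (edges placed on the power-law image of an even density
grid). Air and the cortical constant always keep their own reserved bins, so
binning never mixes materials across branches. Representatives are within-bin
means; counts always sum to the voxel total. The solver export writes one
isotropic elastic material per occupied bin; the Poisson ratio it needs is
not derivable from any density conversion, so it is a configuration constant
(default 0.3) and the output header says so explicitly.

## Problem sizes and test design

The test-suite fixtures are sized for fast, exact checks: phantoms of
8×40×40 voxels (≈390 voxels per insert), bone volumes of 12×32×32, vectorized
versus per-voxel-loop equivalence on twenty random 16³ volumes, monotonicity
on a 10⁵-point density grid, and calibration-recovery coverage over 100
seeded phantom acquisitions. Reference readers (pydicom, SimpleITK) serve as
independent oracles for the writers in the image-I/O tests.

## Known limitations

* Only uncompressed Explicit-VR-little-endian single-frame DICOM is read or
  written; enhanced multi-frame CT and compressed transfer syntaxes are out
  of scope.
* The material law is isotropic and site-agnostic; anisotropic tensors and
  site-specific power laws are not modelled.
* The calibration is a single global line per series; it cannot correct
  spatially varying artifacts (beam hardening, scatter) — scanning the
  phantom together with the anatomy mitigates scanner drift but not
  in-image artifacts.
* With few inserts, fitted standard errors are t-distributed with few
  degrees of freedom; ±3·SE intervals are not "3 sigma" guarantees.
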
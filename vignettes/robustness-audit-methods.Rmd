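---
title: "Methods: dosimetric robustness auditing of synthetic arc plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosimetric robustness auditing of synthetic arc plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`rtrobust` evaluates how fragile the dose-volume quality of an
intensity-modulated photon plan is under two families of clinically
motivated uncertainty: rigid patient-setup errors and systematic
multi-leaf collimator (MLC) miscalibration. Robustness is always
quantified as *differences to the engine's own nominal scenario*: the same
simplified engine computes both the unperturbed and the perturbed dose, so
engine-specific features of the depth-dose and penumbra model largely
cancel in the comparison. This is the same rationale that justifies
recomputing clinical plans in a single reference dose engine when plans
from many sources are compared: absolute dose fidelity matters less than
the *response* of each plan to a perturbation.

The pipeline is fully synthetic: a case generator produces phantoms,
structure sets and normalized multi-phase arc plans, so every stage is
testable without any external data set.

### Coordinate and rotation conventions

The patient frame is right-handed with x = LR (+x toward patient left),
y = AP (+y anterior) and z = SI (+z superior). A setup error is a rigid
6-DOF transform: translations (`tx`, `ty`, `tz`) in mm and rotations
pitch (about LR), yaw (about AP) and roll (about SI) in degrees. Audit
protocols typically quote only magnitudes per axis, so one rotation
convention has to be pinned: we use fixed extrinsic axes composed as
`R = Rz(roll) Rx(pitch) Ry(yaw)`, rotation about the isocenter,
translation applied after rotation. For the +-3 degree range relevant
here the ordering effect is second order, but it is explicit and tested
(`transformMatrix`, `decomposeTransform`).

Transforms describe *patient* displacement from the planned position.
Dose under a scenario is computed by moving the beam frame by the inverse
transform while the voxel lattice stays fixed. This avoids interpolating
dose grids (no "dose-cloud shifting"): every scenario dose is a genuine
recomputation.

### Dose engine

The engine (`computeDose`, kernel in C++) is a divergent point-source
model:

* the MLC aperture of each control point, weighted by its MU, defines a
  fluence map at the isocenter plane (1 inside the aperture,
  `leafTransmission` outside), convolved with an isotropic Gaussian of sd
  `penumbraSigma`;
* each body voxel receives `fluence(projection) x exp(-mu * d_rad) x
  (SAD / r)^2 x output`, where `d_rad` is the radiological depth obtained
  by 1 mm fixed-step ray marching through the body mask (the phantom is
  water-equivalent) and `r` the source-voxel distance;
* contributions are summed over control points; voxels outside the body
  are exactly zero.

Defaults: SAD 1000 mm, penumbra sigma 3 mm, attenuation 0.005/mm, leaf
transmission 1.5%, 5 mm leaves, 2.5 mm grid spacing (the audit's
calculation voxel size). Only the voxel size is prescribed by the audit
protocol; the others are generic 6 MV-like values and all are
configurable. The build-up region is deliberately ignored (pure
exponential depth dose): a documented simplification, acceptable because
every reported quantity is a difference between two doses computed with
the same model. Jaws and interleaf effects are not modelled; the aperture
is defined solely by the MLC. An arc is represented directly by its
control-point list (a contribution model, not a delivery simulation).

The MLC miscalibration parameter delta moves every left tip by `-delta`
and every right tip by `+delta` (per-tip convention: the gap changes by
`2 delta`), including parked pairs, since a real bank miscalibration
affects every leaf; over-closed pairs clamp at the gap midpoint. Positive
delta therefore means a wider field opening.

### Scenario suite

`buildScenarioSuite()` reproduces a 49-scenario audit protocol:

* one scenario with random setup errors only, Gaussian with sigma 2.0 mm
  per translational axis and 0.5 degrees per rotational axis, redrawn
  independently every fraction (inter- and intra-fraction motion are
  folded into a single per-fraction model, which is what an accumulated
  dose can resolve);
* 18 systematic translations (+-2, +-3, +-5 mm in AP, SI, LR), each
  combined with the random model; the 5 mm shifts are exploratory
  worst-case scenarios and are excluded from the headline worst-case
  group (`sys_trans_le3`);
* 24 systematic rotations (+-0.5, 1, 2, 3 degrees in pitch, yaw, roll),
  likewise combined;
* 6 systematic MLC offsets (+-0.5, 1, 2 mm), with no setup component.

Random and systematic components compose as `systematic o random`
(systematic applied last); at these magnitudes ordering is second order,
but fixed. Each scenario draws from its own stream, seeded by a stable
hash of (master seed, scenario name), so adding scenarios never perturbs
the draws of existing ones; each scenario is an independent realization
(a configuration option to share one stream across scenarios was
considered and rejected as the less common convention, since the single
recorded seed already makes the whole suite reproducible). Whether random
rotations should be redrawn per fraction or fixed per treatment is not
prescribed by typical protocols; per fraction is used, consistent with
treating them as inter-fraction setup errors.

### Fraction-wise accumulation

For setup scenarios, each fraction of each phase is computed with that
fraction's sampled transform at per-fraction MU (phase dose divided by
the derived fraction count) and summed; random draws continue across the
concatenated fraction sequence of the phases and the systematic component
is shared, because a systematic error does not re-randomize between
courses. Fractions with bitwise-identical transforms are computed once
and weighted by multiplicity — a pure optimization that also guarantees a
scenario with all perturbations zero reproduces the nominal dose
*bitwise*. MLC scenarios are computed once per phase with the perturbed
plan and identity setup. Fraction weighting is uniform (per-fraction dose
= phase dose / n); non-uniform fractionation is out of scope.

The accumulation has a classical sanity limit: for a translations-only
random model on a laterally homogeneous slab, the expectation of the
accumulated dose is the nominal dose convolved with the 3-D Gaussian of
the setup sigma (the static-dose-cloud approximation). The test suite
verifies 2% RMS agreement in the field core at 200 fractions and recovers
sigma = 2 mm from the quadrature broadening of the 80-20 penumbra within
+-0.4 mm.

### Dose-volume endpoints

Endpoints follow the audit convention: D98% and D2% of the CTV (coverage
and hot spot), mean dose for parallel organs at risk, and the near-max
dose D0.03cc for serial organs; PRVs inherit their serial parent's
endpoint. The DVH rule is nearest-rank on voxel doses with full-voxel
membership (voxel-centre inclusion, no partial volumes): sort member
doses descending, request volume `V` (from percent or cc), return
`d(ceil(V / v_voxel))` clamped to the valid range. Nearest-rank was
chosen because it is exactly checkable against a brute-force
cumulative-volume walk (the suite does this on 1000 random structures);
interpolated DVH variants differ by at most one voxel's dose and are not
implemented. Differences are signed (`scenario - nominal`) and the
worst case of a scenario group is the signed difference of the largest
absolute value, ties broken by suite order — signed, so hot and cold
deviations remain distinguishable. No renormalization is applied to
scenario doses.

### Synthetic cases

Three built-in templates emulate the geometric logic of a brain case and
two head-and-neck cases:

* `brainlike`: one phase, 60 Gy in 30 x 2 Gy, prescribed to 50% of the
  PTV, 5 mm CTV-PTV margin;
* `hn-unilateral`: elective phase 50 Gy to 95% of the elective PTV plus a
  separate (non-integrated) boost course to 70 Gy on the summed plan,
  3 mm margins;
* `hn-bilateral`: 50 / 66 / 70 Gy over three phases, 3 mm margins.

The case-A prescription statement exists in two traditions (to 50% or to
95% of the PTV); the 50% median-dose form is the default here and the
coverage statement is a per-phase field, so either can be requested.
Fraction counts are derived from the prescription statements (e.g. 30 for
the brainlike case, 25 + 10 for the two-phase case), never hard-coded.

Each case has a serial OAR abutting the PTV (sub-voxel gap), a parallel
OAR lateral to the target and a distant OAR far from target and beam
path (clearance >= 60 mm by default); head-and-neck cases carry a 3 mm
PRV around the serial OAR. Margins are realized as Euclidean expansions
of the analytic signed-distance function before rasterization — exactly
the continuous morphological dilation. The ellipsoid distance uses the
normalized-radius approximation (exact for spheres); expansion oracles in
the tests therefore use spheres and capsules, whose distances are exact.
PTVs are trimmed 3 mm from the body surface.

Plans are geometric conformal arcs: 360 degrees, 36 control points by
default, apertures conforming per leaf row to the BEV projection of the
phase PTV plus a 5 mm aperture margin, uniform MU before normalization.
There is no inverse optimization — the generator emulates the geometry
and normalization statistics of clinical arc plans, not their modulation.
Consequently the synthetic plans are *more* robust to MLC perturbations
than highly modulated clinical VMAT (fewer, larger apertures) and carry
no OAR-sparing gradients; passing tests demonstrate the audit machinery
and the qualitative ranking of uncertainties (abutting serial structures
most sensitive, distant structures least), not clinical effect sizes.
Normalization solves one MU scale factor per phase (monotone 1-D
root-find) so the coverage statement holds on the accumulated nominal
dose, phase by phase in prescription order with earlier phases' dose
included for boost coverage.

## Numerical choices

* Fluence maps at 0.5 mm resolution; Gaussian penumbra applied as a
  separable convolution with constant extension at the closed-leaf
  transmission level; bilinear fluence lookup in the kernel.
* Ray marching step 1 mm, nearest-neighbour mask sampling, rays clipped
  to the lattice bounding box. Depth quantization is sub-percent in dose
  and common to nominal and scenario doses.
* Nearest-rank index computed as `ceil(V / v_voxel - 1e-9)` to keep exact
  integer volumes on their exact rank.
* Normalization root-finds to a relative tolerance of 1e-10; prescription
  checks in the tests use 0.01 Gy.
* Degenerate inputs fail loudly: empty structures, non-congruent lattices,
  non-finite transform components and over-requested D_cc volumes (which
  clamp to the minimum dose with a warning) are all covered by tests.

## Problem sizes

The package's own studies run at two resolutions, chosen once as the
desk-scale conditions of the shipped examples: full 49-scenario audits
with fraction-wise accumulation on the brainlike case at 5 mm grid
spacing and 24 control points (a complete audit in a few minutes on one
core), and nominal-dose worked examples (prescription normalization) at
the protocol's 2.5 mm voxel size with 36 control points. The physics
kernel is identical at both resolutions.

## Known limitations

* Homogeneous water-equivalent phantom; no heterogeneity corrections, no
  build-up, no collimator rotation, no tongue-and-groove or interleaf
  leakage, no couch model.
* Apertures are geometric; clinical modulation (and hence clinical MLC
  sensitivity) is not reproduced.
* Random uncertainty of the MLC itself is not simulated (log-file studies
  show it is dosimetrically negligible next to miscalibration); only
  systematic MLC offsets are modelled.
* Worst-case aggregation scans the discrete scenario set; it is not a
  continuous worst-case optimization.
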
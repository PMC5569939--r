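---
title: "Measuring facial-palsy rehabilitation with 2D-image-fitted 3D face models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring facial-palsy rehabilitation with 2D-image-fitted 3D face models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palsy3d)
```

## The measurement problem

Facial palsy weakens the facial musculature, usually on one side and
often unequally between the upper (eye/brow) and lower (mouth) face.
Rehabilitation aims to restore movement, and outcomes improve when the
therapy plan is adjusted against objective feedback. `palsy3d`
implements one route to such feedback from plain 2D photographs: lift
sparse 2D landmarks to a dense 3D reconstruction by fitting a linear 3D
morphable model (3DMM), then quantify a prescribed movement (e.g. "smile
as far as you can") as geometric displacement over clinician-chosen mesh
regions, and track how that quantity changes across sessions.

The package deliberately starts *after* landmark detection: 2D landmark
fitters (DRMF-style constrained local models, cascaded-CNN methods such
as PIFA, or manual annotation) are consumed as `.pts` files. Training
or running those detectors is out of scope, but the package implements
the hybrid strategy of combining two detectors' outputs — one fitter
for the mouth subset, where mouth-specialised methods do better, and
another for everything else (`merge_hybrid()`).

## Model and fitting procedure

**Shape model.** A face is `S = S̄ + A_id (α_id ⊙ σ_id) + A_exp (α_exp ⊙
σ_exp)`, with the bases stored flattened so that row `3(v−1)+c` holds
coordinate `c` of vertex `v` (the column-major flattening of a `3 × m`
matrix; a round-trip unit test pins this convention). Coefficients are
kept in standard-deviation units — `construct_shape()` multiplies by the
per-component scales internally — so that a ridge penalty on the
coefficients is scale-free and a coefficient of 1 always means "one
trained standard deviation", whatever the component.

**Camera.** Weak perspective: `s_2d = f · P · R · X + t` with
`P = [[1,0,0],[0,1,0]]`. This is adequate when depth variation across
the face is small relative to camera distance (frontal-ish photographs
at arm's length or more). Three conventions are fixed for
reproducibility, since "pitch, yaw, roll" alone does not determine a
matrix:

* composition order `R = R_z(roll) · R_y(yaw) · R_x(pitch)`,
  right-handed axes;
* image coordinates with origin top-left, u right, v down, in pixels
  (matching `.pts` files);
* only the image-plane translation is stored. A 3D translation applied
  before rotation is not fully observable under orthographic
  projection — its component along the rotated optical axis vanishes —
  so the pose keeps the identifiable `t = f·P·R·t_3d`
  (`translation_from_3d()` performs the reduction). This removes a
  non-identifiable degree of freedom from fitting.

**Pose sub-solve.** `estimate_pose()` removes centroids, solves the
unconstrained `2 × 3` linear map from centred 3D to centred 2D by least
squares, and projects it onto the nearest scaled row-orthonormal matrix
via SVD (scale = mean singular value). The third rotation row is the
cross product of the first two, so the result is always a proper
rotation (`det = +1`) even for mirror-flipped observations. On exact
weak-perspective data the generating pose is recovered to machine
precision. Angle extraction from the matrix uses the closed form of the
documented composition; at gimbal lock (`|cos(yaw)| < 1e-9`) pitch and
roll are not separately identifiable and the branch is resolved by
setting roll to 0.

**Coefficient sub-solve.** At fixed pose the projected landmarks are
affine in the coefficients, so the ridge-penalized reprojection
objective has a unique closed-form minimizer, computed as one QR solve
of the augmented system (`solve_coefficients()`). With both ridge
weights zero a rank-deficient system raises an error advising positive
weights rather than returning one of many minimizers.

**Alternation.** `fit_face()` starts from the mean face (coefficients
zero) with the pose estimated against the mean-shape landmarks — a
deterministic, randomness-free initialization — and alternates the two
sub-solves. Each step is the exact minimizer of its sub-problem, so the
penalized objective cannot increase. The *reported* residual is the
ocular-scaled reprojection RMSE (data term only); should a step increase
it through floating-point effects near a fixed point, the previous
iterate is kept and iteration stops, which makes the non-increasing
residual trace a structural guarantee rather than an empirical
observation.

### Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_iters` | 50 | iterations | the alternation contracts quickly from the mean-face start on realistic geometry |
| `tol` | 1e-8 | relative residual change | well below any meaningful landmark precision |
| `lambda_id`, `lambda_exp` | 1e-3 | squared sd units | mild shrinkage; keeps the normal matrix well-conditioned with 68 landmarks and larger bases, negligible bias otherwise |
| scheme subsets | iBUG-68: mouth 49–68, eyes 37–42 / 43–48 | 1-based indices | shipped as an overridable YAML config |

The original formulation of the fitting objective carries no
regularization term and published implementations do not document one;
the ridge weights here are an explicit, exposed design choice with a
noted default rather than a claim about prior work. For recovery
experiments where bias matters, the tests and acceptance script use
`lambda = 1e-8`.

## Error evaluation

Landmark accuracy is ocular-scaled RMSE: root-mean-square Euclidean
error divided by the interocular distance (IOD), reported as a percent.
The IOD is defined as the distance between the centroids of the two eye
subsets — a deliberate choice, since the literature rarely states its
convention; centroids are robust to single-landmark noise, and
corner-to-corner variants are expressible by redefining the subsets.
Because published tables of landmark error rarely define their absolute
scale, no attempt is made to reproduce any specific published number;
the percent-of-IOD convention is dimensionless and standard.
`per_subject_report()` emits both plausible "total" conventions: the
headline total pools all landmarks of all subjects into one quadratic
mean, and a second column averages the per-subject RMSEs.

## Rehabilitation metrics

`motion_magnitude()` reads motion as per-vertex *squared* Euclidean
displacement between the neutral mesh and the end-range mesh, summed
and averaged per region; the mean is the headline since it is invariant
to region size. The printed form of such evaluations is ambiguous about
aggregation, so both are reported and the invariant
`E_sum = E_mean · n_vertices` is asserted in tests.

Two consequences of this definition are load-bearing:

* **Pose independence must come from upstream.** E is computed on
  meshes in model space — fitted meshes are pose-free by construction —
  so rigid head motion between captures does not contaminate the
  measurement. A residual global translation of one mesh produces equal
  `E_mean` in *all* regions (a property the tests pin), which is the
  signature to look for if pose normalization fails.
* **Attenuation enters squared.** If one side's movement amplitude is
  attenuated by ρ, that side carries ρ² of the healthy side's E, so the
  asymmetry index `(E_R − E_L)/(E_R + E_L)` equals `(1 − ρ²)/(1 + ρ²)`
  and ρ is recoverable as `sqrt((1 − |a|)/(1 + |a|))`
  (`attenuation_from_asymmetry()`).

Progress is the signed difference `R = E_mean(session) −
E_mean(baseline)`. No clinical direction is attached to the sign:
motion gain is positive by construction, but hyperkinetic conditions
can make a *decrease* desirable, and mapping R onto clinical grading
scales (House–Brackmann, Sunnybrook, Yanagihara) is explicitly not
attempted — it would require labelled clinical data that does not
publicly exist.

When both regions show zero motion the asymmetry index is undefined and
returned as `NA` with a warning, never as 0: "no motion at all" and
"symmetric motion" are clinically different statements.

## The synthetic generator

`make_model()` builds a small face-like morphable model: the first 68
vertices follow the iBUG landmark layout (eye and mouth clusters
included), filler vertices come in mirrored pairs, and the mean shape
is *exactly* symmetric about x = 0 (left-half coordinates are reflected
onto their partners, so the mirror test holds bit-for-bit, not just to
tolerance). Basis columns are orthonormal; component standard
deviations decay geometrically with ratio 0.8 from 4 mm, giving
identity variation of a few millimetres against a ~140 mm face — small
enough for the alternating fit to behave as it would with a trained
model.

The first two expression components are constructed as mirror-image
*lateralized* displacement fields: component 1 is supported only on
left-half vertices, component 2 is its mirror image, and both vanish on
the midline. A symmetric movement is their sum; a palsy-like movement
attenuates one component. This is the one place the generator is
deliberately engineered rather than random: it makes side-attenuated
motion lie exactly inside the model span, so the closed-loop property —
generate, observe, fit, and recover region motion from the *fitted*
meshes — is achievable and meaningful. It is also why `make_model()`
requires `k_exp ≥ 2`. Midline vertices would receive the mean factor
`(1 + ρ)/2` of the two sides; with midline-free movement fields this is
vacuous but implemented for generality.

`make_cohort()` emulates a small clinical study: six subjects by
default (a realistic size for a pilot palsy dataset), each with a prior-
sampled identity, a fixed affected side (alternating by subject), a
per-session head pose, and an affected-side attenuation rising linearly
from ρ₀ = 0.4 to 1 across sessions — the simplest monotone ground truth
for sign checks on R. Observations are noiseless by default so that
closed-loop checks isolate method error; `noise_sigma` adds i.i.d.
Gaussian pixel noise when degradation behaviour is the subject under
test.

What the generator does *not* emulate: detector-specific landmark error
(which is structured and pose-dependent, not i.i.d. Gaussian),
occlusion, out-of-plane extreme poses, perspective effects,
synkinesis, and identity-dependent movement styles. Passing tests on
synthetic cohorts therefore demonstrate correctness of the geometry and
the estimators under the stated model, not clinical performance on
photographs of real patients.

## Numerical and formatting choices

* Model containers are plain-text arrays at 17 significant digits —
  enough to round-trip IEEE doubles exactly, so save/load is
  bit-identical and two saves of one model are byte-identical.
  `.pts` and OBJ files use 6 decimals (sub-micron at face scale).
* `estimate_pose()` requires ≥ 3 non-collinear points and raises a rank
  error on degenerate clouds; coincident eye centroids raise a
  degenerate-geometry error in `interocular_distance()`.
* All indices (vertices, landmarks, regions, triangulation) are 1-based
  throughout the R interface; `.pts` files are positional, so no index
  arithmetic occurs at I/O boundaries.
* Every generator takes an explicit seed and restores the caller's RNG
  state, so package functions never perturb a user's random stream.

Problem sizes in the shipped tests and the acceptance script (m = 90 to
250 vertices, 8 + 4 basis components, cohorts of up to 6 × 3 sessions)
were chosen as the smallest sizes at which every property being checked
is non-trivially exercised — landmark count comfortably exceeding
coefficient count, filler vertices dominating the landmark vertices,
and multi-session recovery schedules with interior points. Production
morphable models are orders of magnitude denser (tens of thousands of
vertices); nothing in the code assumes a particular m.

## Known limitations

* Weak perspective ignores perspective distortion; close-range selfies
  violate the camera model before they violate anything else.
* The fitter is a block-coordinate method on a non-convex joint
  problem; from the mean-face initialization it converges reliably in
  the tested regimes, but pathological initial poses (near-profile
  views) can stall in local minima.
* Motion metrics inherit the fit's accuracy only at the 68 landmark
  vertices; off-landmark vertices are constrained solely by the model
  prior, so region statistics reflect the model's interpolation as much
  as the data where regions are landmark-sparse.
* Landmark detection itself — the dominant error source on real
  images — is outside the package.
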
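# palsy3d

Rehabilitation outcomes for facial palsy (e.g. Bell's palsy) depend on
sustained, well-monitored therapy, but objective measurement of facial
movement usually requires a clinic visit and specialist judgement.
`palsy3d` implements a measurement pipeline that works from ordinary 2D
photographs: sparse facial landmarks are lifted to a dense 3D face
reconstruction by fitting a morphable model, and prescribed facial
movements are then quantified as geometric motion over clinician-defined
mesh regions, giving side-to-side asymmetry and session-to-session
progress numbers a therapist can track remotely.

It is aimed at researchers in medical image analysis and computer vision
who need a reproducible, fully offline implementation of 3D morphable
model (3DMM) fitting from sparse landmarks plus the downstream motion
metrics — including a synthetic data generator that stands in for
patient data and licensed face models.

## The model

A face is represented by a linear 3DMM,

    S = S̄ + A_id (α_id ⊙ σ_id) + A_exp (α_exp ⊙ σ_exp)

where `S̄` is the mean shape (3 × m vertices), `A_id` and `A_exp` are
identity and expression principal axes with per-component standard
deviations `σ`, and the coefficients `α` are dimensionless (sd units).
The camera is weak-perspective:

    s_2d = f · P · R(pitch, yaw, roll) · S + t,   P = [[1,0,0],[0,1,0]]

Fitting minimizes the 2D distance between the projected model landmarks
and the observed landmarks over `(f, R, t, α_id, α_exp)` with a mild
ridge penalty on the coefficients, by alternating two closed-form
sub-solves: scaled-orthographic Procrustes for the pose and ridge least
squares for the coefficients. Both steps are exact minimizers of their
sub-problems, so the residual trace is non-increasing and the solver is
fully deterministic.

Landmark handling follows the 68-point iBUG convention, including a
*hybrid merge* that combines two landmark fitters' outputs (one fitter
for the mouth subset, another for the rest) and landmark accuracy
reported as ocular-scaled RMSE — root-mean-square error as a percentage
of the interocular distance.

Motion between a neutral capture `S0` and the end range `S1` of a
prescribed movement is measured per clinician-defined vertex region `d`
as the per-vertex squared displacement

    E = Σ_{v ∈ d} ‖S1_v − S0_v‖²     (reported as sum and mean)

on pose-free fitted meshes, and rehabilitation progress between sessions
is the signed change from the pre-rehabilitation baseline,
`R = E_mean(session) − E_mean(baseline)`. A left/right asymmetry index
`(E_R − E_L)/(E_R + E_L)` summarizes lateralization; for movement
attenuated by a factor ρ on one side it equals `(1 − ρ²)/(1 + ρ²)`,
so ρ can be estimated back from it.

## Worked example

Simulate a palsy patient whose left side moves at half amplitude,
observe the 68 landmarks, fit the model, and measure the asymmetry:

```r
library(palsy3d)

model <- make_model(m = 250, k_id = 8, k_exp = 4, seed = 1)
truth <- sample_face(model, seed = 2)
pose  <- face_pose(scale = 3, yaw = 0.2, translation = c(250, 300))

mv   <- simulate_movement(model, truth, amplitude = 25,
                          side = "left", attenuation = 0.5)
obs0 <- observe(mv$S0, pose, model$correspondence, noise_sigma = 0, seed = 3)
obs1 <- observe(mv$S1, pose, model$correspondence, noise_sigma = 0, seed = 4)

fit0 <- fit_face(model, obs0)
fit1 <- fit_face(model, obs1)
fit1
#> Morphable-model fit: 68 landmarks, 19 iterations (converged)
#>   reprojection residual: 0.000157004 % interocular distance
#>   pose: f = 3, (pitch, yaw, roll) = (1.002e-07, 0.2, 4.631e-07) rad

regions <- face_regions(model, c("left", "right"))
ev <- motion_magnitude(fitted(fit0), fitted(fit1), regions,
                       session_id = "baseline")
ev
#> Motion evaluation 'baseline' (squared model units):
#>  region n_vertices    E_sum   E_mean
#>    left        120 156.2354 1.301961
#>   right        120 624.8983 5.207486

a <- asymmetry_index(ev, "left", "right")
c(asymmetry = a, attenuation = attenuation_from_asymmetry(a))
#> asymmetry: 0.6000, attenuation: 0.5000
```

The fit recovers the generating pose (yaw 0.2 rad) and reprojects the
landmarks to within 0.00016 % of the interocular distance; the left
region carries 0.25× the motion of the right (squared displacement of a
half-amplitude movement), giving an asymmetry index of 0.6 and an
attenuation estimate of exactly the simulated 0.5.

A cohort-level pipeline is available both as functions
(`cmd_simulate()`, `cmd_fit()`, `cmd_evaluate()`, `cmd_progress()`) and
as a shell command (`inst/cli/palsy3d`):

```sh
Rscript inst/cli/palsy3d simulate --out cohort --seed 1
Rscript inst/cli/palsy3d fit --model cohort/model.txt --landmarks-dir cohort --out fits
Rscript inst/cli/palsy3d evaluate --cohort cohort --fits fits --out eval
Rscript inst/cli/palsy3d progress --motion eval/motion.csv --out progress.csv
```

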
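# tendonstrain

Real-time estimation of the localized strain field in the free Achilles
tendon from joint angles and EMG, in R.

Tendon adaptation (and rehabilitation after tendinopathy or rupture) is
thought to be driven by the magnitude of tissue strain, not by external load
alone — but strain inside the free tendon cannot be observed during
movement.  `tendonstrain` implements a multiscale pipeline for biomechanists
and rehabilitation researchers that makes a subject-specific strain estimate
cheap enough to serve as live biofeedback:

1. **EMG-informed Hill-type muscle model.**  Causal EMG envelopes drive
   activation dynamics (second-order recursive filter with unit DC gain,
   exponential shaping `a = (e^{Au}-1)/(e^A-1)`); muscle–tendon lengths and
   moment arms come from a tensor-product cubic B-spline over the 3-DOF
   knee/ankle space; fiber–tendon equilibrium
   `fmax [a fl(l) fv(v) + fp(l)] cos(phi) = fmax f_t(eps)` is solved per
   frame, with the dimensionless tendon curve
   `f(eps) = 0 | a eps^2 | m eps + q` fitted to the subject's isometric
   force–elongation data under exact C1 continuity (`m = 2 a eps0`,
   `q = -a eps0^2`).
2. **Personalized finite-element tendon model.**  A transversely isotropic
   hyperelastic free tendon (`W = C1(I1b-3) + C2(I2b-3) + W_f(lambda) +
   kappa/2 (ln Jbar)^2`, exponential-toe/linear fiber stress `C3, C4, C5,
   C6`, 30° helical fiber twist, mid-portion waist in the cross-section
   profile) is calibrated inversely so its elongation under the 70%-MVIC
   tendon force matches the measurement, then solved over a 0–200% MVIC
   force sweep at 10% intervals: 21 levels × 2048 Gauss points of
   fiber-aligned strain.
3. **Spline surrogate.**  One cubic spline per Gauss point over force
   (selected by leave-one-out validation against partial-least-squares and
   broken-linear B-spline alternatives) replaces the FE solver in the
   streaming path, so each 4 ms motion-capture frame yields the full
   2048-point strain field plus the global (elongation / resting length)
   strain.

Every input — subject profile, tendon geometry, isometric series, walking /
hopping / heel-drop / MVIC trials — is produced by a seeded synthetic-subject
generator that stores its ground-truth parameters, so the calibration stages
are testable by parameter recovery and the whole package runs without any
external data.

## Worked example

```r
library(tendonstrain)

subject <- make_subject(seed = 0)
subject
#> Synthetic subject (seed 0)
#>   mass 80.8 kg, height 1.72 m, MVIC 156.0 N m, AT moment arm 56.8 mm
#>   free tendon 54.1 mm, CSA 54-75 mm^2, twist 30 deg

# tendon force-strain curve from the isometric series
iso   <- make_isometric_series(subject)
curve <- fit_tendon_curve(normalize_measurements(
  iso, subject$profile, subject$truth$fmax_total))

# inverse FE calibration at 70% MVIC, then the surrogate training table
mesh <- build_tendon_mesh(subject$geometry)        # 256 hexes, 2048 Gauss pts
C5   <- compute_C5(iso, subject$geometry, subject$profile$at_moment_arm)
init <- material_coefficients(C1 = 1.5, C3 = 2.5, C4 = 30, C5 = 1000 * C5,
                              lambda_star = 1 + curve$eps0)
cal  <- calibrate_material(mesh, init, iso$elongation[4],
                           iso$torque[4] / subject$profile$at_moment_arm)
tab  <- generate_training_table(mesh, cal$coefficients,
                                subject$profile$mvic_torque /
                                  subject$profile$at_moment_arm)

loo_validate(tab)
#> Leave-one-out surrogate validation
#>   pls           RMSE = 2.169e-03 strain, R = 0.999528
#>   cubic_spline  RMSE = 3.014e-04 strain, R = 0.999985  <- selected
#>   basis_spline  RMSE = 1.203e-03 strain, R = 0.999815

# stream a walking trial through the calibrated models
nms  <- truth_nms_model(subject)
pipe <- build_pipeline(nms, fit_surrogate(tab, "cubic_spline"),
                       subject$profile$tendon_resting_length)
res  <- process_trial(pipe, make_trial("walking", subject, duration = 4,
                                       truth_model = nms))
res
#> Stream result: 1000 frames (0 dropped), peak global strain 0.087 at 1.78 s
#> Latency over 1000 frames: mean 14.12 ms, 95th percentile 17.00 ms
```

The leave-one-out table says the cubic-spline surrogate reproduces held-out
FE strain levels to a pooled RMSE of a few 1e-4 strain (well under one
percentage point of strain) and beats both alternatives, so it is the one
the pipeline serves.  The stream result shows the walking peak: global
free-tendon strain close to 9% at push-off, co-occurring with the peak
summed triceps-surae force; per-frame compute times are wall-clock
measurements of this R implementation on the current machine.

A command-line wrapper over the same functions lives in
`inst/cli/tendonstrain` (subcommands `simulate`, `fit-curve`,
`calibrate-nms`, `build-fe`, `calibrate-material`, `fe-table`,
`fit-surrogate`, `validate-surrogate`, `run`, `report`).

## Method docs

The methods vignette
(`vignettes/multiscale-strain-estimation.Rmd`) documents the model
assumptions, parameter defaults and units, the numerical choices in the FE
solver (mean-dilatation volumetric treatment, smoothed fiber turn-on,
descending load continuation), what the synthetic generator does and does
not emulate, and known limitations.
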
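---
title: "Multiscale estimation of localized Achilles tendon strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale estimation of localized Achilles tendon strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tendonstrain` couples three models of very different cost so that the strain
field inside the free Achilles tendon — the segment between the calcaneal
notch and the soleus muscle–tendon junction — can be estimated frame by frame
at motion-capture rates:

1. an **EMG-informed Hill-type neuromusculoskeletal (NMS) model** turns joint
   angles and EMG envelopes into triceps-surae tendon forces;
2. a **transversely isotropic hyperelastic finite-element (FE) model** of the
   free tendon maps a summed tendon force to fiber-aligned strains at 2048
   Gauss points — far too slowly for real time;
3. a **surrogate** (one univariate interpolant per Gauss point over force)
   replaces the FE solver in the streaming path at negligible cost.

Because no public data set carries all the inputs (anthropometry, isometric
force–elongation measurements, tendon geometry, dynamic trials), the package
ships a seeded synthetic-subject generator that emits every input together
with the ground-truth parameters that produced it, so each calibration stage
can be tested by parameter recovery.

## The muscle level

Muscles (medial/lateral gastrocnemius, soleus, tibialis anterior) are
Hill-type actuators.  EMG envelopes are produced causally — band-pass
Butterworth (30–300 Hz, order 2), rectification, low-pass Butterworth (6 Hz,
order 2), MVIC normalization, clipping to [0, 1] — so that the output at any
instant depends only on past samples.  Neural activation follows a
second-order recursive filter with unit DC gain whose poles are
`exp(-dt/tau_act)` and `exp(-dt/tau_deact)` (defaults 12 and 24 ms), an
electromechanical delay (default 10 ms; the value is a package default, not a
measured quantity), and the exponential shaping
`a = (exp(A u) - 1)/(exp(A) - 1)` with `A` in [-3, 0) (default -2).

Active force–length is a Gaussian of width 0.45 in normalized fiber length;
force–velocity is a piecewise hyperbola with curvature 0.25 and eccentric
plateau 1.8; passive force is exponential with shape 4 reaching 1 at 60%
fiber strain.  Pennation follows the constant-thickness assumption.  These
shapes are conventional; any standard parameterization satisfies the
equilibrium contract, and the constants live in one place
(`R/nms-model.R`).

The series tendon of the three triceps-surae muscles uses the
subject-fitted dimensionless curve

\[ f(\varepsilon) = 0\ (\varepsilon<0);\quad a\varepsilon^2\
(\varepsilon<\varepsilon_0);\quad m\varepsilon+q\ (\varepsilon\ge\varepsilon_0) \]

with C1 continuity enforced *structurally*: only `(a, eps0)` are free and
`m = 2 a eps0`, `q = -a eps0^2` are derived, so the continuity constraints
hold exactly rather than to an optimizer tolerance.  The fit profiles `a`
out analytically (the model is linear in `a` at fixed `eps0`) and minimizes
the squared residual over `eps0` by a grid scan plus local refinement; the
squared-error loss is a package choice — absolute error would be an equally
defensible reading.  The antagonist's tendon uses a generic literature-shaped
curve (`a = 1300`, `eps0 = 0.015`, about 3.5% strain at maximum isometric
force).

Maximum isometric forces of the triceps surae come from muscle volumes via a
specific tension of 55 applied to PCSA = volume / optimal fiber length.  The
units are N/cm^2 on PCSA; a specific tension quoted per *volume* (N/cm^3)
would not be dimensionally consistent with a force, so the PCSA reading is
used.

**Fiber–tendon equilibrium** is solved per frame by bisection on fiber
length (60 iterations, bracket 0.3–1.9 optimal lengths; no root in the
bracket returns the nearer bound flagged `clamped`).  Fiber velocity uses a
two-pass explicit scheme: all frames are first solved isometrically, the
velocity is estimated from a causal first-order difference of those fiber
lengths smoothed by the same causal Butterworth used for angles, and the
frames are re-solved with that velocity fixed.  Every quantity at frame *i*
depends only on frames ≤ *i*, which is why the streaming pipeline reproduces
the batch result exactly.

**MTU kinematics** use a tensor-product cubic B-spline with not-a-knot end
conditions over a 3-DOF angle grid (knee flexion, ankle plantar-dorsiflexion,
ankle pronation-supination); moment arms are the negative partial derivative
with respect to the angle in radians, and evaluation outside the grid is an
error (the pipeline clamps and counts instead).  Not-a-knot interpolation
reproduces cubics exactly; since the generator's ground-truth MTU paths are
quadratic in the ankle angles and linear in knee angle, the surrogate equals
the generating geometry to machine precision — deliberate, so that the
calibration fixed-point tests are exact.  The Achilles moment arm is matched
to its "measured" value by a path offset standing in for the distal
attachment point; the moment arm is linear in the offset, so the match is
exact.

**NMS calibration** minimizes the summed squared difference between model
and reference joint moments over one trial per task, by Nelder–Mead on
parameters scaled to their initial values inside a ±20% box (quadratic
penalty outside) with one restart.  By default only the four tendon slack
lengths are calibrated.  This is an identifiability decision, not a
limitation of the optimizer: slack length dominates the moment error, while
activation/deactivation time constants (available via
`calibrate = c("tendon_slack_length", "time_constants")`) trade off against
it and, at desk scale (three short trials), inflate slack-length errors
beyond what force estimates tolerate.  Triceps-surae maximum forces stay at
their volume-derived values throughout.

## The tissue level

The free tendon is meshed by lofting elliptical cross-sections (area and
aspect ratio interpolated from the geometry's station profile) into
trilinear hexahedra: 16 axial layers by 4x4 section elements with 2x2x2
quadrature, i.e. 256 elements and exactly 2048 Gauss points.  Semi-axes are
scaled so the *discrete* polygonal section area equals the target
cross-sectional area; the element volumes then integrate the CSA profile to
well within 2%.  Reference fiber directions are helical — tangent to paths
that twist linearly about the longitudinal axis, accumulating 30 degrees
from the distal to the proximal end — so a fiber on the axis is purely
longitudinal and off-axis fibers incline with radius.

The strain energy is
\[ W = C_1(\bar I_1 - 3) + C_2(\bar I_2 - 3) + W_f(\lambda) +
\tfrac{\kappa}{2}(\ln \bar J)^2 \]
with \(C_2 = 0\) by default (Neo-Hookean matrix) and the fiber term defined
through \(T(\lambda) = \lambda\,\partial W_f/\partial\lambda\): zero below
slack, exponential toe \(C_3(e^{C_4(\lambda-1)}-1)\), then linear
\(C_5\lambda + C_6\) above the transition stretch \(\lambda^*\), with
\(C_6\) always recomputed from stress continuity at \(\lambda^*\).  The
transition stretch defaults to `1 + eps0` of the fitted tendon curve,
coupling the toe-region extent across the muscle and tissue scales.  `C5` is
measured, not fitted: the linear-region stiffness of the isometric
force–strain data divided by the mean cross-sectional area.  Units are mm,
N, MPa internally; GPa appears only in reports.

Boundary conditions: distal nodes fully fixed; the proximal force is applied
along the longitudinal axis of inertia of the reference mesh, distributed
over the proximal face in *tributary-area* nodal shares — the discrete
version of a uniform traction ("evenly applied to the surface").  Equal
per-node shares were tried first and rejected: face corner nodes carry tiny
tributary areas, so equal shares concentrate load there and produce a
spurious, non-converging strain spike.

Localized strain at a Gauss point is engineering fiber strain
\(\lambda - 1\) with \(\lambda = |F a_0|\); global strain is the mean
longitudinal displacement of the proximal node set over the resting length.
The choice of the engineering measure (rather than Green–Lagrange) is a
package decision — reported strain magnitudes in this field read naturally
on that scale — and `convert_strain()` converts between the two.

### Numerical choices in the FE solver

* **Mean-dilatation (Q1P0) volumetric treatment.**  Fully integrated
  trilinear hexahedra lock volumetrically at bulk penalties large enough to
  approximate incompressibility; the volumetric term therefore acts on the
  element-average Jacobian \(\bar J\).  With \(\kappa = 1000\,C_1\) the
  uniform-cylinder solve matches a 1D incompressible oracle to about 0.1%.
  Near-incompressibility is asserted on \(\bar J \in [0.95, 1.05]\) per
  element — the quantity this formulation constrains; the pointwise `J` is
  also reported and fluctuates a few percent around \(\bar J\) at clamped
  corners under extreme load.
* **Smoothed fiber turn-on.**  The solver kernel replaces \((\lambda-1)_+\)
  in the toe exponent by a softplus of width \(10^{-3}\) strain.  The
  smoothed law agrees with the exact piecewise law to machine precision a
  few widths away from slack but is infinitely differentiable, which removes
  a tangent jump of order \(C_3 C_4\) (large against the matrix stiffness
  \(2C_1\)) that otherwise stalls Newton whenever Gauss points cross slack.
  The exported `fiber_stress_derivative()` keeps the exact piecewise
  contract.
* **Newton with consistent finite-difference tangents.**  The residual uses
  the analytic first Piola–Kirchhoff stress; element tangents are central
  finite differences of that residual (step `1e-6` of the layer height),
  verified against a global finite-difference tangent.  A best-of-ladder
  backtracking line search accepts the step fraction with the lowest
  residual.  Convergence requires the free-DOF residual below `1e-8`
  relative to the applied load.
* **Continuation for cold starts.**  The twisted fiber field makes the
  tendon untwist under load through a rotation mode whose stiffness is
  orders of magnitude below the axial one (tangent condition numbers around
  `3e5`), and the exponential toe makes low-force states the most nonlinear.
  Cold solves therefore start from an analytic slender-body guess (per-layer
  1D uniaxial stretch at the local CSA, transverse contraction
  \(\lambda^{-1/2}\), and the layer rotation that balances the fiber
  untwisting torque against the matrix torsion); at high force this guess
  converges directly, while low-force targets are reached by *descending*
  load continuation from a stiff anchor state (the force at which the mean
  section sits just above \(\lambda^*\)).  Warm starts (force sweeps,
  calibration iterates) attempt the full load directly with step halving as
  fallback.

**Inverse material calibration** optimizes \(C_1, C_3, C_4\) (log-scale
Nelder–Mead, \(C_5\) fixed, \(C_6\) refreshed every iterate,
\(\kappa = 1000\,C_1\)) so the FE elongation under the 70%-MVIC tendon force
matches the measured elongation; each candidate is solved warm-started from
the previous converged state.  A single elongation cannot identify three
coefficients — \(C_1\) in particular is weakly identified — so the
calibration contract is *output* reproduction (elongation to 0.5%), not
coefficient recovery.

**The training table** sweeps 0–200% of the MVIC tendon force at 10%
intervals (21 levels), warm-starting each level from the previous one, and
records all 2048 localized strains plus the global elongation per level.

## The surrogate level

Spline surrogates fit one univariate interpolant per Gauss point over force:
a cubic B-spline with not-a-knot ends, and an order-2 (broken-linear)
B-spline as the genuinely different second spline method.  Both reproduce
training rows exactly, so leave-one-out error measures between-level
interpolation only.  The PLS surrogate regresses the 2048-vector of strains
on polynomial force features \((F, F^2, F^3)\) with the component count (≤3)
chosen by an inner leave-one-out; the paper-level contract is only that a
single-input polynomial regression loses to cubic interpolation on smooth
monotone tables, and it does.  Global elongation is served by its own cubic
spline over the per-level elongations.

Leave-one-out validation retrains on 20 levels and predicts the held-out
level, pooling all Gauss points globally into one RMSE and one correlation
coefficient per method.  The two extreme levels are excluded by default
(predicting them would be extrapolation, which is a different claim than
interpolation accuracy); `include_extremes = TRUE` gives the inclusive
variant, with splines evaluated at their clamped boundary.  Above the
training range, predictions clamp to the 200%-MVIC row and are flagged.

## The streaming pipeline

`pipeline_step()` advances one frame: causal low-pass of angles (clamped to
the spline grid with a counter when outside), causal low-pass of each EMG
sample in the frame block with the most recent value consumed (EMG arrives
at 1500 Hz, frames at 250 Hz; the rate reconciliation is a zero-order hold,
since nothing in the formulation requires sub-frame EMG detail), the
electromechanical-delay buffer, the activation recursion, B-spline
kinematics, the same two-pass equilibrium solve as the batch engine, summed
triceps-surae force, surrogate lookup, and a strain frame with min/mean/max
summary and wall-clock compute time.  Envelope values above 1 are clipped
and counted.  Batch processing literally runs the same per-frame code, which
is what the stream-equals-batch and prefix-replay tests pin down.  Latency
is *reported* (mean, 95th percentile, histogram), never asserted against any
particular hardware figure.

## What the generator emulates — and what it does not

The generator draws a subject (mass, height, MVIC torque, Achilles moment
arm 45–65 mm, free-tendon length 38–70 mm, muscle volumes), a tendon
geometry with a mid-portion CSA minimum (waist 42–58% along the tendon,
ends 20–45% larger) and 30 degrees of twist, and ground-truth parameters.
The dimensionless curve's slope is drawn so the implied linear-region
modulus sits near 0.58 GPa, a representative young-adult Achilles value.
Trials are sums of Gaussian bumps (EMG envelopes) and periodic splines
through keypoints (joint angles): walking (1.2 s cycle, gastrocnemius
envelope peaking in late stance, tibialis anterior around heel strike and
swing), single-leg hop (0.6 s cycle, triceps bursts at contact), eccentric
heel drop (a slow 15-degree-plantarflexion-to-15-degree-dorsiflexion ramp
under moderate, rising triceps drive), and an MVIC ramp-and-hold.  Reference
joint moments are computed by the ground-truth forward model itself, which
makes "inverse dynamics" internally consistent by construction.

Consequences for interpretation: passing tests demonstrate internal
consistency (parameter recovery, oracle equivalence, causality, ordering),
not validity on real data.  Real EMG has stochastic carrier content, motion
artifact and crosstalk; real kinematics come from marker-based inverse
kinematics with its own errors; real tendons are viscoelastic,
inhomogeneous, and composed of sliding sub-tendons — all outside this
model.  Four EMG channels are generated rather than a full 16-site montage,
because only the triceps surae and their antagonist enter the modelled
3-DOF system.

## Problem sizes used by the test suite

The default subject (seed 0) drives every expensive artifact exactly once
per test run: one inverse material calibration (~60 FE solves), one 21-level
training table, one leave-one-out validation of all three methods, one NMS
slack-length recovery (three trials of 1.8–3 s), one 1000-frame walking
stream, and one mesh-halving convergence solve (32 layers by 8x8 sections,
16384 Gauss points).  These sizes were chosen as the smallest at which each
claim is meaningful: a 21-level sweep is the table the method defines;
1000 frames cover more than three gait cycles; the convergence pair is a
true halving of element size in all directions.

## Known limitations

* One force input: the surrogate maps the *summed* triceps-surae force;
  per-muscle force components and sub-tendon differential loading are out of
  scope.
* The FE model is quasi-static and elastic; no viscoelasticity, no contact
  with surrounding tissue, no aponeurosis.
* The untwist rotation under load is soft and strongly nonlinear; solver
  robustness near zero force depends on the descending-continuation
  strategy described above.
* Latency figures from `run_stream()` are wall-clock measurements of this
  R implementation and are not comparable across machines.
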
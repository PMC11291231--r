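---
title: "Modeling triceps surae force sharing under Achilles tendon compliance and subtendon twist"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling triceps surae force sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsforce)
```

## The question

The Achilles tendon is loaded by three muscles — soleus (SOL), gastrocnemius
medialis (GM) and gastrocnemius lateralis (GL) — through three subtendons
that twist around each other before inserting on the calcaneus. Two
properties of this structure vary across people and with pathology:

* **subtendon twist**: the arrangement of the three insertion regions on the
  calcaneus (classified as low, medium or high twist), which perturbs each
  actuator's moment arm by a millimetre-scale amount; and
* **tendon compliance**: tendinopathic Achilles tendons are more compliant
  than healthy ones, which changes where on the force–length and
  force–velocity curves the muscle fibers operate.

`tsforce` implements a reduced, fully scripted version of the simulation
experiment that asks: *how much do twist and compliance each change the
sharing of force among the three muscles* at the moment of peak total
triceps surae force, during a bilateral heel drop (eccentric), a bilateral
heel rise (concentric), and walking stance?

The force-sharing statistic is each muscle's tendon force divided by the sum
of the three forces at the frame where that sum peaks, in percent.

## Model

### Muscle–tendon units

Each actuator is a Hill-type muscle in series with an elastic tendon:

* **Tendon**: normalized force–strain law
  $f_T(\tilde{l}_T) = c_1 e^{k_T(\tilde{l}_T - c_2)} - c_3$ with
  $c_1 = 0.2$, $c_2 = 0.995$, $c_3 = 0.25$, clipped at zero. The normalized
  stiffness $k_T$ is the slope at the nominal operating force
  $f_T = 1 - c_3$; it is the single parameter varied by the compliance
  analysis. The generic (healthy control) value is $k_T = 35$; the
  tendinopathic mean is 20% lower (28); the compliant and stiff extremes
  (21 and 47) lie two group standard deviations (3.5 tendinopathic, 6.0
  control) from the respective means — see `derive_compliance_models()`.
* **Active force–length**: a three-Gaussian sum, recentred and rescaled so
  its maximum is exactly 1 at the optimal fiber length. The recentring
  (shift ≈ 0.013, scale ≈ 1.0005) is a normalization of this package; the
  shape is the standard one used in direct-collocation muscle-redundancy
  frameworks.
* **Passive force–length**: exponential, zero at or below optimal length,
  reaching 1 at 60% passive strain.
* **Force–velocity**: logarithmic–hyperbolic law, affinely rescaled so the
  isometric value is exactly 1 and the value at maximal shortening exactly
  0; the eccentric branch is clamped at its value at $+v_{max}$ (bounded
  plateau ≈ 1.79).
* **Pennation**: fixed-height model, $l_m \sin\alpha$ constant.

Given activation, musculotendon length and a fixed fiber-velocity estimate,
the fiber–tendon equilibrium is a one-dimensional root-find in the fiber
extent along the tendon line; `tsforce` solves it by safeguarded Newton with
bisection fallback to a residual of $10^{-14}$ in normalized force units
(`solve_fiber_equilibrium()`). The tight tolerance is needed so that the
redundancy solver's optimality conditions can be verified to $10^{-6}$.

Muscle constants default to the gait2392 triceps surae values
(SOL: 3549 N, 30 mm, 268 mm, 25°; GM: 1558 N, 60 mm, 390 mm, 17°;
GL: 683 N, 64 mm, 385 mm, 8°; $v_{max} = 10\,l_0/s$), recorded in
`inst/extdata/default_model.yaml` and overridable.

### Geometry

The full-body musculoskeletal geometry is replaced by a sagittal-plane
ankle: each muscle is a polyline (origin → via point → calcaneal insertion)
in a shank-fixed frame (x anterior, y superior, z lateral, right leg);
the insertion rotates with the ankle about the z axis, dorsiflexion
positive. The plantarflexion moment arm is the tendon-excursion derivative
$r(\theta) = dL/d\theta$ (with $\theta$ dorsiflexion-positive this is
positive for plantarflexors and equals $-dL/d\theta_{pf}$ for a
plantarflexion-positive angle).

Subtendon twist is realized purely through insertion points: the no-twist
model inserts all three muscles at the Achilles midpoint; the low/medium/
high classes offset each insertion by the rows of
`inst/extdata/twist_offsets.csv`, a **synthetic stand-in** for
subject-specific subtendon midpoints (the source experiment derived them
from a subject-specific 3D ultrasound reconstruction that is not public).
The stand-in arranges the subtendons on an ellipse in the calcaneal
cross-section (5 mm mediolateral, 1.5 mm anteroposterior, 1 mm vertical
semi-axes) rotated by 15°/40°/65° for the three classes, so the SOL
subtendon rotates from medial toward lateral as twist increases, and
moment-arm perturbations stay in the observed low-millimetre range.
Enlarged tendons are modeled by scaling every offset vector by 1.5 or 2.0.

### Model identification

Two aspects of the reduced geometry cannot be carried over from the source
models and were identified once, then frozen in the default configuration:

1. **Path constants.** Each path's constant length offset is set so that at
   neutral ankle, with the tendon unloaded, the normalized fiber length
   equals a configured constant (`neutral_fiber_norm`: SOL 0.92, GM 0.98,
   GL 1.20).
2. **Insertion midpoint.** The Achilles midpoint sits 66 mm posterior and
   35 mm inferior to the ankle center, giving an effective plantarflexion
   lever of ≈ 5.5–7 cm over the motion range — the upper end of reported
   Achilles moment arms, compensating for the straight-line (non-wrapping)
   path.

The identification criteria were: reproduce the published generic-model
heel-drop sharing (≈ 66/24/11), place the heel-drop fibers on the
descending limb of the force–length curve (as reported for the source
simulations), and reproduce the *directions* of the published compliance
effects (soleus share increasing with compliance in the heel drop,
decreasing with compliance in walking). Everything else this package
reports — the magnitudes of the compliance deltas, the twist bound, the
heel-rise and walking share levels — is a prediction of the identified
model, not a fitted quantity.

## The redundancy solver

At each frame the net plantarflexion moment $M(\theta)$ must be produced by
the three muscles plus a bounded residual torque actuator:

$$\min_{a \in [0,1]^3} \; \sum_m a_m^2 + w\left(\frac{M - \sum_m r_m f_m(a_m)}{s}\right)^2$$

with $w = 1000$, $s = 1$ N·m, and $f_m(a)$ the elastic-tendon equilibrium
force. The residual absorbs demands the muscles cannot meet (e.g.
dorsiflexion moments) and is flagged beyond its bound (50 N·m default).
Moment equilibrium holds exactly by construction (the residual is defined
as the gap).

The problem is smooth and strictly convex in the activations, and
`solve_frame()` solves it deterministically in two phases:

1. a projected Gauss–Newton descent on the penalized objective (the
   Hessian is diagonal-plus-rank-one, so the step is closed-form), which is
   globally convergent but limited by the penalty's conditioning; then
2. a primal–dual Newton polish of the KKT system with the exact diagonal
   Jacobian term $2 - \lambda\, \partial q_m/\partial a_m$ (the curvature
   of muscle force in activation matters at short fiber lengths), which
   resolves the multiplier to machine-level consistency.

Every frame satisfies the projected KKT conditions to $10^{-6}$; the test
suite also verifies on random frames that no point of a dense activation
grid (step 0.005) beats the solver's objective.

Trials are solved frame-wise: a first pass with isometric fibers yields
equilibrium fiber lengths; fiber velocities are then central differences of
those lengths; a single fixed-point pass re-solves all frames with the
velocities held fixed. This deliberately replaces the source framework's
full direct-collocation dynamic optimization: the reported outcome (sharing
percentages at one peak instant) is governed by the cost function, the
characteristic curves and the geometry, all preserved here; activation
dynamics are omitted (see Limitations).

## Synthetic trials

No motion-capture data are distributed, so `gen_heel_drop()`,
`gen_heel_rise()` and `gen_walk()` generate the three exercises at the
study's stated conditions (85-kg participant; heel exercises on a box,
3 s per repetition at a 1-Hz metronome; self-paced walking stance):

* **Heel drop**: minimum-jerk ankle sweep from −20° (plantarflexed, on
  tip-toe) to +15° (heels below box edge) over 3 s; the moment follows a
  quasi-static forefoot lever under half body weight,
  $M = \tfrac{1}{2} m g\, \ell \cos\theta$ with $\ell = 0.12$ m. The
  muscle–tendon units lengthen throughout (eccentric).
* **Heel rise**: the exact time-reverse (concentric).
* **Walk**: stance only (0.7 s default): brief loading plantarflexion to
  −15°, dorsiflexion ramp to +12° at 70% stance, push-off return; the
  moment rises to a single peak of 1.4 N·m/kg × body mass at 75% stance.

Gaussian noise of configurable standard deviation can be added to both
channels (defaults are zero: the acceptance analyses are deterministic);
a seeded generator makes every trial reproducible, and event times (cycle
start/end) ride along for time normalization.

What the generator does **not** emulate: measured subject kinematics
(the published angles are not deposited), ground-reaction-force waveforms,
marker noise with realistic autocorrelation, inter-repetition variability,
or knee-angle coupling during gait (the knee is held straight unless a
knee channel is supplied). Tests passing on these trials therefore
demonstrate the mechanisms (compliance moves operating points; twist moves
moment arms) under controlled, plausible kinematics — not agreement with
any individual's measured data.

## What the pipeline reproduces

With the default (frozen) configuration the package reproduces, on its own
synthetic trials, the headline results of the experiment it models — run
`scripts/acceptance.R` or the test suite to regenerate all of them:

* generic-model heel-drop sharing near 66% SOL / 24% GM / 11% GL, with the
  fibers on the descending limb;
* soleus share increasing monotonically with tendon compliance in the heel
  drop (and the gastrocnemii decreasing), with compliant-minus-generic and
  compliant-minus-stiff deltas of a few to ~10 percentage points;
* the opposite, smaller trend in walking; and
* twist-induced sharing changes bounded by ~2 percentage points, an order
  of magnitude below the compliance effect.

## Numerical choices

* Equilibrium root-find: bracket is (0, tendon-force-free extent); Newton
  with bisection safeguard; residual tolerance $10^{-14}$; degenerate
  slack-tendon/slack-fiber cases return the zero-force configuration with
  the tendon at its force-free length.
* Frame solver: phase-1/phase-2 structure above; activations snapped to
  bounds within $10^{-9}$; first-occurrence rule for tied peaks.
* Velocities: one fixed-point pass (no iteration to self-consistency);
  central differences, one-sided at the ends.
* Moment arms: analytic derivative of the polyline length; the
  finite-difference oracle in the tests agrees to $10^{-6}$ m.
* Problem sizes: 100 Hz sampling for the 3-s heel exercises (301 frames)
  and 0.7-s stance (71 frames); a full 3 × 4 × 4 grid solves 48
  trial-model combinations in a few minutes on one core.

## Limitations

* Frame-wise optimization without activation dynamics: no excitation
  filtering, so rapid force transients are instantaneous. At the analyzed
  peaks (near-isometric instants) this matters little, but transient-phase
  quantities should not be over-interpreted.
* The three actuators are independent; subtendon sliding and inter-tendon
  force transmission are not modeled.
* The geometry is a calibrated sagittal stand-in, not subject-specific
  anatomy: twist offsets and the insertion midpoint are synthetic defaults,
  and conclusions about any individual require replacing them in the
  configuration.
* Single "subject": the generator emulates one body mass and one kinematic
  pattern per exercise; no population statistics are implied.
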
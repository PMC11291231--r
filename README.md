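# tsforce

Triceps surae force sharing under Achilles tendon compliance and subtendon
twist.

The Achilles tendon is loaded by three muscles — soleus (SOL),
gastrocnemius medialis (GM) and gastrocnemius lateralis (GL) — through
three twisted subtendons. Tendinopathic tendons are more compliant than
healthy ones, and the subtendon twist pattern varies between people.
`tsforce` is a simulation pipeline for quantifying how these two factors
change the *sharing* of force among the three muscles during rehabilitation
exercises (bilateral heel drop and heel rise) and walking.

The pipeline consists of:

* **Hill-type muscle–tendon units** with an elastic tendon whose normalized
  force–strain curve `f = c1·exp(kT(l̃ − c2)) − c3` is parameterized by a
  single normalized stiffness `kT` (generic healthy model: 35;
  tendinopathic mean: 28; compliant and stiff extremes: 21 and 47);
* a **sagittal-plane ankle geometry** with polyline muscle paths,
  tendon-excursion moment arms `r(θ) = dL/dθ`, and subtendon insertion
  sets for no/low/medium/high twist (with 1.5× and 2× enlargement
  scaling);
* a deterministic **muscle redundancy solver** minimizing the sum of
  squared activations plus a heavily penalized residual torque, subject to
  elastic-tendon muscle mechanics and exact moment equilibrium
  (`Σ rₘ fₘ + residual = M`);
* a **synthetic trial generator** for the three exercises (85-kg
  participant; 3-s metronome-paced heel exercises; walking stance with a
  1.4 N·m/kg push-off peak); and
* **sharing analyses**: percentage contributions at the frame of peak
  total triceps surae force, grids over exercise × twist × compliance,
  difference tables, and fiber operating-point reports.

## Worked example

Solve the default synthetic heel drop with the generic model and with a
compliant (tendinopathic) tendon:

```r
library(tsforce)

trial <- gen_heel_drop()                 # -20° -> +15°, 3 s, zero noise
generic <- solve_trial(trial, ts_model(k_t = 35))
compliant <- solve_trial(trial, ts_model(k_t = 21))

round(contributions_at_peak(generic), 2)
#>   SOL    GM    GL
#> 69.30 19.14 11.56
round(contributions_at_peak(compliant), 2)
#>   SOL    GM    GL
#> 75.74 15.99  8.26
```

At the moment of peak total force the generic model attributes ~69% of the
triceps surae force to the soleus; making the tendon compliant (as in
Achilles tendinopathy) raises the soleus share by ~6 percentage points at
the expense of both gastrocnemii. The mechanism is visible in the fiber
operating points: at the peak (deep dorsiflexion under load) all three
muscles sit on the descending limb of the force–length curve, and a more
compliant tendon stretches more, letting the fibers work at shorter, here
more favourable, lengths:

```r
round(generic$lm_norm[peak_index(generic), ], 3)    # normalized fiber length
#>   SOL    GM    GL
#> 1.221 1.135 1.331
round(compliant$lm_norm[peak_index(compliant), ], 3)
#>   SOL    GM    GL
#> 1.083 1.078 1.283
```

The full cross-analysis (3 exercises × 4 twist classes × 4 compliance
models) and its difference tables:

```r
grid <- grid_run()          # ~5 minutes on one core
grid$sharing                # contributions at peak, one row per combination
grid$stats                  # max twist- and compliance-induced changes
write_sharing_table(grid, "results/")
```

A thin command-line wrapper is included (`inst/cli/tsforce.R`) with
`simulate`, `solve`, `grid` and `report` subcommands.

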
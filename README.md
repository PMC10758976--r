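# padrom

Quantifying how protective equipment restricts upper-body mobility — and how
that restriction relates to comfort — from inertial motion capture.

Shoulder and elbow pads protect ice hockey players but also limit movement.
padrom is an R package for the full analysis chain used to measure that
trade-off: it converts frame-wise unit-quaternion segment orientations
(96 Hz IMU capture) into clinical joint angles, extracts range of motion
(ROM) for static single-joint tasks and event-segmented wrist/slap shots,
compares pad conditions with repeated-measures statistics, and correlates
the objective restriction with Likert comfort surveys. It is written for
sports-biomechanics and ergonomics researchers who need a reproducible,
tested pipeline rather than a one-off script.

## The model in brief

* **Joint kinematics.** For each joint, the relative rotation between its
  segments is the joint quaternion
  `q_joint = q_prox^(-1) ⊗ q_dist`
  (scalar-first, Hamilton convention), decomposed in the intrinsic
  Y–X′–Z″ order: Y = flexion/extension, X = abduction/adduction,
  Z = axial rotation. Orientation streams are smoothed with a zero-phase
  4th-order Butterworth low-pass (6 Hz) applied to the quaternion
  components, then renormalized.
* **ROM.** Static ROM is the excursion from the initial anatomical angle
  (mean of the first 0.25 s) to the task-direction extremum, averaged over
  sides and repetitions. Shots are segmented by shot initiation (SI),
  swing top (ST, slap only) and shot release (SR) detected from the lead
  hand's angular-speed profile; phase ROM is max − min inside the event
  window. Right-handed shooters are mirrored to left-handed form.
* **Statistics.** One-way repeated-measures ANOVA with Greenhouse–Geisser
  handling (Mauchly-gated by default), partial eta-squared
  `η²p = SS_cond / (SS_cond + SS_err)` with 0.01/0.06/0.14 bands, LSD
  post-hoc paired t-tests, Friedman + exact Wilcoxon signed-rank tests for
  the ordinal surveys, and Spearman correlations (exact p for ≤ 8 pads)
  between per-pad comfort and total ROM.
* **Synthetic studies.** A generator reproduces the 9-participant ×
  11-task × 6-condition × 5-repetition design with known restriction
  factors, ground-truth shot events, and comfort scores coupled to the
  injected restriction, so the whole pipeline is testable end to end.

## Worked example

Generate a small synthetic study, run the pipeline, and look at the
shoulder-flexion comparison:

```r
library(padrom)

cfg <- run_config(
  generator = list(n_participants = 9, repetitions = 1,
                   tasks = c(static_tasks(), "wrist_shot"), seed = 20230),
  output_dir = "demo_run")
res <- run_pipeline(cfg)

subset(res$stats, joint_plane == "shoulder_flexion",
       select = c(mean_no_pads, mean_vik_max, f_stat, p_value, eta_sq))
#>  mean_no_pads mean_vik_max   f_stat      p_value    eta_sq
#>      164.9141     149.0185 32.82284 3.771456e-13 0.8040313

res$comfort$correlations
#>     scope  rho    p_value     band
#>    static  0.9 0.08333333     high
#>   dynamic -0.5 0.45000000 moderate
#>  combined  0.5 0.45000000 moderate
```

Reading the numbers: the unpadded control reaches a mean shoulder flexion
ROM of ~165°, the most restrictive pad model ~149°; the condition effect is
significant (F ≈ 33, p < 0.001) with a large effect size (η²p ≈ 0.80,
above the 0.14 "large" threshold). Across the five pads, higher comfort
scores go with more preserved mobility over the static tasks (Spearman
ρ = 0.9, a "high" band). The dynamic scope in this small demo rests on a
single wrist-shot task with one repetition, so its correlation is
essentially noise — a full study (all eleven tasks, five repetitions)
stabilizes it. The same tables are written as CSVs (`rom_table.csv`,
`stats_static.csv`, `normalized_rom.csv`, `correlation_report.csv`, ...)
into `demo_run/`, together with the run log and a config copy.

`make_paper_tables(res$stats)` renders the one-decimal
`mean ± SD^markers` layout used in condition-comparison tables.

A thin command-line wrapper with verbs `generate`, `rom`, `stats`,
`comfort`, `run` and `tables` is installed at
`system.file("scripts", "padrom", package = "padrom")`.

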
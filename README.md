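# facestress

Automated stress scoring for head-fixed mice from tracked facial landmarks.

Head fixation is a routine but stressful procedure in rodent neuroscience,
and the standard way to monitor the animal's state — an experimenter
eyeballing grimace-scale cues — is subjective, intermittent, and hard to
reproduce. `facestress` replaces that with an explicit, configurable
pipeline: it consumes per-frame (x, y, likelihood) trajectories of seven
facial landmarks (both ears, the four eyelids, the nose) as exported by
markerless pose-tracking software, and turns them into per-feature and
aggregate stress scores on a 0–10 scale with a three-level status
(okay / caution / stressed), both offline (batch) and live (streaming).
It is aimed at labs that already track facial keypoints and want a
quantitative, weight-adjustable stress readout, plus the statistical tools
to validate that readout against human raters and physiological measures.

## The model

All quantities are computed on 2-second windows of a cleaned trajectory
table, normalised by the body scale *S* (median inter-ear distance), which
makes every score invariant to camera distance and framing:

* **Eyelid aperture** `a_t = ‖upper_t − lower_t‖` per eye. Closure epochs
  are maximal runs with `a_t < 0.4 · B`, where *B* is the open-eye baseline
  (75th percentile of the aperture series). Epochs shorter than 1 s are
  **blinks** (reward/reflex-associated, ignored); epochs of ≥ 1 s are
  **squints**, the sustained closures that indicate stress.
* **Nose activity.** Per window: the maximum range of motion
  *R* (diameter of the visited point set), the travel distance
  *T* (cumulative Euclidean path length, so *T ≥ R* always), and the
  activity index `A = (R/S + T/S) / 2`.
* **Ears.** The same activity index per ear, plus the asymmetry
  `|A_L − A_R| / (A_L + A_R)` (0 when both ears are still), and a fold flag
  when an ear is simultaneously immobile (window range `< 0.05·S`) and
  displaced from its session-median position (by `> 0.15·S`).
* **Freezing.** A window freezes when the nose and both ear activity
  indices all fall below a threshold (default 0.145).
* **Scores.** Piecewise-linear calibration maps send each feature's driving
  metric to [0, 10]: eyes from squint coverage and relative aperture, nose
  and ears from the inverted activity index, with additive ear bumps for
  fold and asymmetry. The total is the weighted mean
  `Σ wᵢ sᵢ / Σ wᵢ` over the five features (EAR_LEFT, EAR_RIGHT, EYE_LEFT,
  EYE_RIGHT, NOSE); weights default to 1, and weight 0 removes a feature
  exactly (for head-posts that obscure or immobilise it). Status splits the
  scale at 10/3 and 20/3.

The package also ships a synthetic session simulator with ground-truth
event logs, a streaming evaluator equivalent to the batch scorer on the
trailing window, feature-ablation analysis, and method-comparison
statistics (min-max profile normalisation, Pearson r with t-based p,
pairwise-averaged weighted Cohen's kappa, and a Monte Carlo
identity-shuffle test).

## Worked example

Simulate 30 s that start relaxed and end in combined stress (sustained
squinting + freezing + a folded ear), then score it:

```r
library(facestress)
s <- simulate_session(sim_config(
  duration_s = 30, seed = 42,
  state_schedule = list(list(state = "relaxed", duration_s = 15),
                        list(state = "stressed_combined", duration_s = 15))))
rep <- score_session(s$table)
print(rep)
#> <stress_report> 15 windows, session mean 4.45 / 10 [caution]
#> window status: okay=8 caution=0 stressed=7
summary(rep)
#> Session stress: 4.45 / 10 [caution] over 15 windows
#> Mean feature scores:
#>  EAR_LEFT EAR_RIGHT  EYE_LEFT EYE_RIGHT      NOSE
#>      5.00      4.59      4.24      4.24      4.21
#> Freezing in 47% of windows
#> Status counts: okay=8 caution=0 stressed=7
```

The first half of the session scores in the okay band (window totals
0.1–0.7: open eyes, busy nose, symmetric ears); the second half is scored
stressed (squint coverage near 1, activity indices collapse, freezing
flags on), and the session mean lands in between — exactly what a
half-stressed recording should report. Ablation quantifies how much the
readout depends on feature coverage; the deviation from the all-features
baseline grows with the number of removed features:

```r
ablation_by_size(ablation_analysis(s$table))
#>   n_removed deviation
#> 1         0 0.0000000
#> 2         1 0.1086865
#> 3         2 0.1572377
#> 4         3 0.2358565
#> 5         4 0.4347459
```

Real recordings enter through `read_trajectories()` (the 3-header-row CSV
dialect or the equivalent HDF5 layout), are cleaned with
`clean_trajectories()` (short low-likelihood gaps interpolated, long ones
flagged missing), and scored the same way. `replay_stream()` /
`live_monitor()` provide the streaming evaluation; a command-line front
end is installed at `system.file("cli", "facestress", package = "facestress")`
with `simulate`, `score`, `ablate`, `validate`, and `replay` subcommands.

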
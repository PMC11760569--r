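# ahmmtraj

Weight-trajectory discovery in aging mouse colonies with autoregressive
hidden Markov models.

## What this package is for

Longitudinal colony data — one weight measurement per mouse per visit,
at irregular ages and frequencies, with sex and APOE genotype as static
covariates — hides distinct aging phenotypes (weight gain, loss,
stability) that a colony-mean curve averages away. `ahmmtraj` is for
biostatisticians and preclinical aging/Alzheimer's researchers who want
to recover those phenotypes from such data and validate them against
survival, body-composition, and plasma-biomarker measurements.

## The model

Each mouse's series is governed by a latent first-order Markov chain
`H_t ∈ {1..N}` (default `N = 10`) with transition matrix `A = [a_ij]`.
Given `H_t = i` the observations factorize as

    Normal(age_t; μ_i, σ²_i)
    × Cat(sex; p_sex,i) × Cat(genotype; p_geno,i)
    × Normal(w_t; α_i + δ_i·[male] + φ_i·w_{t−1}, σ²_w,i)

with a separate per-state Gaussian for the first visit (no AR
predecessor). Because the AR parent is observed, exact junction-tree
inference on this structure reduces to forward–backward with modified
emissions. Fitting is EM (Baum–Welch) with closed-form M-steps, 10
random restarts of up to 1,500 iterations by default, best likelihood
selected. Trajectories are defined by the *ending states* — states with
self-transition probability above 0.3 — and each mouse is assigned to
the state its series ends in (smoothed-posterior argmax at the last
visit). Groups are phenotyped by percent weight change from the 12-month
anchor and validated with Kaplan–Meier curves, log-rank tests,
composition chi-square tests, Welch t tests, and the adipose index.

A synthetic-colony generator with known ground truth
(`colony_config()`, `simulate_colony()`, `simulate_posthoc_measures()`)
makes the whole pipeline testable end to end without any external data.

## Worked example

```r
library(ahmmtraj)

cfg  <- branching_colony_config(n_mice = 600, seed = 1)
sim  <- simulate_colony(generate_true_params(cfg), cfg)

pre  <- apply_exclusions(colony_from_table(sim$colony)$mice)
seqs <- as_observation_sequences(pre$retained)

fit <- fit_with_restarts(seqs, n_states = 9, n_iters = 300,
                         n_restarts = 3, master_seed = 1)
cls <- classify_states(fit)
cls$ending_labels
#> [1] "A" "B" "G" "H" "I"

asg <- assign_terminal_states(seqs, fit, method = "posterior")
grp <- group_by_trajectory(asg, cls)
round(sapply(grp$groups, function(g) percent_weight_change(g, seqs)), 1)
#>     A     B     G     H     I
#> -23.7 -13.9   2.8  18.8  38.9

ph  <- simulate_posthoc_measures(sim$truth, cfg)
bio <- ph$biomarkers
bio$group <- setNames(asg$state, asg$mouse_id)[bio$mouse_id]
welch_ttest(bio$abeta40[bio$group == "I"],   # gain group
            bio$abeta40[bio$group == "G"])   # stable group
#> $t: 9.61   $p_value: 1.86e-10
#> $mean_a: 88.7   $mean_b: 49.9
```

The first two lines of output are the fitted model's verdict: exactly
five of the nine states are ending states (self-transition above 0.3),
and the percent weight changes from 12 months of age sort their member
mice into deep loss (−23.7%), moderate loss (−13.9%), stable (+2.8%),
and two gain phenotypes (+18.8%, +38.9%). The Welch test then shows the
gain group's plasma biomarker level (88.7) far above the stable group's
(49.9) — the association between weight gain and amyloid burden that the
post-hoc battery is built to detect. Exact numbers vary with the seeds;
the values above are one run of this snippet.

`run_pipeline(pipeline_config(...))` ties all stages together —
preprocess → fit → classify → group → phenotype → validate — and writes
an exclusion report, fitted-model JSON, transition-matrix CSV, group and
curve CSVs, validation JSON, and a run log, all stamped with a
configuration fingerprint and the master seed.

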
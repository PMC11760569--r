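---
title: "Modelling body-weight trajectories in aging mouse colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling body-weight trajectories in aging mouse colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahmmtraj)
```

## The problem

Large aging colonies of humanized-APOE mice are weighed roughly monthly,
but enrolment age, visit spacing, and series length differ widely between
animals, and a colony-wide mean weight curve hides subpopulations that
gain, lose, or hold weight during aging — the phenotypes that in humans
are associated with Alzheimer's disease risk. `ahmmtraj` models each
mouse's measurement series with an autoregressive hidden Markov model
(AHMM), groups mice by the hidden state their series ends in, and
validates the groups with survival, composition, and biomarker
statistics.

## The model

Each mouse contributes an observation sequence
$\{(a_t, w_t)\}_{t=1..k}$ of ages (months) and weights (grams) together
with its static sex and APOE genotype, governed by a latent first-order
Markov chain $H_t \in \{1, \dots, N\}$ with initial distribution $\pi$
and transition matrix $A = [a_{ij}]$. Conditional on $H_t = i$ the
observations factorize as

$$
p(\cdot \mid H_t = i) =
\mathcal{N}(a_t; \mu_i, \sigma^2_i)\;
\mathrm{Cat}(\mathrm{sex}; p^{sex}_i)\;
\mathrm{Cat}(\mathrm{genotype}; p^{geno}_i)\;
\mathcal{N}(w_t; \alpha_i + \delta_i\,[\mathrm{male}] + \phi_i\, w_{t-1},
\sigma^2_{w,i}),
$$

i.e. weight follows a state-specific AR(1) on the previous *measured*
weight with a state-specific male intercept offset $\delta_i$ (the
sex-weight interaction; males run several grams heavier throughout
life). The first visit of a series has no AR predecessor and uses a
separate per-state Gaussian $(\alpha^0_i + \delta^0_i[\mathrm{male}],
\sigma^2_{w0,i})$ rather than discarding the observation, so the minimum
usable series of three measurements stays fully informative. Static
covariates are re-emitted at every visit, as the per-slice observation
structure implies; a consequence worth knowing is that longer series
weight the sex/genotype terms more than short ones.

Because the AR parent of weight is *observed*, exact inference on this
chain — formally a junction-tree/clique-tree propagation — reduces to the
classical forward-backward recursions with modified per-visit emission
densities: conditioning on the observed previous weight changes only the
emission term, never the clique structure. `forward_backward()`
implements the scaled recursions (stable for series up to thousands of
visits); `viterbi()` decodes the most probable path with ties broken
toward the lower state index.

Irregular visit spacing is handled by the model's design rather than by
imputation or time-rescaling: each retained measurement is one Markov
step, and age is an observed emission carrying the time information. The
model never imputes missing visits.

## Fitting

`em_fit()` runs EM (Baum-Welch): exact forward-backward E-steps and
closed-form M-steps (normalized expected counts for $\pi$ and $A$,
responsibility-weighted frequencies for the categoricals,
responsibility-weighted moments for the age Gaussians, and
responsibility-weighted least squares on $(1, [\mathrm{male}],
w_{t-1})$ for the weight regressions). The total log-likelihood is
non-decreasing; the test suite asserts this on every fitted dataset.

Defaults follow the headline analysis protocol: $N = 10$ states, 10
random restarts, up to 1,500 iterations each, best final likelihood
wins (`fit_with_restarts()`). An early stop at
$|\Delta \mathcal{L}| < 10^{-8} |\mathcal{L}|$ is on by default; with it,
well-behaved fits converge in tens to a few hundred iterations. Numerical
guards: all variances floored at $10^{-3}\,\mathrm{g}^2$, probabilities
floored at $10^{-12}$ before normalization, emissions clamped at the
$\log 0$ sentinel $-10^{10}$, and a state whose total responsibility
collapses is re-seeded from a random observation with a warning.

Initialization matters for this likelihood surface. Flat random starts
reliably reach a degenerate family of optima in which the AR slope drifts
to $\phi \approx 1$ (weight explained as a random walk) and the states
specialize on age alone. We therefore initialize from a k-means
clustering of the observations — alternating between a weight-only view
(targets level-separated states) and a joint age-weight view (targets
age-structured states) across restarts — push the hard labels through
one closed-form M-step, and seed the weight regression at the cluster
level with a randomized moderate slope ($\phi_0 \sim U(0.05, 0.5)$).
EM raises $\phi$ smoothly when the data call for it, but this start
keeps the weight-anchored basin reachable.

States of the selected fit are relabeled canonically by their implied
stationary weight level $\alpha_i / (1 - \phi_i)$ (ascending, labels
`A`, `B`, ...), so labels are stable across restarts and platforms;
relabeling never changes the likelihood.

## From transition matrix to trajectories

`classify_states()` applies the ending-state rule: a state is *ending*
when its self-transition probability exceeds 0.3 (strict inequality on
the diagonal). Among non-ending states, those with the least incoming
probability mass are *starting*, the rest *intermediate*. Mice are
assigned to the state their series ends in — by default the argmax of
the smoothed posterior at the final visit (`assign_terminal_states()`,
with a Viterbi-last alternative behind a flag) — and mice terminating in
an ending state form one trajectory group per such state; the rest are
reported as unassigned, mirroring the fraction of colony mice without a
stable end state.

Group phenotypes are quantified by `trajectory_curve()` (mean ± SD
weight in 1-month age bins centred on integer months, matching the
monthly weighing cadence; bins with fewer than 3 member mice are
omitted) and `percent_weight_change()` (signed percent change of the
group mean from the bin nearest 12 months — the end of the growth phase
and the conventional middle-age anchor, matched within ±1 month because
irregular sampling rarely hits 12.0 exactly — to the last qualifying
bin).

## Post-hoc validation

Survival uses time from birth to death, censoring at the last weight
measurement for mice alive, and excludes sacrificed mice entirely (their
endpoint reflects an experimental schedule, not mortality; changing
unrelated flags never changes the result). `km_estimate()` is the
product-limit estimator, `median_survival()` the first time the curve
reaches 0.5, and `logrank_test()` the standard K-sample log-rank with
the exact hypergeometric covariance on K-1 groups (generalized inverse
for degenerate tables). These are implemented in-package and
cross-checked against `survival::survfit()`/`survdiff()` in the test
suite only.

Composition is compared with Pearson chi-square tests without continuity
correction (overall and pairwise modes); biomarker and body-composition
contrasts default to Welch's unequal-variance t test (a pooled-variance
flag exists; the analysis convention this mirrors does not specify the
variant, and Welch is the safer default). No multiplicity correction is
applied by default, matching the unadjusted reporting convention, but a
Holm-adjusted column is always emitted alongside. The adipose index is
`100 * fat / (fat + lean + free_water)`.

Cross-sectional measurements collected once per mouse (glucose, gait,
recognition, body composition) are attached to the model by
`infer_state_single_obs()`: the posterior over hidden states given one
(age, weight, sex, genotype) observation, using the first-visit weight
Gaussian and, by default, the stationary distribution of the fitted
transition matrix as prior (the long-run occupancy; the fitted initial
distribution is available as an alternative — the choice is a genuine
judgment call since a single observation carries no position in the
chain, and stationarity is the neutral assumption for a mouse sampled at
an arbitrary point of its life).

## The synthetic colony generator

`simulate_colony()` draws colonies with known ground truth so that every
stage has a parameter-recovery and end-to-end test surface. The default
configuration (`colony_config()`) emulates the published colony's
conditions: 1,196 mice, 45/55 female/male, genotypes 30/28/42%
(E3/3, E3/4, E4/4), first visit at 5-8 months, roughly monthly visits to
28 months with 10% missingness beyond the third visit, state-dependent
constant-hazard mortality (exponential waiting times between visits),
and state-dependent biomarker means with the gain archetype highest.

Its generative structure is a shared *young growth chain* (four
transient states, ages ~5-11 months, self-transition 0.22 — below the
0.3 ending threshold) that branches into five persistent phenotype
archetypes (three loss levels, one stable, one gain; self-transition
0.94+). Branching is genotype-coupled (the gain archetype enriched for
E4/4 carriers) and optionally sex-coupled, which gives composition tests
real signal. Weight in a state follows that state's AR(1); the first
visit is drawn from the young chain's first-visit Gaussian at a
young-adult level, so weights diverge from a common growth path toward
each archetype's stationary level. We deliberately do *not* draw the
first weight from the archetype's stationary marginal: with persistent
states that choice makes every group's mean curve flat and destroys the
gain/loss/stable structure the generator exists to emulate.

Two reference designs are exported for experiments.
`progression_colony_config()` is a single-track young/middle/old
progression (levels 18, 30, 42 g over ages 5-22 months) whose states are
simultaneously age bands and weight levels; on it the generative
parameters are identifiable and EM recovers the transition matrix to
within a few hundredths, with a wide first-visit weight spread supplying
the high-leverage pairs that pin down the young state's AR slope.
`branching_colony_config()` is the well-separated five-archetype design
(levels 13-42 g, strong sex/genotype branch fingerprints, follow-up to
~17 months) used for end-to-end trajectory recovery;
`trajectory_agreement()` scores a fitted grouping against the ground
truth.

What the generator does **not** emulate: litter, cage, diet-change, and
seasonal effects; measurement-device error structure; informative
missingness (visits are dropped completely at random); and
age-continuous mortality within the visit grid beyond the per-state
constant hazard. Passing tests on synthetic colonies therefore
demonstrate the correctness and statistical behaviour of the machinery
under the model's own assumptions, not fidelity of any particular real
colony.

### A note on identifiability, honestly

Because the model emits age from per-state Gaussians, its maximum
likelihood genuinely prefers state allocations that stratify age. When
phenotype archetypes run in parallel over a long age span, solutions
that merge the two closest weight levels and spend the freed state on an
extra age band can carry higher likelihood than the generative
structure, and best-of-restarts selection will (correctly, by its own
criterion) pick them. This is a property of the model family, not a
bug: on real colony data the discovered states are age-weight compounds
too, and trajectory groups are defined operationally by the fitted
ending states rather than by a claim that the fit equals a generative
truth. The design choices in `branching_colony_config()` (short
archetype phase relative to the follow-up, wide level gaps, categorical
branch fingerprints) push the generative structure close to the model's
preferred solution; recovery there is complete in most seeds but not
guaranteed in every one, and the test suite reports this property at its
face value.

The exclusion rules interact with the generator in one more way worth
noting: the rapid-loss rule (monthly loss over 20% between consecutive
measurements, normalized to a 30.44-day month, pairs closer than 15 days
skipped) caps how fast a loss archetype may pull weight down without its
members being excluded from the cohort; loss archetypes in the reference
designs approach their levels at rates below the cap.

## Preprocessing

`apply_exclusions()` applies the cohort rules in a fixed order: breeders
out (diet-change confound, input flag); record-level date sanity
(measurements before birth or after death); records under 5 months of
age dropped; rapid-loss mice excluded; then mice with fewer than 3
remaining records excluded. Record-level sanitation precedes the
minimum-points count so the rule applies to clean records, and the whole
procedure is idempotent and order-insensitive, with a reconciling
exclusion report (input = retained + excluded, every exclusion carries a
reason).

## Problem sizes used in the checks

The packaged experiments run at sizes chosen to exercise the claims
meaningfully: exhaustive-enumeration checks at $N \le 4$, $k \le 6$
(hundreds of random instances); EM monotonicity across dozens of
dataset-seed pairs; parameter recovery at 300 mice and ten seeds on the
progression design; end-to-end trajectory recovery at 600 mice and ten
seeds on the branching design with two to three restarts and early
stopping; and the pipeline demonstration on a full-size default colony
with three restarts. The full published protocol (10 restarts of 1,500
iterations at N = 10) remains the package default for real analyses.

## Worked example

```{r example, eval = FALSE}
cfg <- colony_config(n_mice = 400, seed = 1)
truth <- generate_true_params(cfg)
sim <- simulate_colony(truth, cfg)

loaded <- colony_from_table(sim$colony)
pre <- apply_exclusions(loaded$mice)
seqs <- as_observation_sequences(pre$retained)

fit <- fit_with_restarts(seqs, n_states = 9, n_iters = 300,
                         n_restarts = 3, master_seed = 1)
cls <- classify_states(fit)
asg <- assign_terminal_states(seqs, fit)
grp <- group_by_trajectory(asg, cls)
sapply(grp$groups, function(g) percent_weight_change(g, seqs))

surv <- make_survival_records(pre$retained,
                              groups = setNames(asg$state, asg$mouse_id))
logrank_test(surv[!is.na(surv$group), ])
```

## Known limitations

Single-order autoregression only; no continuous-time transitions (a
mouse weighed twice in quick succession takes two Markov steps); static
covariates re-emitted per slice (see above); the ending-state threshold
is a fixed rule, not an inferred quantity; and terminal-state assignment
confidence is the smoothed posterior mass, which can be close to 1/N for
short series even when the group structure is real.
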
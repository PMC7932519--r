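---
title: "Temporal affect networks from experience sampling data: models, metrics and comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal affect networks from experience sampling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`affectnet` implements a complete pipeline for asking whether the *dynamics*
of momentary affect — how states like feeling down or cheerful push each
other around from moment to moment in daily life — differ between groups of
people on different symptom trajectories. The pipeline covers (i) a
synthetic experience-sampling (ESM) cohort generator with known
ground-truth dynamics, (ii) preprocessing and inclusion diagnostics,
(iii) symptom-change group composition with multiverse variants, (iv)
multilevel lagged regression models assembled into directed networks, (v)
network summary statistics, and (vi) permutation tests for group
differences. This vignette explains the models and the design choices.

## The data and the model

The unit of observation is a *beep*: a semi-random prompt at which a person
rates six momentary affect states — three positive-valence items
(*cheerful*, *relaxed*, *energetic*) and three negative-valence items
(*irritated*, *down*, *lonely*) — on a 1–7 Likert scale. The emulated
design collects 10 beeps per day between 07:30 and 22:30 (mean gap about
90 minutes) on 6 consecutive days, for persons nested in twin families.
Only beeps with all six items present count as observed; persons missing
more than 30% of the 60 scheduled beeps are excluded (strictly more: 18/60
missing is kept, 19/60 is not).

The temporal network is defined by six multilevel lagged regressions, one
per outcome state $j$:

$$
y^{(j)}_{i,t} \;=\; \beta_0 + \sum_{k=1}^{6} b_{jk}\,
\tilde y^{(k)}_{i,t-1} + \beta_{\text{time}}\, t
+ u_{f(i)} + v_{i} + \sum_k w_{ik}\,\tilde y^{(k)}_{i,t-1}
+ w_{i,\text{time}}\,t + \varepsilon_{i,t},
$$

where $\tilde y^{(k)}_{i,t-1}$ is the *person-mean-centered* rating of
state $k$ at the previous beep (centering isolates within-person
fluctuation; the outcome is left raw because the random intercepts absorb
levels), $u_{f(i)}$ is a family-level random intercept, $v_i$ a
person-level random intercept, and $w_{i\cdot}$ person-level random slopes
with a *diagonal* covariance. The residual $\varepsilon_{i,t}$ carries a
continuous-time AR(1) correlation $\phi^{\Delta t}$ over the within-person
observation order, with $\Delta t$ in hours of clock time (order-based
AR(1) is the fallback when timestamps are absent). Estimation is by
maximum likelihood through `nlme`, which keeps AIC comparisons coherent
across structures that share fixed effects. Fixed-effect p-values use a
normal reference for estimate/SE; no degrees-of-freedom convention is
imposed.

Lag pairs are formed only from *consecutive same-day* beeps with both
observations complete: lags over the night are excluded, so each day
starts a fresh chain. The time covariate is the beep number over the whole
period (1–60); internally it is rescaled by the scheduled beep count for
numerical conditioning and reported back per beep.

The fixed effects $b_{jk}$ populate the network: `W[j, k]` is the directed
edge $k \rightarrow j$ (effect of state $k$ at $t-1$ on state $j$ at $t$),
with autoregressions on the diagonal. Edge lists are emitted as
`(from = k, to = j)`.

### The convergence ladder

Mixed models of this size do not always converge. `fit_lagged_model()`
walks a fixed ladder, recording the rung used: full model (AR(1) +
random slopes) → drop AR(1) → intercepts only → person intercept only →
pooled regression with person-clustered robust standard errors. The
bottom rung always fits, because person-mean-centered predictors absorb
person levels. With `aic_compare = TRUE` the two top rungs are both fitted
when the full model converges and the AIC-better one is reported — the
"best model fit by AIC" rule; it is off by default because it doubles the
cost of every fit and, in our simulations, the two rungs give practically
identical fixed effects. Convergence is governed by `max_iter` (default
100) on `nlme`'s `optim` path.

### The two estimator tiers

Everything downstream can run on either of two estimators:

* **full** — the multilevel ladder above; the estimator of record for
  reported networks.
* **fast** — a two-stage estimator: one ordinary least-squares lagged
  regression per person (all six outcomes share one QR decomposition),
  averaged within group; standard errors from the between-person spread of
  coefficients and t-based p-values with $n_{\text{persons}} - 1$ degrees
  of freedom.

The fast tier exists because a permutation test re-estimates both group
networks in every replicate; re-fitting the multilevel ladder ten thousand
times is not tractable, while re-averaging precomputed person-level
coefficient matrices is essentially free. In the zero-random-effect limit
the two tiers agree (a tested invariant), and at study scale their group
differences track each other closely. Persons contributing fewer than 12
analysis rows (or a rank-deficient design) are dropped from the fast tier.

## Network statistics

* **Negative connectivity** — the sum of absolute edge weights among the
  negative nodes, excluding self-loops by default ("paths *between*
  nodes"); a flag includes them for sensitivity.
* **Out-strength centrality** — the summed outgoing edges of a node to the
  *other* nodes. Absolute values by default, so inhibitory influence also
  counts; a signed mode is available because the field's convention is not
  settled.
* **Cross-valence effects** — the summed magnitude of the nine edges from
  positive to negative states (PA→NA) and vice versa (NA→PA).
* **Reinforcing cycles** — simple directed cycles of length 2–3 among a
  same-valence node subset in the significance-filtered network
  (`p < 0.05` edges), with every edge weight positive: the structural
  signature of a "vicious cycle" such as down ↔ lonely. The cycle's
  strength is its weakest edge. This is a structural claim only; no
  dynamical activation of the cycle is simulated.

An internal-consistency identity ties these together: negative
connectivity equals the summed out-strengths of negative nodes restricted
to negative targets. Scaling the network scales all summed metrics
proportionally and leaves the cycle inventory unchanged.

## Group composition

The one-year symptom course is the change in the SCL-90 sum score
(90 items × 1–5, so sums live in [90, 450]): `scl_t1 - scl_t0`. Cohort
screening keeps persons scoring strictly *below* the cohort median on the
four positively-phrased childhood-experience items (JTV, sums in [4, 20]);
"below the median" is read strictly, with a weak variant available.
Change scores are then cut into tertiles by a stable rank ordering on
(change, person id): lowest third → Decrease, middle → Stable, highest →
Increase, with boundary ranks at `round(n * p)` so group sizes differ by
at most one before ties; ties straddling a boundary split
deterministically by person id. The Decrease tertile is excluded by
default because its inflated baseline makes network comparisons
confounded by item-variance differences; `assign_groups()` always attaches
a baseline-comparability report (pairwise Welch tests of `scl_t0`) so that
rationale is checked rather than assumed.

`multiverse_grid()` re-runs the grouping under a grid of defensible
cutoffs — by default the quantile pairs (25, 75), (30, 70), (33.3, 66.7),
(40, 60), chosen to bracket the tertile rule symmetrically — and
`multiverse_report()` summarises how often each qualitative feature (a
significant signed edge, a reinforcing cycle) survives across
assignments. Absolute-cutoff specifications assign ties to the lower
group.

## Permutation testing

Group labels are shuffled across permutation units — whole families by
default, so twins always carry the same label and the family-level
dependence is respected; person-level shuffling is available for
comparison. Group sizes are preserved in every replicate; both networks
are re-estimated (fast tier) and the metric difference recorded. The
two-sided p-value uses the add-one rule
$p = (1 + \#\{|d^{\text{perm}}| \ge |d^{\text{obs}}|\})/(1 + n_{\text{perm}})$,
so $p \in (0, 1]$ and exact-zero p-values cannot occur. No multiple-testing
correction is applied across metrics; each metric's p-value is reported
per metric. The exact null construction of the original permutation
procedure is not published in full; group-label permutation over
persons/families is this package's documented interpretation, and results
should be read with that divergence risk in mind.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the conditions under
which every downstream claim is checked.

Each person's latent affect state follows a stationary VAR(1) within days:
$x_t = \mu_p + \delta\,t + z_t$, $z_t = B_p z_{t-1} + e_t$, with $e_t$ an
AR(1) residual (correlation $\phi^{\Delta t}$ per hour, default
$\phi = 0.2$). The first beep of every day is drawn from the person's
stationary marginal — an *overnight reset*, chosen because overnight lags
are excluded from the analysis anyway, which keeps the generator's
estimand exactly the quantity the models estimate. Person means combine a
family-level deviation (SD 0.3 per node) and a person-level deviation
(SD 0.5); person transition matrices add independent N(0, 0.05²) entrywise
deviations (diagonal covariance, mirroring the fitted random-slope
structure), redrawn if non-stationary. The default drift $\delta$ is zero.
Innovation SDs are calibrated by an exact discrete-Lyapunov solve (on the
augmented state $(z_t, e_t)$) so each node's latent stationary SD is 1.0,
matching items selected for within-person SDs near one.

Observation is round-half-up then clipping into [1, 7]; missingness is
beep-level MCAR (default 25%) and drops all six items together, because
the analysis is complete-case anyway. Ground-truth transition matrices per
group: the Stable matrix has an interconnected positive cluster that
dampens *down* and **no** lagged connections among negative states; the
Increase matrix shares the positive cluster but adds a connected negative
cluster with reciprocal down ↔ lonely edges of 0.25 — the injected
vicious-cycle structure. Node means, SCL-90 baselines and changes
(Stable −5.04 ± 4.95, Increase +25.7 ± 22.5, Decrease −41.48 ± 33.09, with
the Decrease baseline inflated), JTV sums, age and sex follow the observed
group-level distributions of the cohort design this generator emulates.
SCL scores are truncated into scale bounds by resampling rather than
clipping, avoiding boundary point masses; note truncation necessarily
shifts the realized mean change upward for the Decrease group (removing a
~13% lower tail shifts a normal mean by about a quarter SD) — the tests
check against the analytic truncated mean.

### What the generator does not emulate

Real ESM data have floor effects *with* skewness rather than a censored
Gaussian, item-level (not only beep-level) missingness that is unlikely to
be MCAR, circadian mean structure, measurement reactivity, and extra
morning/evening items that can push the filled-in observation count above
the 60 scheduled main beeps. Twin resemblance is reduced to a shared
family-level intercept; zygosity and heritability are out of scope.
Passing recovery tests on this generator therefore shows the estimator is
faithful *under the stated model*, not that real cohort estimates are
unbiased — in particular, floor-heavy items (*down*, *lonely* have means
near 1.8 with SD 1) attenuate latent-scale coefficients in ways no
complete-case estimator can undo.

## Numerical choices and degenerate inputs

* Schedules use stratified-interval jitter (one uniform draw per equal
  block of the day window), which yields the target mean gap with no
  collision handling; an infeasible window errors at configuration time.
* The Likert map is round-half-up (`floor(x + 0.5)`), not banker's
  rounding, so `3.5 → 4` deterministically.
* Singular designs error early and name the offending column (constant
  predictor, outcome duplicated as predictor, collinear predictors,
  fewer rows than parameters).
* `stationary_cov()` symmetrises the Lyapunov solution and refuses
  spectral radius ≥ 1; zero-innovation configs short-circuit to the
  deterministic fixed point.
* The add-one permutation p-value uses a `1e-12` slack on the
  `>=` comparison so floating-point ties count as exceedances.
* Tertile boundaries at `round(n * p)` reproduce near-equal thirds
  (80/79/80 at n = 239); an all-equal JTV vector errors with guidance
  rather than returning an empty cohort.

## Problem sizes used in the checks

The package's own test suite runs the full estimator recovery on 20
simulated Stable-style cohorts of 80 persons in 40 families (6 × 10 beeps,
25% missingness), permutation calibration on 200 null experiments of 24
persons per group at 199 permutations, and qualitative-structure recovery
on 20 replicates of 80 persons per group with the fast-tier estimator —
sizes chosen to mirror the emulated study design while keeping a complete
run on one CPU inside tens of minutes. The two calibrated expectations
worth restating: per-edge tests at $\alpha = 0.05$ imply a
$0.95^6 \approx 0.74$ chance that all six true-null negative–negative
edges stay clean in any one Stable network, and truncation shifts the
Decrease mean change — both are properties of the design, not bugs.

## Limitations

Group-level networks say nothing about any individual's dynamics; the
estimand is the average within-person lagged effect. The permutation
scheme is an interpretation (see above). Contemporaneous (residual)
networks, regularised estimation, and person-specific networks are out of
scope by design. Coefficients are on the observed Likert scale; with
floor-heavy items they underestimate latent-scale dynamics.
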
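---
title: "Models and methods: within-session fatigue and time-of-day effects in learning-session logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: within-session fatigue and time-of-day effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diurnalfatigue)
```

## The scientific question

When people study voluntarily in a spaced-repetition app, two very different
kinds of "running out of steam" can show up in their logs. The first is
*within-task mental fatigue*: accuracy declining the longer a single session
lasts. The second is *domain-general depletion* (the "ego depletion" or
limited-resource account of self-control): the prediction that a day full of
effortful activities leaves people less willing and less able to study in
the evening, whatever they did earlier. Session logs with 24-hour coverage
let both be measured on the same data: fatigue from the accuracy trajectory
within sessions, and depletion from how login activity, session length and
session accuracy vary with time of day.

`diurnalfatigue` implements that full analysis pipeline — and, because the
cohorts that motivate it are proprietary, a synthetic session-log generator
whose every latent parameter is exposed, so each inferential stage is
validated by parameter recovery rather than by reference to unavailable
data.

## Data model and screening

A *trial log* has one row per event: user, session, 1-based trial index,
event type (`learn` or `test`), UTC timestamp, the user's UTC offset (or
missing), correctness (test events only) and elapsed seconds since the
session started. `read_session_log()`/`write_session_log()` round-trip a
plain CSV dialect byte-for-byte; validation rejects malformed rows with
line-numbered diagnostics.

Local session start times come from `localize_times()`, in two modes that
deliberately mirror a two-cohort replication design: `"none"` (raw clock
time, for a cohort whose offsets are unknown) and `"per_user_offset"`
(shifted modulo 24 by each user's offset). Screening (`screen_sessions()`)
applies configurable filters in a fixed order — trial, then session, then
user level — with defaults of at least 5 test trials per session, sessions
no longer than 6 hours, and at least 2 sessions per user. These defaults
are conservative stand-ins, not canonical: the exact screening rules of the
motivating studies are not public, so every threshold is an explicit
parameter and the screening report accounts for every removal. Screening is
idempotent because the user-level rule cannot re-invalidate sessions.

## The synthetic cohort generator

`generator_config()` parameterises the structure the analyses assume:

* over-dispersed per-user session counts (negative binomial; the
  `reference_cohort_config()` preset uses mean 16.81, SD 15.71) and session
  lengths (preset ~58.6 trials, SD 45.3, ~17.2 s per trial, so ~16.8
  minutes);
* a diurnal login intensity given as a harmonic curve, floored at zero and
  normalised over 48 half-hour bins (the preset peaks late in the evening
  near 21:30 with a deep trough near 04:00);
* accuracy on the *probability scale* as an additive sum: a quadratic
  fatigue curve in trial index, an early-session difficulty handicap, a
  diurnal modulation of session-level accuracy, user random intercepts and
  slopes, and session random intercepts, clamped to [0.01, 0.99] before
  Bernoulli sampling. The additive-probability convention (rather than a
  logit link) is deliberate: the downstream models are linear in accuracy,
  so recovery targets stay on the scale the analyses report.

The preset fatigue curve is constructed, not fitted: the vertex
$-\beta_1/(2\beta_2)$ sits at trial 75 and the latent drop from trial 75 to
trial 150 is exactly 5%, with $\beta_0 = 0.80$. The difficulty handicap is
a negative term decaying as $e^{-(k-1)/3}$ over the first ~10 *test* trials
(harder items are scheduled early in spaced-repetition systems), which is
intentionally *not* modelled in the fatigue fit — it makes the fitted
fatigue estimate conservative, and the generator exists partly to quantify
that conservatism. Learn trials are interleaved at random positions with a
configurable fraction (preset 0.30) and carry no correctness.

All sampling comes from one seeded stream in a fixed order, so
`generate_log()` is bit-reproducible, and the returned truth record stores
every sampled latent.

Things the generator deliberately does **not** emulate: the actual
(proprietary) item-scheduling algorithm, email prompts, weekday/weekend or
term-time structure, user-level diurnal preferences, and any correlation
between a user's preferred study time and their ability. Passing recovery
tests therefore shows the *estimators* are correct under the assumed
structure — not that real cohorts satisfy that structure.

## Within-session fatigue

`smooth_sessions()` drops learn events while keeping the original trial
order (so index gaps remain), then averages correctness over consecutive
bins of 5 test trials. Bins span learn-trial gaps rather than resetting at
them — a convention, since either reading of "every 5 trials" is
defensible; the bin's axis value is the mean original trial index (or mean
elapsed minutes). Trailing partial bins are dropped by default so that bin
variance stays homogeneous; `drop_partial = FALSE` keeps them.

`fit_fatigue()` fits maximum-likelihood multilevel models (lme4,
`REML = FALSE`) of bin accuracy on a null, linear or quadratic polynomial
of the axis, with a random intercept and linear slope per user. The
quadratic term is fixed-only in the default structure: richer random
structures routinely fail to converge on data of this shape, and an honest
`converged` flag (with optimizer messages) is part of the fit object —
boundary/singular fits are flagged separately, because a zero variance
component is a legitimate optimum, not a failure. Internally the axis is
divided by 100 for optimizer conditioning and coefficients are transformed
back. `compare_fits()` applies the conventional rule that an information
criterion difference of at least 2 is meaningful support; smaller margins
are reported as "indistinguishable". `quadratic_summary()` turns a concave
quadratic fit into the two quantities of interest, the accuracy peak
$-\hat\beta_1/(2\hat\beta_2)$ and the drop from that peak to a horizon
(150 trials by default).

The recovery study used by the tests draws 500-user cohorts (3 sessions per
user, ~150-trial sessions so the observed range brackets both the vertex
and the horizon, no difficulty handicap) from the constructed truth and
checks that the fitted vertex lands in [65, 85] and the fitted drop in
[0.03, 0.07] in at least 90% of 20 seeded replicates, with the quadratic
beating the linear model by at least 2 AIC points in at least 95%.

## Time-of-day analyses

`bin_day()` aggregates session summaries into 48 half-open half-hour bins
of local start time: mean session accuracy, mean session length, or login
fraction (counts rescaled to sum to 1, which makes two cohorts of very
different sizes comparable). The bin weight is its session count; empty
bins are omitted from likelihoods rather than imputed.

`fit_day_model()` regresses bin values on a harmonic (cosinor) basis —
sine/cosine pairs of period 24 h up to order K, kept in coefficient form so
the model stays linear — or on intercept/linear/quadratic-in-time
baselines, weighting each bin as a mean of `weight` replicates with
variance $\sigma^2/w$ (this matches weighted least squares at the mode).
Two engines share that likelihood:

* **weighted least squares** for point fits (used wherever exactness
  matters: noise-free harmonic series are recovered to 1e-8);
* **Bayesian weighted normal regression** wherever WAIC is needed. Priors
  are weakly informative — coefficients $N(0, (10\,\mathrm{sd}(y))^2)$,
  residual SD half-normal with scale $2.5\,\mathrm{sd}(y)$. Because the
  coefficient block is conjugate given $\sigma$, the $\sigma$ marginal is
  computed exactly on a dense log-spaced grid (320 points spanning a wide
  bracket of the WLS residual SD) and 2000 joint draws are taken without
  MCMC, so the posterior is deterministic given a seed and has no
  convergence diagnostics to tune. WAIC is computed from the pointwise
  log-densities as $-2(\mathrm{lppd} - p_\mathrm{waic})$.

The original analyses report WAIC without stating their posterior
machinery, so absolute WAIC values are not reproduction targets anywhere in
this package — only the selection logic is: which model wins, with the
same "difference of at least 2" reading used for AIC (ties are reported as
a tied set).

`oos_rmse()` evaluates a *frozen* model on a new binned series with no
refitting — the replication currency of a two-cohort design — and
`replication_protocol()` chains the exact three stages: WAIC selection on
cohort 1 (clock time), frozen-model RMSE on cohort 2 (clock time, the
direct replication), and a WAIC refit on cohort 2 with timezone adjustment.

## Theoretical daily-behaviour curves

`build_theory()` realises three competing accounts of daily behaviour as
mean ± SD curves over the day, each a smoothed piecewise-linear family with
every anchor exposed in `theory_params()` (defaults: wake 07:00, sleep
onset 01:00, evening rise from 18:00, SD ribbon 15% of the plateau):

* **limited self-control**: activity peaks right after wake and declines
  monotonically until sleep — what a finite, domain-general resource
  predicts;
* **unlimited self-control**: a flat waking plateau with a night trough —
  the null account;
* **evening preference**: a flat day level rising monotonically after an
  evening onset — daytime obligations pushing voluntary learning into the
  evening.

The exact curve parameterisations behind the original figures are not
public, so the curves here are documented defaults and the package's claims
are about the *scoring machinery*, not about reproducing specific deviance
values. Scoring is Gaussian negative log-likelihood — the minimal
location-scale likelihood consistent with a mean ± SD specification — with
observations min-max standardised to [0, 1] so one curve family serves
accuracy, login fraction and session length (both the standardisation and
the per-session vs per-bin observation unit are explicit options, since the
choice changes NLL magnitudes by orders of magnitude). Self-consistency is
the acceptance property: data generated under each curve are won by their
generator in at least 90% of seeded replicates.

## Moderation of fatigue by time of day

`extract_session_coefs()` refits the quadratic fatigue model grouped within
users *and* sessions and returns each session's empirical-Bayes coefficient
realization (fixed effect + user deviation + session deviation) for the
intercept, linear and quadratic terms. This pathway needs per-session
quadratic variation, so its random structure carries diagonal (uncorrelated)
intercept/linear/quadratic terms at both levels — the `||` form exists
precisely because the correlated version routinely fails to converge; a
genuine non-convergence is an error instructing the user-grouped fallback,
never a silent substitution. Coefficients are model-based (shrunken)
predictions, not per-session refits: shrinkage is why the recovery test for
a session-intercept SD of 0.05 accepts [0.03, 0.07] rather than a point.

`moderate_by_time()` regresses each component on $\sin(2\pi t/24)$ and
$\cos(2\pi t/24)$ by OLS — unweighted by default, matching the exploratory
status of this analysis, with cluster-robust (by user) standard errors as
an option — and applies the strict critical value $\alpha = .008 \approx
.05/6$ for the 6-test family (3 components × 2 terms). A joint
sine + cosine F test per component is reported alongside the per-term t
tests, since both readings of "regressed onto the sine and cos function"
are in use. Under a time-independent truth the per-test rejection rate
stays within binomial tolerance of .008 and the family-wise error of the
battery stays below .05 (the theoretical value under independence is
$1 - .992^6 = .047$, which is why the family-wise check simulates 20,000
replicate datasets — enough that the Monte-Carlo standard error of ~.0015
makes the bound meaningful).

## The depletion simulator

`simulate_day()` is a discrete-time (default 5-minute steps) agent
simulation of the population-level prediction that a finite self-control
reservoir generates: agents wake at normally distributed times, face tasks
arriving at `task_rate` per awake hour that deplete a [0, 1] reservoir by a
truncated-normal demand, recover a little on restful idle steps, and
recover toward full during sleep. The acceptance properties are exact where
the dynamics are degenerate (zero task rate ⇒ flat at 1; zero recovery with
a common wake time ⇒ monotone non-increasing awake-population mean — the
common wake time matters, because freshly waking agents enter the awake
pool at full reservoir and can otherwise raise its mean) and stochastic for
the headline: under the deliberately lenient preset (0.5 tasks/h, demand
0.05 ± 0.02, rest probability 0.3, recovery 0.02/h, 10,000 agents) the
awake-population mean is already lower one hour after the mean wake time,
and its daily minimum falls in the afternoon or later, across 20 seeds.
The simulator is a minimal documented realization of that qualitative
claim — its exact original rules are not public — and it is not fitted to
data. Multi-day steady state is out of scope for the single-day version.

## The end-to-end study and its demonstration

`run_study()` chains everything under one config with full determinism:
screening both cohorts, fatigue fits and AIC tables per cohort, the
three-stage diurnal replication per metric, theory deviance tables over the
three dataset variants (cohort 1, cohort 2 direct, cohort 2
timezone-adjusted — the layout of a three-column deviance table), and the
moderation stage. `study_demo()` generates two reference-preset cohorts
(250 users each by default; cohort 1 on a single timezone, cohort 2 with
the mixed UTC-9..-5 offsets) and recovers the qualitative headline pattern
by construction: the quadratic is the within-session winner in both
cohorts, evening preference wins the login deviance in all three variants,
and fatigue-shape moderation by time of day is small or absent. "Small or
absent" is asserted the way a replication design reads it — no shape term
significant in *both* cohorts and modulation amplitudes a small fraction
of the fixed effects — because a single-cohort false positive at
$\alpha = .008$ is an expected event, not a failure.

## Problem sizes, numerical choices and limitations

The simulation studies run at deliberate desk scale: 500-user cohorts for
fatigue recovery, 48-bin series with weight-25 bins and noise SD 0.03 for
WAIC selection (signal amplitudes 0.06–0.1, the regime where the
penalisation actually has work to do), 150-point datasets for theory
scoring, 200-session datasets for moderation error rates, 250-user cohorts
in the demo. These sizes were chosen so every property is decided with
comfortable Monte-Carlo margins while the whole battery stays fast; none
of them is a claim about the minimum data a real analysis needs.

Numerical conventions worth knowing: half-open bins $[k/2, (k+1)/2)$
everywhere (no double counting at bin edges); bins with zero weight are
omitted, never imputed; the harmonic design is evaluated at bin midpoints;
the fatigue axis is rescaled by 1/100 inside the optimizer; accuracy
probabilities are clamped to [0.01, 0.99] in the generator; WAIC ties are
broken by reporting the tied set rather than forcing a winner; and every
stochastic routine takes an explicit seed and restores the caller's RNG
state.

Known limitations: the time-of-day analyses do not model user-level
diurnal preference (a real confound if night owls differ in ability); the
fatigue fit inherits the conservatism of non-random item difficulty; the
theory curves are one documented parameterisation of three qualitative
shapes; and the depletion simulator is a single-day, discrete-time
idealisation.
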
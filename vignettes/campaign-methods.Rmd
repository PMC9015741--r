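---
title: "Adaptive goal setting and engagement analysis: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive goal setting and engagement analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalwave)
```

This vignette documents the science inside `goalwave`: the personalization
and scoring rules of the campaign engine, the generative model of the
synthetic cohorts, the statistical models of the analysis layer, and the
design choices made where the design was genuinely open.

## The campaign engine

A campaign runs for `W` waves (default 4) of `wave_days` days (default 14).
Each participant holds six tasks per wave; three are *dynamic* with
complexity parameters: the minimum distance of a longer walk (meters), the
minimum distance of a longer bike ride (meters), and the number of rewarded
sports sessions per week (the frequency parameter `X`).

### Personalization

For the personalized arm, each parameter at the commencement of wave `w` is

$$\mathrm{parameter}(w) \;=\; \mathrm{capability} +
(\mathrm{goal} - \mathrm{capability})\,\frac{w}{W},$$

rounded to the nearest integer task unit and then capped (walks 1–10 km,
rides 2–17.5 km, sports 2–10 sessions/week). The schedule reaches the goal
exactly in the final wave and is constant when goal equals capability. A
plausible alternative indexing, $(w-1)/(W-1)$, would start exactly at the
capability instead; we use $w/W$ because the intervention should already
stretch participants beyond their current level in wave 1 and must reach the
goal in wave `W`. Parameters are recomputed only at wave commencement, never
mid-wave.

Capabilities are resolved per activity dimension in strict priority order:

1. the intake self-report, transformed to task units — daily steps are
   multiplied by a 0.73 m average stride and divided over 3 walks per day;
   weekly bike kilometers are divided over 5 rides per week (so 7000
   steps/day → 1703 m, 10 km/week → 2000 m);
2. the participant's most recent recorded performance of that type (ties on
   the same day resolved to the larger magnitude);
3. the mean performance of all *other* users up to the scheduling instant;
4. fixed defaults: 1000 m (walk), 2000 m (ride), 2 sessions (sports).

For sports, "performance" needs a unit conversion that the intake does not:
an activity event records minutes, but the task unit is sessions/week. We
define a participant's last sports performance as the number of sports
events in their most recent 7-day scoring week containing one, and the
population average as the mean weekly sports-event count over other users'
active weeks. This is the one place where history-based fallbacks required
an interpretation rather than a transformation.

Goals are the transformed intake targets when stated. A completed intake
with no improvement target on a dimension is a *maintenance* goal: goal :=
capability, so the parameter is flat across waves. Without any intake the
fallback goal is capability × 1.1 for distances and capability + 1 for
sports — implemented as a fixed endpoint reached at wave `W`, not as a
per-wave compounding rate; compounding would make the effective improvement
depend on `W` and overshoot the stated 10%.

Rounding is half-up to the integer task unit (the transformation example
1703.33 → 1703 is unaffected; half-up avoids the round-to-even surprises of
IEEE rounding for `x.5` session counts).

The control arm follows the fixed guideline schedule (walks
1500/2000/2250/2500 m, rides 3500/4000/4250/4500 m, sports 4/4/5/5), which
raises task complexity by roughly 20–40% over the campaign.

### Scoring

Every registered activity is matched to the tasks rewarding its kind, kept
if it clears the threshold, and credited to the *single highest-points*
qualifying task: a 2.5 km walk is one trip, and crediting both the short-
and longer-walk tasks would double-count it; the per-task weekly maxima
also only make sense under single crediting. If the matched task's weekly
reward count or point cap is exhausted, the event earns nothing — it does
not fall back to a cheaper task. Weeks are consecutive 7-day windows
anchored at campaign start, so each 14-day wave contains exactly two
scoring weeks and weekly state never crosses a wave boundary. Sports points
are `40/X` kept as an exact numeric (for `X = 7` the weekly cap is enforced
on the exact value, with a small tolerance against floating-point
accumulation). Manual and tracker-sourced events are scored identically;
the source is retained for audit. Leaderboards rank wave totals within
organization (individuals) and mean wave totals (departments) and reset to
zero at each wave start; the reset period is configurable per organization
to accommodate sites that reset less often while still updating tasks every
two weeks.

### Allocation

Joining participants keep the default (control-style) task set until their
join wave ends, then are allocated by sequential minimization within their
goal-type stratum (`unknown`, `maintain`, `improve` — `unknown` is itself a
stratum, since participants without intake were still randomized): the arm
with fewer members wins, ties break by a seeded coin flip. This guarantees
per-stratum imbalance of at most one and reproduces near-equal overall
splits. Participants joining during the final wave are never allocated.
Batch-per-wave allocation would behave identically here because the balance
rule only depends on running tallies; the sequential variant is what the
package implements.

## The synthetic cohort generator

The generator emulates the study conditions the analysis layer assumes: 176
participants across 7 organizations joining over 4 waves, goal types split
93 unknown / 26 maintain / 57 improve (assigned deterministically by count,
not sampled, so the composition is exact), and engagement outcomes per
participant-wave following

$$y_{igr} = \beta_0 + \beta_{time}\, r + \beta_{goal} + \beta_{arm} +
u_i + v_g + \varepsilon_{igr},$$

with `r` the 0-based relative wave since the participant's first wave,
$u_i \sim N(0, \sigma_u^2)$, $v_g \sim N(0, \sigma_v^2)$,
$\varepsilon \sim N(0, \sigma_e^2)$. The default fixed effects are the
reported engagement effects that serve as ground truth: −1.174 visit days
per relative wave with +2.176 (maintain) and +1.625 (improve) goal effects;
−0.080 activities per wave with +1.535 and +3.258; +0.261/+0.917 longer
walks; +0.405/+0.318 sports sessions by goal and +0.276 if personalized.
Each outcome is generated from its own reported model independently — the
activity-count scale of the time effect (−0.080) is not forced to be
jointly consistent with the per-type counts, because the reported models
plainly used different outcome definitions and no single joint process can
satisfy all coefficients at once.

Unreported quantities are free configuration values, chosen once at what a
campaign of this kind plausibly produces and never acceptance-tested:
variance components $\sigma_u = 1.5$, $\sigma_v = 0.5$, $\sigma_e = 2.0$ on
the visit-days scale (0.8/0.3/1.0 for per-type counts); intercepts 8 visit
days and 5 activities at relative wave 0, 1.0–1.2 for per-type counts;
join-wave distribution 140/16/10/10 (fixing the 10 final-wave joiners);
posttest residual SD 0.05, scaled so the small reported perception effects
(+0.047) are identifiable at the posttest sample size of ~40.

Two generation modes exist because truncation biases linear-model recovery:

* **gaussian** — continuous outcomes, no truncation, no dropout; the linear
  mixed model is exactly correctly specified, so parameter recovery is
  unbiased and Monte-Carlo checks are sharp.
* **realistic** — visit days rounded and truncated to `[0, 14]`, counts to
  non-negative integers, and a discrete-time dropout process with logistic
  hazard $h(r) = \mathrm{logit}^{-1}(-1.0 + 0.3\,r)$ (about a third of
  participants lost after their first relative wave, rising thereafter) and
  a 0.15 per-wave reclaim probability. Used for pipeline demonstrations;
  fitting linear models to these count-like outcomes mirrors the original
  analysis but is not expected to recover the betas exactly.

What the generator does **not** emulate: GPS traces or within-day timing,
capability drift over the campaign, fraudulent manual registrations,
organization-specific recruitment dynamics, or any dependence of dropout on
arm or goal (dropout is covariate-independent by default). Passing tests on
synthetic cohorts therefore show that the pipeline is internally consistent
— estimator matches generator — not that real campaigns satisfy the model.
A `posttest_selection_bias` knob weights posttest response by engagement to
probe (not correct) response selection bias; the default is missing
completely at random.

## The analysis layer

**Dropout labeling.** A participant who did not visit the app during a wave
is assumed to have lost interest during the *previous* wave; a later visit
marks them reclaimed. The join wave always counts as visited. The count
regression (`dropouts ~ wave * arm`) uses waves `1..W−1`, since a dropout
during the final wave is unobservable (there is no following wave to miss).
Note that raw per-wave dropout counts conflate hazard with the shrinking
risk set: with a constant risk set an increasing hazard yields a positive
wave coefficient, while in a full cohort the declining number still at risk
can dominate. A participant-level logistic variant would separate these;
the count regression is what the package reports.

**Analysis subset.** Treatment evaluation keeps a participant-wave only if
the participant was allocated to an arm (final-wave joiners are excluded),
visited the app in at least two distinct waves (excluding registration-only
users), and visited during that wave. The filter is idempotent.

**Engagement models.** Linear mixed models (`lme4`) with random intercepts
for participants and organizations. Candidate fixed-effect structures are
every subset of the main effects (relative wave, goal type with reference
level `unknown`, arm) down to the intercept-only model, plus the full
main-effects model with each second-order interaction added singly and
jointly. Candidates are fit by maximum likelihood and compared by AIC over
an identical random structure — REML likelihoods are not comparable across
fixed-effect structures. Because models within about 2 AIC units of the
minimum are substantially equivalent, the most parsimonious candidate
inside that band is selected (remaining ties go to the lower AIC); plain
lowest-AIC selection over a candidate set in which a predictor appears many
times would retain a null predictor far more often than its single-test
inclusion rate suggests. The winner is refit by REML for reporting.
Including main-effect subsets lets selection drop a predictor with no
support (an arm with no effect is then absent from the selected model more
often than not), and makes a constant outcome select the intercept-only
model rather than fail.
p-values for fixed effects use the normal approximation of the t-ratio and
are documented as approximate; with the cluster counts involved (≥100
participants, 7 organizations) the approximation is adequate for screening
but not a substitute for profile or parametric-bootstrap intervals. With a
single organization in the data the organization intercept is dropped with
a warning; candidates that fail to fit are dropped from the comparison.

**Posttest models.** Ordinary linear models of the four posttest outcomes
(perceived walk/bike/sports performance impact, self-efficacy) on the total
number of waves visited, goal type, arm, and all second-order interactions,
restricted to respondents who used the app in more than one wave. Backward
elimination repeatedly removes the highest-p term above .05 using
`drop1()` F-tests, which only ever offer marginality-respecting deletions —
an interaction always leaves before its main effects. Elimination
terminates in at most as many steps as there are initial predictors.

## Numerical choices and degenerate inputs

* Integer task parameters use half-up rounding; caps are applied after
  interpolation, and capping is idempotent.
* The sports weekly point cap compares exact values with a `1e-9` tolerance.
* Zero-capability sports suggestions are overridden to 2 sessions/week by
  the cap, end to end.
* Empty event logs, empty posttest tables, single-arm dropout tables and
  constant outcomes all degrade to reduced models or empty results with
  warnings rather than errors.
* Equal-day scoring ties keep input order; totals within a week are
  order-insensitive for homogeneous events.

## Problem sizes

The test suite fits the recovery study with 100 replicate Gaussian-mode
cohorts per outcome (176 participants, 4 waves; the allocated 166 enter the
analysis subset), which pins each fixed effect's Monte-Carlo standard error
near 0.03–0.04 units — small enough that a |bias| < 2 SE check is a sharp
consistency test between generator and estimator. The demonstration scripts
use the same cohort size with a fixed seed; all randomness in tests and
scripts is seeded, and the generator is byte-reproducible under a fixed
seed.

## Known limitations

* The engagement models are linear-Gaussian, as in the analysis they
  reproduce; count outcomes would more naturally be Poisson or negative
  binomial, and the realistic mode's truncation is exactly the regime where
  the linear fit is misspecified.
* AIC selection among a small candidate set can retain spurious
  interactions in single realizations; recovery claims are made only over
  replicates in gaussian mode.
* The dropout count regression cannot distinguish hazard from risk-set
  shrinkage (see above).
* Leaderboard accounting ignores likes/comments/chat and any social
  spillover; scoring treats manual and tracked activities identically, so
  fraudulent registrations are out of scope.
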
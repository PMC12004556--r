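---
title: "Trial sequential analysis and the between-study variance estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial sequential analysis and the between-study variance estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A cumulative meta-analysis is re-run every time a new randomized trial
is published. Testing the pooled z-score against ±1.96 after every
update is repeated significance testing: under a true null the chance
of at least one "significant" result grows with every look, far past
the nominal α. Trial sequential analysis (TSA) ports group-sequential
trial monitoring to this setting: an α-spending function allocates the
overall type-I error across looks, monitoring boundaries convert the
allocation into per-look critical values, and evidence is declared
conclusive only when the cumulative z-curve crosses a boundary.

Every ingredient of a random-effects TSA passes through the estimated
between-study variance τ². With within-study variances ν_i, the
random-effects weights are W_i = 1/(ν_i + τ̂²), the pooled variance is
ν̂_R = 1/ΣW_i, diversity is D² = (ν̂_R − ν_F)/ν̂_R (ν_F the
common-effect pooled variance), the adjustment factor is
AF = 1/(1 − D²), and the required information size (RIS) is the
fixed-sample participant requirement multiplied by AF. Different τ²
estimators therefore produce different boundaries and, sometimes,
different verdicts from identical data. This package implements the
whole chain and a sensitivity sweep across six estimators in routine
use: DerSimonian–Laird (DL), restricted maximum likelihood (REML),
maximum likelihood (ML), Paule–Mandel (PM), Sidik–Jonkman (SJ) and
Hunter–Schmidt (HS).

## Model and assumptions

Per-trial 2×2 tables are converted to log odds ratios
y_i = ln(ad/(bc)) with ν_i = 1/a + 1/b + 1/c + 1/d. The random-effects
model treats y_i ~ N(θ_i, ν_i) with θ_i ~ N(θ, τ²) — normality on the
log-OR scale, independent trials, within-study variances treated as
known. The cumulative z-curve re-estimates τ² on each prefix of the
accumulation order (the cumulative meta-analysis convention);
single-trial prefixes carry no heterogeneity information and use
τ̂² = 0. A fixed-τ² mode is available for sensitivity work.

Sparse tables use a continuity correction: 0.5 added to all four cells
of any trial with a zero cell (the dominant convention for
inverse-variance odds ratios; configurable, `correction = "none"`
drops uncorrectable trials). Trials with zero events in both arms — or
events in every participant of both arms — carry no information about
the odds ratio and are flagged out rather than corrected.

## Tunable parameters

* `alpha = 0.05`, `beta = 0.20` — the conventional two-sided design
  errors (80% power).
* `rrr = 0.20` — the anticipated relative risk reduction; converted to
  a log-OR magnitude at the control event rate. The control rate
  defaults to the pooled observed control-arm proportion; a fixed
  design value can be supplied.
* `ris_mode` — the RIS scale. `"proportion"` (default) is the
  participant scale, 4(z₁₋α/₂ + z₁₋β)² p̄(1−p̄)/(p_C − p_I)² times AF,
  rounded up to whole participants: this is the scale on which RIS
  values in the tens of thousands of participants arise and the scale
  practitioners plan on. `"eq1_literal"` is the statistical-information
  scale 4(z₁₋α/₂ + z₁₋β)² ν̂_R/μ², retained because it makes the role
  of ν̂_R explicit; its units are information, not participants.
* `estimator` — one of DL, REML, ML, PM, SJ, HS.
* Heterogeneity is flagged at p < 0.10 by default (the low power of
  Cochran's Q with few trials is the usual justification); 0.05 is
  available.

## The spending function and boundary numerics

The default spending function is the O'Brien–Fleming-type
α*(t) = 2(1 − Φ(z₁₋α/₂/√t)) on the total two-sided error, the
convention of dedicated TSA software. The classic group-sequential
tables (ld98 and descendants) instead spend α/2 per side, i.e.
α*(t) = 4(1 − Φ(z₁₋α/₄/√t)); `compute_boundaries(spending = ...)`
accepts any spending function, and the test suite reproduces the
published two- and five-look table values under that convention while
validating the default convention by Monte-Carlo crossing
probabilities.

Boundaries are computed by the standard recursion: the sub-density of
non-crossed Brownian paths is propagated across looks by convolution
with the Gaussian increment kernel on a numeric grid (512 trapezoid
points per look by default; agreement with a 4,096-point run is tested
to 5×10⁻⁴), and each boundary solves the incremental crossing
probability by bracketed root finding. Numerical guards: information
fractions are floored at 0.01 and clipped to 1 (all remaining α is
spent at the first look reaching full information; later looks reuse
that boundary); flooring ties are nudged by 10⁻⁶ to keep the schedule
strictly increasing; incremental spends below 10⁻¹² — routine under
O'Brien–Fleming-type spending at small fractions — cap the boundary at
|z| = 8 with a `capped` flag. The "minimum α-spending boundary"
reported per estimator is the most extreme signed boundary on the
effect's side across looks, excluding cap-valued looks (the cap is a
numerical guard, not a boundary value) unless every look is capped.

## The sensitivity sweep

`sweep_estimators()` re-runs the full TSA once per estimator and
summarizes τ̂², D², AF, adjusted RIS, the minimum boundary and the
extreme cumulative z with ranges and the quartile coefficient of
variation, QCV = (Q3 − Q1)/(Q3 + Q1), in percent. Quartiles use linear
interpolation between order statistics by default (the common
scientific-computing rule; Tukey's inclusive-median hinges are
available, because printed QCV values can depend on the convention).
Signed quantities are summarized on magnitudes — QCV needs a positive
scale — with signs carried in the per-estimator rows. When Q1 = Q3
(including the all-zero case produced when several estimators return
τ̂² = 0) the QCV is 0; a zero Q1 with positive Q3 gives 100%, which is
how near-zero-heterogeneity outcomes show maximal relative
disagreement.

## What the synthetic data emulate — and what they do not

`simulation_spec()` draws k trials with true log odds ratios from
N(θ, τ²), control rates fixed or uniform on a range, per-arm sizes
uniform on a range, and binomial event counts: exactly the model the
estimators and the TSA assume. The four `preset_specs()` mirror the
size/heterogeneity layout typical of a Cochrane review's outcomes —
small homogeneous (k = 7, τ² = 0), small heterogeneous (k = 9,
τ² = 0.15), large homogeneous (k = 48, τ² = 0) and large heterogeneous
(k = 62, τ² = 0.10) — with event rates and arm sizes in the ranges
common for airway-management trials (control rates 3–25%, arms of
30–400). The θ values (−0.4 to −0.7) are moderate protective effects;
τ² = 0.10–0.15 gives the marked-but-plausible heterogeneity seen in
such reviews.

Because the generator satisfies the model exactly, passing tests show
the machinery is correct under its own assumptions. They do not show
robustness to what real review data add: publication bias and
small-study effects, time trends in the accumulation order, correlated
subgroups, non-normal random effects, or rare-event outcomes where the
normal approximation to the log OR is poor. The error-rate simulations
evaluate z-curves at the generator's true τ² (oracle variance), which
is what makes "crossing ≈ α" a well-posed calibration target; with τ²
re-estimated at every look — the practical procedure and this
package's default for data analysis — the null crossing rate falls
below α (measured ≈ 0.03 at the simulation's scale) because estimation
noise inflates the pooled variance. That conservatism is a property of
random-effects TSA itself, not of this implementation.

## Numerical choices

* PM solves the generalized Q equation by bracketed root finding; the
  bracket doubles from Var(y) until the statistic falls below k − 1.
* ML/REML use the standard fixed-point iteration (tolerance 10⁻¹⁰ on
  τ², 100 iterations) with a bisection fallback on the score; failure
  to converge is reported via `converged = FALSE`, never silently.
* SJ uses divisor k for its initial estimate, the original proposal's
  form (k − 1 available).
* All estimates truncate at 0.
* Accumulation ties are broken by study id, then input order, so the
  z-curve is reproducible.
* RIS values are ceiled to whole participants on the proportion scale
  and left unrounded on the information scale.

## Problem sizes in the shipped analyses

The `analysis/` drivers use: the four presets above (k = 7–62); 2×10⁵
Monte-Carlo Brownian paths for boundary calibration; and 1,000
replicate meta-analyses per error-rate scenario (10 trials of 322 per
arm spanning the design RIS of 6,429 participants at p_C = 0.1,
RRR = 20%). The test suite re-runs the same experiments at 200–2,000
replicates. These sizes put Monte-Carlo standard errors well inside
the tolerances being asserted while keeping a full run in the order of
a minute.

## Known limitations

Scope is the inverse-variance odds-ratio pipeline: no Mantel–Haenszel
or Peto pooling, no risk ratios or continuous outcomes, no futility
(β-spending) boundaries, no Pocock or power-family spending, and no
confidence intervals for τ². The Brownian approximation ignores the
discreteness of binomial data; at the simulated scales the pooled Wald
z is itself mildly conservative (its null standard deviation is
slightly below 1), which shows up as crossing rates a shade under α
even with oracle variance.
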
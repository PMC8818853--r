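---
title: "Methods: scoring and modelling trial-level ambivalence in the MCQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and modelling trial-level ambivalence in the MCQ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcqamb)
```

`mcqamb` analyses trial-level ambivalence in the abbreviated 18-item Monetary
Choice Questionnaire. This vignette documents the models, the conventions the
implementation fixes where the field's practice is ambiguous, the synthetic
cohort generator used for validation, and the limits of what the validation
shows.

## The instrument and discount-rate scoring

Each MCQ item pairs a smaller-sooner amount (SS, delivered today) with a
larger-later amount (LL, after `D` days). Under the hyperbolic model
`V = A/(1 + kD)`, the two are equally valuable at the per-day rate
`k = (LL/SS − 1)/D`; items are rank-ordered 1–9 within each magnitude
condition (small, LL \$25–\$35; large, LL \$75–\$85) by this rate.
`mcq_item_bank()` stores the rates at full precision; the published table
prints them at two significant figures, and the test suite checks the
round-trip at that precision.

A participant's discount rate is estimated by *consistency scoring*
(`estimate_k()`): candidate rates are the two endpoint item rates plus the
geometric means of adjacent item rates (10 candidates), each candidate is
scored by the fraction of the nine observed choices that match the choice it
implies as a threshold, and the most consistent candidate wins; equally
consistent candidates are combined by their geometric mean.

Conventions fixed here, and why:

* **Prediction at exact indifference.** `predicted_choice()` resolves
  `k == k_item` toward LL — any fixed convention works; this one is applied
  consistently and documented.
* **Consistency at a candidate equal to an item's rate** counts either
  observed choice as consistent: the participant is indifferent there by
  construction. This is the standard scoring convention; it also makes the
  boundary assignments below fall out of the argmax rather than needing a
  special case, and it guarantees that every pattern of the form
  SS…SS LL…LL (including all-SS and all-LL) attains consistency 1.
* **Non-switchers.** A pattern with no SS→LL transition in ascending rank
  order has no estimable switch trial. All-LL responding lands on the lowest
  item rate, all-SS on the highest; these are boundary *assignments*, not
  estimates, and the trial set is flagged.
* **Switch trial.** For a clean single switch, the switch trial is the first
  LL by ascending rank. For multi-switch patterns it is the lowest rank
  whose item rate strictly exceeds the estimated `k` (e.g. an estimate of
  0.0019 falls between the rank-3 and rank-4 small-item rates, so the switch
  trial is rank 4). If the estimate sits exactly on the top item rate — a
  rare multi-switch outcome — the rule is capped at rank 9. The two rules
  coincide on perfectly consistent patterns, which the tests assert.
* **Ties in maximum ambivalence** are resolved by averaging the tied ranks,
  so `max_ambivalence_trial()` may be fractional.

The scoring implementation is checked against an independently written
brute-force oracle over all 512 possible response patterns in both magnitude
conditions.

## Ambivalence rescaling

The four measurement conditions differ in phrasing, polarity and range; all
are mapped to a common scale on which 0 is least and 10 is most ambivalent:
A1 (certainty) and A2 (counterfactual unhappiness) are flipped about the
Likert midpoint (`10 − raw`); A3 (indecision) is kept as-is; the A4
preference slider (0 = strongest SS preference, 100 = strongest LL
preference) is folded about its midpoint, `||raw − 50| − 50|/5`, so 50 maps
to 10 and both extremes map to 0.

## The dual-slopes model (ambivalence around the switch)

Trial numbers are centered within each included trial set so that 0 is the
switch trial; the model is piecewise linear with separate slopes before
(`Pre-Switch = min(c, 0)`) and after (`Post-Switch = max(c, 0)`) the switch
and its intercept on the switch trial. Magnitude and measurement condition
enter as sum-to-zero effects codes (small = +1; A4 is the −1-on-all level,
so A1–A3 coefficients are reported), both as main effects and in interaction
with the slopes — 24 fixed-effect terms. Random intercepts and random
pre/post slopes are grouped by participant and the mixed fit uses REML
(lme4). A fixed-effects-only closed-form least-squares engine
(`engine = "ols"`) serves as an oracle.

Before fitting, two preparation rules apply:

* **Non-switching trial sets are excluded** (at the trial-set level — a
  participant can contribute one magnitude condition but not the other).
* **Sparse cells are removed**: within each magnitude–ambivalence pairing,
  switch-centered positions contributed by *fewer than* 20% (strict) of the
  pairing's participants are dropped. The participant base is the number of
  participants contributing at least one centered observation in that
  pairing — the main alternative (all enrolled participants) differs only
  through trial sets excluded entirely, and the threshold is exposed as an
  argument. The filter is idempotent, which the tests assert.

The slope-asymmetry question — does ambivalence fall away from the switch
faster than it rises toward it? — is a linear contrast
`−Post-Switch − Pre-Switch` with a delta-method standard error from the
fixed-effect covariance.

Inference for all models uses Wald z statistics and `b ± 1.96·SE` intervals;
no multiplicity correction is applied anywhere. These are deliberate
conventions of the analysis family the package implements.

## The choice models (ambivalence × reward sensitivities)

Trial-level choice of the LL is modelled by logistic regression on the
reward sensitivities: `MagRatio = ln(LL/SS)` amounts and
`DelayRatio = ln((D_LL + 1)/(D_SS + 1))`. The SS is delivered today
(`D_SS = 0`), so a raw delay ratio is undefined; offsetting both delays by
one day gives `ln(D_LL + 1)`, spanning ln 8 ≈ 2.08 to ln 187 ≈ 5.23 over the
bank, consistent with the instrument's published 2–6 range on this scale.
`convention = "raw"` (`ln D_LL`) is available for sensitivity analyses.

Three nested specifications are compared: **Base** (the two sensitivities),
**BaseAmbMag** (sensitivities crossed with the effects-coded
magnitude-ambivalence pairing factors; 16 terms) and **AmbMag**
(additionally crossed with the 0–10 ambivalence score; 32 terms). Every
fixed term contains a sensitivity: terms without one — including the
intercept — are removed, following the term-dropping rule of this model
family read literally (an `intercept = TRUE` flag restores it). Both
sensitivities enter as per-participant random slopes; a random intercept is
off by default (`random_intercept = TRUE` enables it) since the term-dropping
rule gives no guidance and the fixed intercept is itself excluded. Models are
compared by AIC with a model preferred only when it undercuts every rival by
at least 4; anything less is reported as "no preference".

The key hypothesis term is `DelayRatio:AmbScore`: delay sensitivity is
negative (longer relative delays push choices toward the SS), so a
*positive* interaction means ambivalence pulls the delay effect toward zero.

Engines: the default is `lme4::glmer` (`nAGQ = 0` for speed; the setting is
exposed). `engine = "newton"` is a directly implemented Newton–Raphson
(IRLS) fixed-effects fit used as the oracle and in replicate sweeps; it is
checked coefficient-for-coefficient against `stats::glm`, and against the
mixed machinery profiled at zero random-slope variance, where the two agree
to ~1e−9. A caveat worth stating: on cohorts generated *with* zero
between-participant sensitivity variance, the freely estimated logistic
mixed model does not drive its variance estimate all the way to zero at
desk-scale samples — the magnitude-ratio design is narrow (0.025–0.85 in
ln units) and the variance is weakly identified — so free mixed fits and
fixed-effects fits agree in sign and approximate magnitude rather than to
numerical precision. The linear (REML) case does collapse to the OLS fit, to
better than 1e−3, and the tests assert exactly that distinction.

## Data-quality statistics

`mcq_quality()` reports the paired t-test of within-participant
`ln k_small − ln k_large` (the magnitude effect, used as a group-level
attention check) and the proportion of participants with perfect consistency
when averaging the two magnitude conditions. Two conventions deserve note:

* **Boundary-censored pairs.** Non-switching trial sets carry an assigned
  endpoint rate, not an estimate; a pair censored at the same boundary in
  both conditions contributes a difference of exactly 0 and attenuates the
  mean paired difference. The default therefore excludes pairs in which
  either condition failed to switch (`boundary = "include"` keeps them).
* **Cohen's d** is computed as the standard paired `mean(diff)/sd(diff)`.
  Other conventions exist (e.g. standardising by a pooled or single-condition
  SD and giving noticeably smaller values); the formula used here is stated
  so the number is interpretable.
* Identical paired vectors have zero-variance differences and an undefined
  t statistic; this is a degenerate-input error, not `t = 0`.

## The synthetic cohort generator

No raw data ship with the analysis this package implements, so validation is
simulation-based and the generator (`sim_config()`, `generate_cohort()`) is
first-class, tested code. Its defaults are the study conditions the package
is designed for:

| parameter | default | meaning |
|---|---|---|
| `n_participants` | 370 | cohort size |
| `mu_ln_k_large`, `sigma_ln_k` | ln 0.006, 1.2 | log-normal discount rates, large condition |
| `magnitude_shift_mean`, `_sd` | 0.66, 0.48 | per-person `ln k_small − ln k_large` |
| `choice_noise` (τ) | 2.3 | inverse temperature of `P(LL) = logistic(τ(ln k_item − ln k_p))` |
| `p_extreme` | 0.15 | extreme responders placed 1.5 log units outside the item range |
| `p_flat_ambivalence` | 0.20 | participants with constant (peakless) ambivalence |
| `amb_peak_height_range` | (4, 9) | per-person peak height, 0–10 scale |
| `amb_width` | 1.8 | Gaussian peak SD in ln-k units (item ranks are ~0.9 apart) |
| `amb_noise_sd` | 1.0 | trial-level noise before truncation to [0, 10] |

τ and `p_extreme` were calibrated so that scored cohorts reproduce the
response-quality profile reported for this instrument in online samples —
roughly 79% of participants perfectly consistent and ~15% of trial sets
without a preference switch; the truncated-normal discount-rate distribution
alone places almost no one outside the item-rate range, which is why the
extreme-responder mixture exists at all. Raw responses are encoded as the
exact inverse of the rescaling (Likert conditions round half away from zero;
the A4 slider stays continuous, with the side of the midpoint set by the
simulated choice), so scoring a generated cohort round-trips ambivalence to
within Likert rounding.

Two choice mechanisms are available. `rank_based` (default) draws each
choice from the participant's log-rate distance to the item — ambivalence
then *tracks* the switch point (a Gaussian peak in ln-k distance, a testing
device rather than a claim about any real data-generating process) but does
not influence choices. `sensitivity_based` draws choices from the logistic
sensitivity model; latent ambivalence is computed from the *base* linear
predictor and the choice is then redrawn with the delay coefficient
multiplied by `1 − γ·A/10` — a two-stage construction that implements
"ambivalence attenuates delay sensitivity" without defining ambivalence
circularly from the final choice. With γ = 0 the second stage collapses to
the first, giving exact null cohorts for type-I checks. The generator also
supports a per-participant small-magnitude delay modulation and random
sensitivity SDs so that the pairing terms and random-effect structure of the
fitted models have generative counterparts.

Counterbalancing assigns each participant one ambivalence condition per
magnitude by round-robin over the eight pairing slots of the two study arms
(A1/A2 and A3/A4).

What the generator does **not** emulate: response times, mouse trajectories,
item-order effects within blocks, inattentive or adversarial responding
beyond the extreme-responder mixture, and any dependence of ambivalence on
reward amounts per se. Passing recovery tests therefore show that the
estimators recover the generative structure they target — not that real
respondents follow that structure.

## Parameter-recovery design and problem sizes

The acceptance suite validates the estimators at sizes chosen to finish in
minutes on one CPU:

* **Dual-slopes recovery**: 100 cohorts of n = 200, piecewise-linear
  ambivalence (`amb_shape = "linear"`) with generating slopes +0.4/−0.5,
  peak heights U(5, 7) and noise SD 0.8 (so truncation at the scale bounds
  is negligible), and near-deterministic choices (τ = 1e4). The
  deterministic-choice design is deliberate: with stochastic choices the
  *scored* switch trial occasionally misses the rank at which the
  ambivalence peak was generated, which attenuates the post-switch slope —
  a property of switch-trial identification, not of the dual-slopes
  estimator the criterion is about. The suite checks sign recovery in every
  replicate and ≥90% joint coverage of the generating slopes by the Wald
  intervals.
* **Attenuation recovery and type-I control**: 100 cohorts of n = 200 each
  for γ = 0.6 and γ = 0 (`sensitivity_based`, zero random-sensitivity
  variance so the directly implemented Newton fit is exactly specified);
  ≥90% positive-sign recovery of `DelayRatio:AmbScore` under coupling, and
  ≤10% rejections at α = 0.05 under the null.
* **Model selection**: 11 coupled and 11 null cohorts of n = 150; the AIC
  chain AmbMag ≺ BaseAmbMag ≺ Base (each margin ≥ 4) must hold in the
  majority of coupled replicates, and null cohorts must yield Base or no
  preference.
* **Magnitude effect**: one default cohort of n = 370; the scored paired
  mean difference must fall within a Monte-Carlo band (±0.12) of the
  configured 0.66. The scored estimate is quantised to the candidate grid
  (~0.9 log units between ranks), which adds variance but little bias when
  the rate distribution is smooth relative to the grid.

## Known limitations

* Scored `k` lives on a 10-point grid; analyses of continuous individual
  differences inherit that quantisation.
* Boundary assignment for non-switchers is a convention; downstream users
  should treat those rates as censored (as `mcq_quality()` does by default).
* The dual-slopes model is a piecewise-linear summary of a peak that real
  data need not follow; nonlinear peak models are out of scope here.
* The logistic mixed fits use fast approximations (`nAGQ = 0` by default);
  for publication-grade variance components, refit with `nAGQ = 1` and
  verify convergence flags (`glance()` reports them).
* Only the 18 small/large items are supported; the full 27-item MCQ's medium
  condition is out of scope.
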
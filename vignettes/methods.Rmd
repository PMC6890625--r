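---
title: "Methods: projecting dementia and disability burden under diabetes scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting dementia and disability burden under diabetes scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demburden)
```

This vignette is the package's own account of its model: the assumptions
it makes, the parameters that matter, the places where the design was
genuinely open and what we chose there, and what the passing test suite
does and does not demonstrate about real populations.

## The cohort model

The population aged 35 and over is partitioned into ten states: the cross
of cardiovascular disease status (no CVD / CVD) with four severity levels
(unimpaired, cognitive impairment, moderate-to-severe disability,
dementia), plus two absorbing death states (CVD and non-CVD causes).
Dementia sits above disability in the severity ordering because it is
defined as cognitive impairment coexisting with disability; it admits no
recovery. Within a severity level, CVD can be acquired but not lost.
Severity moves along unimpaired → {cognitive impairment, disability},
cognitive impairment → {dementia, disability}, disability → {dementia,
unimpaired}; the last edge is recovery from disability, the only
improving transition. Every alive state can reach both death states.

Each annual cycle applies, in this order: (1) the one-year transition
matrix of every (age, sex) cohort; (2) ageing by one year, the 100+ group
open-ended; (3) injection of the new disease-free cohort of 35-year-olds.
The engine propagates *expected* counts — fractional persons — rather
than simulating individuals: the scientific questions here concern
population-level expectations and their parameter uncertainty, which a
deterministic cohort sweep answers at a tiny fraction of the cost of
microsimulation, and exactly. There is no half-cycle correction; the
annual census at year boundaries is the model's native resolution, since
all inputs are one-year probabilities. Conservation (alive + cumulative
deaths = initial + cumulative entrants) holds to machine precision and is
enforced by test.

Ages 35–64 are simulated — they feed the future older population — but
headline outputs are reported for the population aged 65+, where the
dementia and disability burden concentrates.

## Mortality projection

Cause-specific mortality (CVD and non-CVD, by 5-year age band and sex,
1990–2016) is smoothed on the log scale with a penalized B-spline: a
cubic basis on equally spaced knots (10 basis functions by default) with
an order-2 difference penalty on adjacent coefficients. The order-2
penalty's null space is the straight line, which carries two useful
consequences: data that are exactly log-linear are reproduced exactly at
*any* penalty weight, and the natural extrapolation of the smooth is
linear continuation of the boundary log-slope — mortality declines
continue at their fitted end-of-sample pace, never cross zero, and
multiply rather than add (log scale). The penalty weight is chosen per
stratum by generalised cross-validation over a log-spaced grid, with a
fixed fallback weight of 10 if the criterion degenerates. The penalized
system is solved in its augmented least-squares form by QR factorisation,
which stays accurate at extreme penalty weights where the normal
equations lose half the working digits.

The projection must then drive the model's death cells, and the coupling
between stratum-level rates and state-specific transition probabilities
is not dictated by anything observable: we fix, per (state, age, sex,
cause), a calibration constant `c` such that `1 - exp(-rate * c)`
reproduces the start-year death probability of the input transition set,
and push each projected year's rate through the same map. This preserves
the relative ordering of state-specific death risks (people with CVD stay
likelier to die of CVD) while the trend tracks the projection; it is the
simplest coupling that is exactly testable.

## Diabetes scenarios and duration structure

Four total-prevalence trajectories are shipped with the package as decade
anchors and interpolated piecewise-linearly (exact at every anchor):
baseline 8.6% → 10.8% by 2060 (+26%), A → 12.8% (+49%), B → 10.3%
(+20%), C → 9.2% (+7%). Relative risks depend on time lived with
diabetes, so prevalence is carried per duration category (<5, 5–9,
10–14, 15–19, 20–24, ≥25 years) by 10-year age band and sex, with the
category RR escalating geometrically: `RR_base * m^k` for category `k`,
`m = 1.13` per five years of duration by default.

How the duration split evolves through time was a genuinely open design
point, and the obvious mechanism is wrong. Advancing the *whole* diabetic
stock through the categories (1/5 per year, terminal accumulating) while
the baseline keeps its reference shares makes every scenario — even one
with uniformly *lower* prevalence — accumulate long-duration, high-RR
mass that the baseline arm never receives; the comparison then reports
extra deaths for scenarios that prevent diabetes, an artifact of the
asymmetric mechanism rather than an epidemiological finding. The package
instead ages only the *excess*: the prevalent stock keeps its reference
category shares, scaled along the baseline trajectory (for the baseline
scenario this is exactly the constant-shares assumption), while the
difference between the scenario's and the baseline's trajectory enters
the "<5 years" category as new incidence — negative incidence for
prevented cases — and advances through the bands at 1/5 per year. Stratum
totals match the scenario trajectory exactly; a scenario pointwise above
the baseline has pointwise more mass in every category, so all the
comparative monotonicity properties hold by construction. When prevented
cases would exceed a category's prevalent stock the category is clipped
at zero with a warning. The mechanism deliberately ignores the higher
death rate of long-duration diabetes, which overstates long-duration
prevalence somewhat — a known limitation of this class of projection.

## The PARF mechanism

For each affected transition family — CVD incidence, cognitive-decline
incidence, disability incidence, recovery from disability, CVD death,
non-CVD death — the multi-category attributable fraction is Levin's
extended formula, `PARF = S / (1 + S)` with
`S = sum(p_i * (RR_i - 1))`. It is algebraically identical to
(total risk − unexposed risk) / total risk for any unexposed baseline
risk, which the tests exploit as a brute-force oracle, and it is valid
unchanged for the protective recovery family (RR < 1, negative PARF).

Rescaling a transition probability for a change in exposure distribution
uses the exact identity `risk_total = risk_unexposed / (1 - PARF)`:

```
tp_scenario = tp_baseline * (1 - PARF_baseline) / (1 - PARF_scenario)
```

A looser reading of "multiply ΔPARF by the transition probability" —
`tp * ΔPARF` — would near-zero every affected risk and cannot be meant;
the ratio form is exact, reduces to `tp * (1 + ΔPARF)` to first order
(the residual is `tp * PARF * ΔPARF / (1 - PARF)`, second-order small,
and bounded in a test), and leaves probabilities bit-identical when the
scenario equals the baseline. PARFs are computed per 10-year age band —
the granularity of the duration-prevalence inputs — and applied to all
single-year ages within the band; the stay-probability absorbs the
residual so every row remains stochastic, and a row pushed past
probability 1 is a hard error, never silently repaired.

The cognitive-decline family covers entries into cognitive impairment
*and* progressions into dementia (from cognitive impairment and from
disability, in both CVD layers). The affected-transition list has no
separate dementia family, and without mapping the dementia-entry edges
the dementia burden would respond to diabetes only through the lagged
cognitive-impairment pathway; treating progression as part of cognitive
decline is the reading consistent with duration-dependent acceleration of
cognitive deterioration.

## Synthetic inputs

No transition probabilities, population tables or duration distributions
are published at the granularity the model needs, so the package
generates them. The generator's defaults describe a stylised
England-and-Wales-like population and are fixed once, not tuned to any
published projection: one million persons aged 35+ with a smoothly
decaying age pyramid and an increasingly female old age; 14,000 entrants
per year; age-specific prevalences of CVD, cognitive impairment,
disability and dementia rising logistic-in-age; morbidity transition
probabilities logistic in age with log-normal cell-level jitter
(SD 0.05); Gompertz-like mortality declining log-linearly from 1990
(−3.5%/year CVD, −1.2%/year non-CVD, log-noise SD 0.03); a national
diabetes prevalence of 8.6% at the 2015 reference, rising with age and
split over duration categories with older bands skewed to longer
durations; relative risks at meta-analytic magnitudes (CVD incidence 2.0,
CVD death 1.8, disability incidence 1.65, non-CVD death 1.5, cognitive
decline 1.45, recovery 0.85) with log-scale standard errors, and the
per-5-year duration multiplier 1.13. Death cells are generated without
jitter so that the combined death probability is monotone in age by
construction.

The generator reproduces the *structural* properties real inputs would
have — row-stochastic transitions, absorbing deaths, declining mortality,
an ageing population, duration mass balance — and that is all the passing
tests certify. They do not certify the magnitudes of any published
national projection: the synthetic population is ~3% of the size of
England and Wales's 35+ population and its transition intensities are
plausible rather than estimated, so headline counts here are
scale-and-fixture-specific even though every qualitative conclusion
(direction of scenario effects, compression of morbidity) is exercised.

## Uncertainty analysis

The probabilistic sensitivity analysis perturbs, per draw: every
permitted transition probability (beta, moment-matched to the point value
with effective sample size 2000 by default — sampling SD
`sqrt(p(1-p)/(ess+1))`); every duration-category prevalence (beta,
likewise); and every base RR (log-normal around the point estimate with
its log-SE). Rows are renormalised through the stay-probability after
perturbation. Scenario and baseline are re-run on the *same* perturbed
inputs (common random numbers), so interval width on differences reflects
parameter uncertainty rather than between-arm noise, and each draw is
seeded from (seed, draw index) alone, making any single draw reproducible
in isolation. Intervals are empirical 2.5th/97.5th percentiles — the
percentile reading of a "95% uncertainty interval" — and the reported
point estimate is the run at the unperturbed inputs. The reference
analysis uses 1000 iterations; the package's test suite and acceptance
script run 200, which stabilises the interval ends to well within the
widths involved while keeping a full-suite run around three minutes.

## Numerical choices, in one place

* Transition rows sum to 1 within 1e-12 at generation; death rows are
  exactly absorbing; structurally forbidden cells are exactly 0.
* Stay-probabilities absorb all modifications; a negative residual stays
  below -1e-9 only through a genuine input error and is raised, not
  clipped. Occupancy going negative in a step is likewise a hard error.
* Probabilities produced by PARF rescaling are clipped to 1 with a
  warning (unreachable under realistic inputs).
* Duration mass balance holds within 1e-9 per stratum-year; category
  floors at 0 warn.
* The penalized-spline solve uses QR on the augmented system; GCV grid
  `10^seq(-3, 8, 0.5)`; fallback weight 10.
* Rates per 1000 use the start-of-year alive population aged 65+ as the
  denominator (the annual census is the model's native time point; a
  mid-year denominator would interpolate information the model does not
  carry).
* "Life spent with disability" counts the two disability states and the
  two dementia states, dementia being definitionally disabled.
* Cumulative comparisons start at 2015, the year the scenarios diverge,
  although the simulation starts in 2006 so the 2015 state reflects nine
  years of modelled dynamics.

## Limitations

Beyond the synthetic-fixture caveat above: obesity enters only as a
scenario label (its non-diabetes pathways to dementia are not modelled);
the duration mechanism ignores duration-dependent mortality; transition
probabilities are age- and sex-specific but time-invariant apart from the
mortality trend and the PARF rescaling, so secular trends in dementia
incidence are not separately modelled; and the PARF approach assumes the
diabetes–outcome associations are causal at the published effect sizes.
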
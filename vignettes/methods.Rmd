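---
title: "Methods: a Markov cohort cost-utility model of negative-pressure therapy in PAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-utility model of negative-pressure therapy in PAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padcea)
```

## The decision problem and model structure

The package evaluates whether an intermittent negative-pressure home
device for lower limb peripheral artery disease (PAD) is worth paying
for, relative to standard NHS care, when offered as a substitute for
care (S0 with nominal support, S1 alone) or as an add-on (S2). The
vehicle is a discrete-time Markov cohort model: a closed cohort
(default 1000 patients) starts in the symptomatic `Progressive` state
and is propagated through a three-month cycle over a five-year horizon
by row-stochastic transition matrices.

Seven states are reported — mild, progressive, severe, minor amputation,
major amputation, recovered, dead — of which `Dead` is absorbing.
Internally the recovered state is split into `RecoveredNoAmp` and
`RecoveredPostAmp`. The clinical meaning of "recovered" depends on
whether the patient has lost a limb, so utility and cost may differ by
amputation history; splitting the state carries that history in the
state itself and preserves the Markov property. The two sub-states are
summed for reporting (`aggregate_trace()`).

Structural rules enforced by `validate_matrix()`: no exit from `Dead`;
`RecoveredPostAmp` reachable only from an amputation state;
`RecoveredNoAmp` never reachable from one. Relapse out of the recovered
states is off by default — the published model diagram does not
establish a relapse arrow, and adding one is a config-level choice (any
row-stochastic matrix satisfying the structural rules is accepted).

## Time-varying post-amputation mortality

Mortality after major amputation is 35 %/year in the first year and
19 %/year thereafter. A faithful sojourn-time implementation would need
tunnel states; instead the default model replaces the
`MajorAmputation` row after the first four *model* cycles (time in
model, not time in state). This is exact for patients amputated at
model start and optimistic-by-one-year at most for later amputees. The
approximation is deliberate and documented; callers needing exact
tunnel behaviour can supply a full per-cycle matrix sequence via the
`override` argument of `build_transition_sequence()`.

## Economic accrual

Costs and QALYs accrue at start-of-cycle occupancy with no half-cycle
correction, matching the all-at-cycle-start convention of the source
model; the half-cycle refinement would shift both arms almost equally
and leaves incremental results essentially unchanged at a three-month
cycle. Discounting is discrete annual (`1/(1+r)^t`, `t` in years),
default 3.5 %/year on both costs and effects, varied 0–3.5 % on effects
in sensitivity grids.

Key parameters, units and defaults:

| parameter | default | units | note |
|---|---|---|---|
| cycle length | 0.25 | years | one device dose = one cycle |
| horizon | 20 cycles | — | 5 years |
| care cost/cycle | 143.09 / 828.43 / 1767.33 / 2254.98 / 4913.19 | GBP | mild→major amputation; recovered and dead cost 0 |
| device rental | 15 | GBP/day | 91.25 days/cycle → 1368.75/cycle, alive patients only |
| nominal care fraction | 0.5 | — | the source defines nominal care only qualitatively; 0.5 of standard is a configurable placeholder |
| utilities | 0.80 / 0.62 / 0.41 / 0.22 / −0.087 | EQ-5D index | strictly ordered by severity; major amputation worse than dead |
| age multiplier | 1 / 1 / 0.96 / 0.95 | — | age 50–59…≥80; age affects utilities only, never costs |
| discount | 0.035 | /year | both axes |

Device rental is charged for every alive state while the regimen is
active, including the recovered states; whether recovered patients
would return the device is unknowable from the source material, and
charging all alive states is the conservative (cost-raising) choice for
the device arms. Rental stops at death, which is why a one-year
single-dose device cost sits slightly below the full quarter's rental.
The `single_annual` regimen activates the first cycle of each model
year; `continuous` activates every cycle; no standby rental is charged
on inactive cycles.

Incremental analysis uses standard care as the fixed comparator for
every arm (no efficiency frontier across S0/S1/S2 — the arms are
mutually exclusive variants compared pairwise to SC). ICERs are
computed from full-precision totals; rounding to 2 dp (money, QALYs)
and 3 dp (probabilities) happens only in `render_cea_table()` /
`render_ceac_table()`, which is why ICERs recomputed from rounded
published totals differ slightly from full-precision ones.

## Probabilistic sensitivity analysis

`psa_spec()` encodes standard HTA distribution choices, since the
source states only that its PSA was multivariate over parameter
ranges: gamma for costs (mean = base case, CV 0.2), beta for per-cycle
probabilities (mean = base case, effective sample size 100), and a beta
rescaled to [−0.594, 1] for utilities (ESS 100) so that worse-than-dead
values remain reachable. Transition rows are renormalised after
drawing; monotone-ordering constraints on costs and utilities are
enforced by rejection with a bounded retry budget (default 100), which
slightly truncates the tails of neighbouring states with overlapping
distributions (materially the Severe/MinorAmputation cost pair) but
keeps every draw a valid parameter set. Parameters are drawn
independently — no correlation structure is reported to estimate one
from. All PSA randomness derives from the single integer seed in the
spec; identical specs reproduce results bit-for-bit.

CEAC probabilities are the fraction of draws with positive incremental
monetary net benefit; their confidence intervals use a percentile
bootstrap over draws (the source names IMNB-based intervals without
describing a construction, so the bootstrap contract is this package's
own and is stated as such).

## The synthetic parameter generator

The complete transition-probability and care-package tables behind the
source model are unpublished, so `generate_calibrated_parameters()`
builds them synthetically under hard epidemiological anchors, all
converted to the per-cycle scale via `annual_to_cycle_prob()`
(constant-hazard conversion, `1-(1-p)^(1/4)`):

- `Severe → Dead`: 25 %/year;
- `Severe →` any amputation: an annual incidence inside [25 %, 40 %];
- `MajorAmputation → Dead`: 35 %/year for four cycles, then 19 %/year;
- care costs fixed at the published per-cycle point estimates;
- utilities strictly monotone in severity, major amputation allowed
  negative.

The five-year 50 % CLI mortality figure is reported by
`measure_anchors()` but not enforced: it is not jointly consistent with
a constant 25 %/year hazard (which alone gives 76 % by year five;
competing amputation exits bring the simulated value near 0.5–0.6), and
the source does not resolve the tension. The device arm equals the
standard-care model with every progression edge scaled by a single
relative risk, mass returned to the diagonal; its default 0.527 was
solved once (root-finding on the default model) so the five-year
discounted QALY gain is ≈ 0.27, and is not otherwise tuned. Free
parameters (progression, recovery, background mortality, the amputation
split and the utility vector) are jittered over plausible ranges under
a seed, so seeds index a family of distinct but always-calibrated
models.

What the generator does *not* emulate: correlations between parameters,
adherence/compliance attrition, state-specific device effects, cost
inflation, or any patient-level covariate structure. Tests passing on
generated models therefore demonstrate the correctness and calibration
machinery of the pipeline, not the clinical conclusions of any real
dataset.

`generate_trial_like_eq5d()` draws per-patient baseline/follow-up
EQ-5D indices from truncated normals matching published stage-level
means and SDs on [−0.594, 1]; it exists to exercise mean-by-stage
utility estimation, not to reconstruct trial data.

## Numerical choices and validation

- Probability conversions: `annual_to_cycle_prob()` then
  `cycle_to_annual_prob()` is the identity to machine precision across
  [0, 1]; the reverse composition underflows for per-cycle
  probabilities near 1 at many cycles per year (`(1-p)^k` below double
  precision), which is inherent to the representation and tested only
  on the representable range.
- Matrix validation tolerance: row sums within 1e-9; cohort
  conservation within 1e-6 of the cohort size.
- Ties in incremental classification (one delta exactly zero) are
  labelled `ICER` with a signed infinite or zero ratio and flagged.
- The cohort engine is validated against the per-patient
  microsimulation oracle on 20 random generated models at 10,000
  patients over 8 cycles. Each state-by-cycle microsimulation count is
  marginally binomial around the cohort expectation, so across ~1400
  correlated comparisons a hard 3-standard-error bound per entry would
  fail by chance in roughly every run (≈ 4 expected chance
  exceedances). The agreement test is therefore calibrated: the rate
  of >3 SE exceedances must stay below 1 % (null expectation 0.3 %),
  and no entry may deviate by more than 4.5 SE plus one count of
  continuity allowance for small expected counts.
- Problem sizes in the shipped tests (10,000-patient microsimulations,
  PSA runs of 12–200 draws at 4–20 cycles, 1000-draw closed-form
  checks) were chosen to keep the whole suite fast while leaving every
  statistical check adequately powered; the pipeline itself runs
  1000-draw PSAs over the full horizon in seconds.

## Known limitations

Time-in-model approximation of the post-amputation mortality tunnel;
independence of PSA draws; a single scalar treatment effect (relative
progression risk) shared by all device scenarios, implying identical
QALYs across S0/S1/S2 with differences confined to cost; no adherence,
no societal perspective, no budget impact, and no value-of-information
analysis. The synthetic parameter family stands in for unpublished
tables and is labelled as such in every serialised output's provenance
field.
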
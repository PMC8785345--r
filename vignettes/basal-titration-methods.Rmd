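---
title: "Model-based titration of long-acting insulin: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based titration of long-acting insulin: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basalopt)
```

## The problem

People with type 1 diabetes on multiple daily injections (MDI) take a
long-acting (basal) insulin dose once daily to cover fasting and overnight
needs, and rapid-acting boluses at meals. The basal dose must be titrated
periodically; the standard of care adjusts it by a few units from fasting
fingerstick (SMBG) readings. `basalopt` implements a model-based
alternative that uses the full continuous glucose monitoring (CGM) trace
and a smart-pen dose log, requires **no carbohydrate records**, and biases
the adjustment against nocturnal hypoglycemia. Two SMBG-based comparator
rules and a synthetic in-silico trial harness are included so the three
strategies can be compared under controlled conditions.

## The glucoregulatory model

The core is a linearized subcutaneous oral glucose minimal model with nine
states: glucose deviation `x1`, insulin action `x2`, a two-compartment
long-acting depot (`x3` precipitate, `x4` soluble), a three-compartment
rapid-insulin path (`x5`, `x6` subcutaneous, `x7` plasma), and a
two-compartment carbohydrate path (`x8` stomach, `x9` gut). The glucose
balance is

\[
\dot x_1 = -S_g x_1 - S_i G_b x_2
           + \frac{f(k_{q1} x_8 + k_{q2} x_9)}{V_g\,BW} + \omega(t),
\]

where `Sg` (glucose effectiveness) pulls the deviation back, `Si` scales
the insulin action, the absorption terms feed carbohydrates in through a
parallel stomach/gut path, and the *residual metabolic signal* `omega`
collects everything the model does not represent. Doses and meals enter as
impulses; the measured output is `x1` plus an affine intercept.

Discretization is exact (matrix exponential; the residual channel is
integrated under a zero-order hold). The once-daily dosing steady state
has the closed form
`X0 = expm(Ac e) (I - expm(Ac T))^{-1} Bc_basal * dose`, with `e` the
elapsed time since the last injection; a test verifies it against
brute-force simulation of one hundred consecutive doses at relative error
below 1e-6.

Population parameter values live in a versioned YAML file
(`inst/extdata/population_parameters.yaml`) with per-section provenance
notes; all structural tests are written to be parameter-value-agnostic.
Two conventions worth knowing:

* **Units.** Insulin is carried in U and carbohydrate states in mg; with
  `Vi` in mL/kg this fixes `Si`'s units to mL/U/min. The printed matrix
  form is preserved; the gram-to-mg conversion sits in the meal input
  vector.
* **Affine intercept.** `x1` is a deviation state. The intercept is
  anchored at the therapy record's implied basal requirement (TDI/2): at
  that dose, with population sensitivity, the daily-mean fasting output
  equals the therapy basal glucose. Anchoring at the *current* dose would
  assert that a possibly mis-titrated dose already achieves target
  fasting glucose, which collapses the identifiability of `Si` whenever
  the patient is under-dosed.

## Individualization without carbohydrate records

Each day (padded by a 6-hour head and a 2-hour tail) is fitted by maximum
a posteriori estimation of one insulin sensitivity `Si` per day plus one
absorption quadruple `(f, kq1, kq2, kq12)` per meal, with the residual
signal fixed at zero during this step. Meal inputs are reconstructed from
the bolus record by inverting the 500/1800 dosing rules
(`U_meal = max((500/TDI)(U_bolus - (G - Gb)/(1800/TDI)), 0)`), then
augmented by a rise detector for unbolused intakes (slope above
1.0 mg/dL/min sustained 25 minutes, outside refractory windows of 120
minutes after a bolus and 240 minutes after any known meal — the longer
meal window prevents the genuine "second rise" of a waning bolus from
being re-detected as food). Detector thresholds are configuration keys;
at the default sensor-noise model the false-positive rate on meal-free
days is about 0.23/day, and meals of 35 g and above are caught.

The likelihood is iid normal with a constant 7 percent coefficient of
variation; priors are log-normal, centred at population values with 30
percent CV for `Si` and 50 percent for meal parameters. Optimization runs
in log-parameter space (bounded quasi-Newton, three deterministic restarts
from the prior mean and one prior standard deviation either side). A
computational note: because the insulin chain does not depend on `Si` and
the glucose balance is linear, the insulin-driven response is simulated
once per window at unit sensitivity and scaled by `Si` inside the
objective, and each meal chain has a closed three-exponential form; the
compiled objective is mathematically identical to the public
matrix-exponential simulator (verified by test to 1e-6).

The residual signal is then deconvolved on a 30-minute grid by ridge
regression with a second-difference penalty. The weight `lambda = 250`
was fixed once from an L-curve sweep on simulated windows (the recovered
signal's correlation with an injected sinusoid is insensitive to `lambda`
over 5-4000; 250 sits at the residual-norm elbow). Deconvolution can only
improve the fit (a property guaranteed by the ridge objective and checked
by test).

## Dose optimization and the update rule

The individualized model predicts the *carbohydrate-free fasting profile*:
the day re-simulated with boluses and meals removed, the dose under test
injected at the patient's usual time from its periodic steady state, and
the estimated residual signal retained. A grid of candidate doses
(plus/minus 40 percent of the current dose in 1 percent steps) is scored
by

\[
\sum_k \mathrm{risk}(Y_k) \;+\;
\alpha \sum_{k \in \text{night}} \max(1 - Y_k / G_t, 0),
\]

with the classic blood-glucose risk index
`risk(g) = 10 (1.509((ln g)^{1.084} - 5.381))^2` (minimum near
112.5 mg/dL), a night target `Gt = 110` mg/dL, and `alpha = 100`, which
makes a single night sample 10 percent below target comparable to a large
daytime risk term. The night window is personalized as the longest
bolus-free clock interval (with margins), falling back to 00:00-06:00.
Ties in the grid search resolve toward the smaller dose
(hypoglycemia-averse). Per-day optima are averaged over the cycle and
rounded to the half-unit pen resolution.

The recommended change passes through the dead-zone/saturation update
`B_next = B_c + Phi(B_opt - B_c)`: changes below `x_min = 0.5` U are
ignored, changes above `x_max` are capped. The cap defaults to
`max(1, 0.05 B_c)` — about one unit per 3-day cycle, the step size of
standard treat-to-target titration schedules, and the rate at which a 50
percent dose error is corrected over roughly ten cycles.

## SMBG comparators

*Control-to-range*: if the cycle's minimum fasting SMBG is below
80 mg/dL the dose drops by 10 percent (at least 1 U); if the cycle mean
exceeds 130 mg/dL it rises by 0.5 U per 20 mg/dL of excess (0.5-5 U).
*Control-to-reference* (iterative learning control): the cycle-mean
fasting error is filtered by a first-order low-pass (pole 0.5) whose DC
gain magnitude is individualized to `3/BW` U per mg/dL. Because insulin
*lowers* glucose, a convergent learning law must increase the dose when
fasting glucose sits above the reference; the filter therefore carries
the stabilizing sign, `B_opt = B_c + (3/BW) F(q) (G_fasting - G_target)`.
Both comparators share the same dead-zone/saturation update as the
model-based method.

## The synthetic trial

The in-silico harness deliberately reuses the model class for its virtual
subjects (an "inverse crime" that gives clean convergence oracles) while
adding mechanisms the identification model does not represent — rescue
carbohydrates, sensor noise, and in the *variance* scenario dawn-phased
sinusoidal (20 percent) and day-to-day log-normal (15 percent CV) insulin
sensitivity variation, variable meals, counting errors and bolus delays —
so the identification step faces model mismatch. It is a synthetic
stand-in for a full physiological simulator: absolute outcome levels are
not comparable to any particular platform, but paired-arm contrasts and
convergence behaviour are.

Subjects are drawn by log-normal jitter around the population values.
Each subject carries a basal glucose `Gb ~ N(115, 8)` (clipped to
100-135) and a zero-insulin fasting intercept `G0 ~ N(225, 25)`; the
steady-state requirement solves `Ubasal_ss = (G0 - Gb)/slope` from the
model's own dose response, so fasting simulation at `Ubasal_ss` averages
`Gb` exactly, with a peak-less ripple below 2 mg/dL (draws violating this
are redrawn). `G0`'s centre makes the 500/1800 therapy rules consistent
with the model's carbohydrate/insulin balance (the implied TDI of ~42 U
gives a carbohydrate ratio matching the balance value of ~12 g/U). The
long-acting absorption rates (`ksp = 2.5e-4`, `ka = 4e-4` 1/min, 98
percent precipitating) produce the day-scale, peak-less profile the
formulation is designed for. Basal timing alternates 07:00/22:00 by
subject id.

Behaviour follows the nominal (50/75/75 g at 07:00/13:00/19:00, no
variability beyond sensor noise) or variance scenario. CGM error is
additive AR(1) (sd 15 mg/dL, lag-1 coefficient 0.7 — about 9 percent
MARD); SMBG error is proportional with 5 percent CV, drawn at waking
(06:00), *before* the first possible rescue treatment: treatments are
allowed from 06:00 and occur within minutes of an ongoing hypoglycemia,
so a later draw would read the 15 g rescue spike instead of the fasting
level the titration rules assume. Hypoglycemia below 70 mg/dL is treated
with 10 percent probability per minute (untreated-for-30-minutes
probability 0.9^30, about 4 percent), never between 00:00 and 06:00, with
a 30-minute refractory period.

Trials start from the steady state of a dose altered by plus/minus 50
percent (half the cohort each way), with meal boluses altered by minus/
plus 25 percent, and titrate every three days. All behaviour and noise
streams are drawn per subject from the trial seed only, so treatment arms
consume bitwise-identical streams.

## Problem sizes and determinism

The shipped acceptance analyses use 20 subjects and 60 trial days (90 for
the ILC arm) in the nominal scenario — a deliberate scale-down of the
100-subject, 120-day design, chosen so the full paired analysis completes
in minutes on a single core. Identification runs three quasi-Newton
restarts capped at 60 iterations per day-window; raising the cap to 150
changes cycle-level recommendations by well under one pen increment.
Everything downstream of a seed is deterministic: the optimizer restarts
are fixed, the grid search is exhaustive, and ties resolve to the smaller
dose.

## What the tests do and do not show

Passing tests establish: the printed model structure and its mass
balances; exactness of the steady-state closed form; correct inversion of
the dosing rules; parameter recovery inside the model class (noise-free
`Si` within 5 percent; median error under 7 percent CV noise within 15
percent); deconvolution fidelity for smooth disturbances; exact agreement
of the grid search with its exhaustive oracle; the dead-zone/saturation
algebra; the paired-arm stream identity; and the closed-loop behaviours
(ILC reference tracking; carbohydrate-robustness of the model-based
optimizer). They do **not** show performance on real CGM data, where
sensor artefacts, unmodelled physiology (exercise, illness, counter-
regulation) and behavioural irregularity are outside the synthetic
generator's scope.

Two known limitations are worth stating plainly. First, with the night
penalty active and meal boluses systematically altered, the titration
equilibrium sits *below* the theoretical steady-state requirement — the
algorithm trades a few units of basal for night-hypoglycemia protection.
Subjects approaching from below therefore level off one to a few units
short of the requirement and may never enter a half-unit neighbourhood
of it, even though their glycemic outcomes are good; convergence-time
summaries right-censor such subjects. Second, the linear model's rescue
carbohydrates raise glucose more sharply than nonlinear physiology
would, which makes daytime traces after a treated hypoglycemia look
spikier than real data.
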
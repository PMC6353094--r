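---
title: "Methods: a Markov cohort model of oral contraceptives for endometriosis-related pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of oral contraceptives for endometriosis-related pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endopain)
```

## The decision problem and the model

Endometriosis-related pain is managed first-line either with combined oral
contraceptives (OC) or with analgesia alone while diagnosis is pursued ("no
hormonal treatment", NHT). The model evaluates the incremental costs and
QALYs of OC versus NHT from an NHS perspective for a cohort entering at age
32 (mean age at diagnosis) and followed to age 50 (mean age at menopause).

Five health states: *no pain* (NRS 0), *mild* (NRS 1–3), *moderate* (NRS
4–6), *severe* pain (NRS 7–10), and absorbing *death*. The cycle length is
one month — short enough to capture symptom change under treatment — giving
216 cycles. Within one month the cohort can move at most one severity level
(a clinical-plausibility restriction), so each arm's transition structure
is a birth–death chain over the four pain states. Death is cause-independent:
the annual probability `q_annual` from the life table is converted to a
monthly `q_m = 1 − (1 − q_annual)^(1/12)`, applied identically from every
alive state, and the arm's pain transitions share the remaining `1 − q_m`.
The disease contributes nothing to mortality; the overlay only makes the
horizon demographically honest. Mortality is refreshed once per model year
(life tables are annual).

Excluded by design: surgery, fertility outcomes, OC side effects, treatment
switching and discontinuation, and any non-pain outcome. These are scope
restrictions of the decision problem, not implementation shortcuts.

## Parameters

* **Transitions** (per arm, monthly): elicited by assigning 1000
  hypothetical patients to each state and counting one-month moves;
  probabilities are the count means (e.g. NHT no-pain→mild 3/1000 = 0.003)
  and the counts double as Beta/Dirichlet pseudo-counts for the PSA
  (`fit_beta_from_counts()`, `fit_dirichlet_from_counts()`).
* **Utilities** (QALY weight per year): elicited from a gynaecologist by the
  roulette ("chips and bins") method — no pain 0.905, mild 0.802, moderate
  0.718, severe 0.573, dead 0 — with per-state Beta PSA parameters from the
  same elicitation. A month in a state contributes `utility/12`. The printed
  utility column is used deterministically and the (α, β) column for PSA
  sampling; the two imply slightly different means (mild: 0.802 printed vs
  82.023/100.265 ≈ 0.818), and which one fed the published deterministic run
  is not stated. `fit_beta_from_roulette()` implements the histogram→Beta
  step by method of moments at bin midpoints; the tool used for the original
  elicitation is named but its fitting math is not published, and method of
  moments is the standard, closed-form, reproducible choice.
* **Costs** (GBP, monthly): GP consultation £26.67 per 10-minute visit,
  every 3 months (NHT) or 6 months (OC); analgesics at maximum-dose monthly
  cost £2.31 (paracetamol) and £2.43 (ibuprofen), scaled by state — none,
  half paracetamol, full paracetamol, full paracetamol + full ibuprofen;
  the OC drug itself £2.82 per pack. A 63-tablet pack covers three 28-day
  cycles, so the monthly drug cost is £0.94. Reading £2.82 as a *monthly*
  cost is tempting but inconsistent with the published totals (it would put
  the OC arm ~£360 too high), while the pack reading reproduces them; the
  package therefore stores `oc_pack_cost` and `oc_pack_months` explicitly.
* **Discounting**: 3.5% per year for costs and QALYs, converted to cycles
  compound — factor `(1.035)^(−t/12)` at cycle `t` — the convention
  consistent with UK HTA practice. A `simple` monthly-rate option exists;
  the difference is below 0.1% of totals.
* **PSA distributions**: utilities Beta(α, β); transition rows Beta for the
  boundary states (single exit) and Dirichlet sampled jointly with the stay
  mass for the interior states; GP visit and OC pack costs Gamma with the
  published mean and an assumed CV of 0.2 (`gamma_from_mean_cv()`) — a
  conventional completion when only a point estimate is published, exposed
  as `costs.cost_cv` so its effect is testable; analgesic unit costs fixed,
  as published.

## Reconstructed inputs

Two inputs of the published analysis are not stated anywhere and had to be
reconstructed. Both are ordinary configuration fields, not constants.

**Initial state distribution.** Because the cohort recursion is linear, any
arm total is a linear function of the starting mix over the four pain
states; four basis runs per arm characterise the model completely
(`initial_split_basis()`). `calibrate_initial_distribution()` exploits this
to find, deterministically, the simplex point minimising the worst relative
error against a set of published totals. The bundled default is the minimax
fit to the published base case (both arms' costs and QALYs, plus the QALY
difference):

```r
inputs <- load_config()
round(inputs$model$initial_distribution, 4)
```

i.e. a cohort entering mostly in mild/moderate pain, which is clinically
sensible for newly diagnosed women. Under this mix all five calibration
quantities are reproduced within about 1.6%. The uncalibrated alternative —
an equal 0.25 split — reproduces the published QALYs almost exactly (within
0.2%) but leaves both arms' costs 3–5% high; the incremental comparison and
the dominance verdict are insensitive to the choice.

**Life table.** Background mortality for women aged 32–50 is tiny and no
source is cited, so the bundled table is synthetic: a Gompertz hazard
`q(age) = 1 − exp(−h0·e^{slope(age−30)})` with `h0 = 4e-4`, `slope = 0.09`,
giving `q_annual` between ~5e-4 and ~3e-3 and cumulative mortality of about
2% over the horizon — the right order for this demographic, documented as
illustrative rather than as any national table. A user-supplied
`age,q_annual` CSV overrides it. Totals move by well under 1% between this
table and zero mortality, so nothing downstream hinges on it.

## Numerical conventions

* **Half-cycle correction**: trapezoidal — cycle accrual weights the mean of
  start- and end-of-cycle occupancy. The correction's variant is not named
  in the publication; the trapezoid is the common implementation, and the
  corrected totals provably lie between the start-of-cycle and end-of-cycle
  accrual conventions (tested). A flag disables it.
* **GP visit costs** are amortised uniformly (visit cost / interval per
  month). The published analysis gives a frequency, not a calendar; the
  alternative `lumped` mode charges the full £26.67 in the visit months and
  differs by under 0.5% of totals (tested), interacting slightly with
  discounting.
* **Dominance and ICER**: differences are intervention (OC) minus comparator
  (NHT). An ICER is reported only when the signs leave a genuine trade-off;
  negative ICERs are never printed — dominance verdicts are, matching
  standard practice.
* **CEAC ties**: draws where the two arms' NMB are exactly equal are split
  half-and-half; the event has probability zero under continuous sampling
  but the rule keeps the two curves complementary by construction. The
  threshold grid is £0–50,000 in £1,000 steps plus an unbounded sentinel
  (`Inf`, "50,000+"), where the comparison reduces to the sign of the QALY
  difference.
* **Degenerate elicitation inputs**: a zero (or full) transition count gives
  a point mass, not an improper Beta, with a warning; a single-bin roulette
  histogram gets its variance floored at `width²/12` (the within-bin
  uniform variance) rather than an error.
* **PSA failure policy**: a draw whose parameters break an engine invariant
  is excluded and counted, and the run continues; the count is reported.
* **Independence**: parameters are sampled independently across draws
  (within-row Dirichlet dependence only), and the one utility set is shared
  by both arms within a draw — utilities are properties of health states,
  not of treatments. No covariance structure is published.

## What the synthetic generators emulate — and what they do not

`simulate_transition_counts()` reproduces the elicitation design itself
(1000 hypothetical patients per state, one-month destination counts) with
known true probabilities, so the Beta/Dirichlet fitting can be
recovery-tested at any cohort size. `simulate_roulette()` emulates a
perfectly calibrated expert whose belief is exactly the target Beta and who
allocates chips multinomially by bin mass. Real elicitation data carry
biases these generators deliberately lack: anchoring, overconfidence,
rounding to focal numbers, and within-expert correlation across states.
Passing recovery tests therefore shows the *computations* are faithful and
consistent, not that elicited inputs are unbiased. Similarly the Gompertz
life table shows the mortality overlay is correct, not that any particular
population's mortality was used.

## Validation

The cohort engine is validated against an independent microsimulation
(`run_microsim()`) that pushes individual patients through the identical
matrices by categorical sampling and accrues rewards per patient with the
same trapezoidal and discounting conventions. The two estimators share no
propagation code, so agreement within Monte-Carlo error is a genuine
cross-check; the test suite requires agreement within 3 standard errors at
200,000 patients, and exact equality on degenerate configurations whose
paths have no randomness. Problem sizes used by the default suite — 216
cycles, 200,000 microsimulated patients, 1,000 PSA draws, recovery checks
at cohort sizes up to 10⁶ — were chosen to keep every Monte-Carlo check at
3-standard-error strength.

## Known limitations

* The published one-way sensitivity analysis (GP costs excluded) cannot be
  reconciled with the published base case under *any* static per-state cost
  vector: subtracting the two published tables implies GP components whose
  ratio contradicts the stated 3:6-month visit frequencies, and an
  analgesic-only NHT total that would require a mean monthly analgesic
  spend unattainable at any state mix consistent with the published QALYs.
  The package computes the scenario faithfully (QALYs bit-identical to
  base; costs drop by exactly the GP component) and reports what the model
  yields — OC dearer by roughly £75 with an ICER near £180/QALY — rather
  than the published £4 and £9/QALY, which this model structure cannot
  produce jointly with the published base case. The qualitative conclusion
  (OC's advantage is carried almost entirely by GP visit frequency, and OC
  remains cost-effective at conventional thresholds) is unchanged.
* The deterministic base case depends on the reconstructed starting mix;
  arm *totals* carry that calibration, while incremental results are robust
  to it.
* The PSA treats parameters as independent and the published sampler and
  seed are unknown, so plane and CEAC summaries are comparable only at
  binomial-tolerance level.
* Cohort homogeneity: no individual heterogeneity, adherence, switching or
  surgery pathways — the model answers the average-cohort question only.
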
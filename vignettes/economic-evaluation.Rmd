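---
title: "Decision-analytic methods behind levoCEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-analytic methods behind levoCEA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levoCEA)
```

levoCEA evaluates, from the hospital payer's perspective, whether a 24-h
levosimendan infusion started 48 h before elective CABG is cost-effective
in patients with LVEF < 40%. This vignette is the package's own account of
the model: its structure and assumptions, the parameters that matter, how
the unpublished inputs were reconstructed and calibrated, the numerical
conventions, and what the synthetic-data checks do and do not demonstrate.

## The decision model

Each strategy (preconditioning vs standard care) is a subtree over four
postoperative complications: new-onset atrial fibrillation (NOAF), low
cardiac output (LCO), renal failure (RF) and prolonged mechanical
ventilation (MV, > 24 h). The dependence structure is the minimal one
consistent with the clinical narrative that LCO may follow atrial
fibrillation and raises the risk of renal failure and prolonged
ventilation:

* NOAF is drawn first (arm-specific marginal);
* LCO is conditional on NOAF;
* RF and MV are conditionally independent given LCO;
* cardiogenic shock is the severe extreme of LCO (a subset, no separate
  tree state);
* death is recorded in cohorts but is **not** a tree state — the model
  tracks complications and length of stay over the admission horizon, not
  mortality, and applies no discounting over so short a horizon.

That yields 16 terminal pathways per arm. A pathway's probability is the
product of its branch conditionals; its ICU and ward stays are an
arm-specific base plus additive per-complication increments; its cost is
priced from the unit-cost catalogue through resource-use profiles:

* `base` — fixed per patient (surgery, pre-operative work-up, routine ICU
  echocardiogram, pre-discharge ECG);
* `per_icu_day` / `per_ward_day` — stay day rate plus daily tests and
  medication, multiplied by the pathway stay;
* `upfront_intervention` — levosimendan vial-course, coronary-care-unit
  day, pre-operative ward day and monitoring tests, intervention arm only;
* per-complication add-ons (`noaf`, `lco`, `rf`, `mv`) — antiarrhythmics;
  daily echocardiography and amines; hemofilter consumables; ventilation
  days and digestive decontamination.

Roll-back is the probability-weighted sum over pathways; effectiveness is
the percentage of patients free of all four complications. The strategy
comparison reports the cost difference as control − intervention and the
stay/effect differences as intervention − control, with dominance declared
when the intervention is simultaneously cheaper and more effective, and an
ICER (euros per additional complication-free patient) otherwise.

## Parameters and their sources

**Probabilities.** The conditional chain is estimated per arm as empirical
fractions from per-patient records (`estimate_probabilities()`), stored as
occurrence/denominator counts. The packaged defaults come from the
reconstructed 54-patient reference cohort (below). A conditional with an
empty denominator falls back to the arm marginal with a warning.

**Unit costs** (euros, hospital accounting): the 23-item catalogue in
`default_catalogue()`, from the 6269.20 € surgery and 1266.95 € ICU day
down to 0.03 € aspirin tablets. Costs are stored at two decimals, arithmetic
runs in full precision, and a written catalogue round-trips exactly.

**Resource quantities.** Per-pathway quantities are *not* published
anywhere; the packaged profiles are reconstructions from the narrative
description of routine care and complication management, with two
calibration degrees of freedom (the average daily laboratory intensity in
the ICU and the monitoring tests attached to the preconditioning
admission) chosen once so that the rolled-back strategy costs reproduce
the observed per-strategy costs of 14,792.33 / 17,006.94 € to within a few
percent. Every quantity is config-overridable and two conventions are
explicit because the source is silent on them:

* mechanical ventilation at ICU (460.00 €) is treated as **per day** of
  prolonged ventilation (2 days by default), not per episode;
* the preconditioning admission consumes **one** coronary-care-unit day
  (the 24-h infusion) plus one ward day; `intervention_upfront_profile()`
  makes both quantities arguments.

**Length of stay.** Strategy-level mean stays are published (ICU
2.50 / 5.70 days, ward 6.46 / 6.40 days) but per-complication attribution
is not. The model fixes clinically motivated additive increments — ICU:
+1 day (NOAF), +4 (LCO), +3 (RF), +2 (MV); ward: +0.5 (NOAF), +1 (RF) —
and solves the arm base days so the rolled-back means equal the published
strategy means exactly. The near-equality of the two ward means despite
very different complication burdens is why the ward increments are small.

**A structural note on the published cost difference.** The published
per-strategy costs imply a difference of 2,214.61 € by column subtraction
(the printed difference row, 2,274.61 €, does not equal the subtraction of
its own columns; the package always reports the arithmetic difference).
Either number is *below* what any additive stay-costing model can produce
given the published stay gap: 3.2 extra ICU days at the 1,266.95 € day rate
already cost 4,054 €, against an upfront preconditioning cost of ~1,726 €.
The calibration therefore prioritises the two strategy cost levels and the
stay means, and accepts a larger incremental saving (~2,700 €) than the
published difference row. This is a genuine internal tension of the source
data, not a tunable residual.

## Probabilistic sensitivity analysis

Distribution families follow standard health-economic practice:
probabilities → beta, defined by occurrence and non-occurrence counts;
unit costs → gamma, with shape solved numerically (cached `uniroot`) so the
central 95% interval spans mean·(1 ± 0.10); resource quantities and stay
parameters → uniform(0.9q, 1.1q). Zero-occurrence beta cells receive the
Jeffreys adjustment (+½ to both shapes). Unit-cost and shared-quantity
draws are common to both strategies within a draw (toggle
`psa$shared_cost_draws`); arm-specific parameters draw independently.

**Effective sample size.** Beta distributions parameterized by the raw
cohort counts (n = 13 and 41) give effectiveness intervals tens of
percentage points wide — far wider than the published probabilistic
intervals, whose effectiveness bounds span only ~5 points, and wide enough
that a noticeable minority of draws would leave the dominant quadrant,
contradicting the published observation that every simulation did. The
packaged configuration therefore scales the beta counts by an
effective-sample multiplier `ess = 75`, calibrated once so the
intervention effectiveness interval width matches the published ~5.7
points (the cost interval widths then match as well). `ess = 1` restores
literal cohort-count betas; the discrepancy between the stated
parameterization and the published interval widths is inherent to the
source and is surfaced here rather than hidden.

Draw order is parameter-major and documented (intervention chain, control
chain, unit costs in catalogue order, stay bases and increments, profile
quantities), so a seed fixes the entire analysis bit-for-bit. The
vectorized evaluator used by `run_psa()` shares its arithmetic path with
`base_case()`, which is why a fully pinned analysis (`fixed = TRUE`)
reproduces the base case *exactly*, not merely within tolerance; agreement
with the per-pathway `build_tree()` + `rollback()` route is asserted to
1e-9 in the tests.

## The reference cohort and the generator

The study's per-patient data are unavailable; only arm-level margins are
published. `reference_cohort()` ships one canonical 54-patient solution of
the published constraint system (event margins per arm, LVEF-stratum LCO
splits, complication-free totals, shock ⊆ LCO, deaths among shock
patients, and integer stays matching the published medians and
interquartile ranges). In the intervention arm the margins force exactly
one complication per complicated patient; in the control arm the
reconstruction concentrates RF/MV/shock on LCO patients. Other solutions
exist: conditionals estimated from the fixture are calibration artifacts,
and the package never presents them as published values. Two further
source discrepancies are recorded rather than resolved: the in-text
stratified p-value (0.02) versus the tabulated 0.01 — the package
reproduces the tabulated value under the continuity correction — and a
15.3% vs 15.4% rounding inconsistency for 2/13, where the fixture keeps
the counts.

`generate_cohort()` draws arbitrary-size cohorts along the same
conditional chain with log-normal stays per (arm, complication-free) cell,
the cell means matching the reference cohort. It emulates the *event
structure* the model assumes — independent patients, the NOAF→LCO chain,
conditional independence of RF and MV given LCO. It does not emulate
correlated comorbidity, continuous biomarkers, within-stay dynamics, or
any violation of the tree's conditional-independence assumptions, so the
parameter-recovery tests demonstrate internal consistency of the pipeline,
not robustness to model misspecification on real data.

## Numerical conventions

* Pathway probabilities must conserve mass to 1e-9 at roll-back.
* Percentages shown at one decimal use half-up rounding (2/13 → 15.4);
  p-values are kept at full precision and rounded only for display.
* Fisher sidedness: the published shock p-value is matched by the
  one-sided hypergeometric tail, so `fisher_exact()` exposes both and the
  analysis labels the one-sided convention explicitly; the two-sided
  p-value sums point probabilities ≤ the observed one (tiny relative
  tolerance for floating-point ties).
* Mantel–Haenszel: continuity correction on by default; variance
  convention N²(N−1), under which a single stratum equals the Pearson
  statistic times (N−1)/N.
* Mann–Whitney: midranks; exact permutation distribution up to 20 total
  observations, normal approximation with continuity correction above.
* The LCO override of the deterministic analysis rescales both LCO
  conditionals by a common factor (preserving the NOAF→LCO association)
  and refuses overrides that would push a conditional past 1.
* No multiple-testing adjustment is applied anywhere, matching the
  analysis this package implements.

## Problem sizes

The shipped analyses use the study's own scale: 54-patient cohort
statistics, 16-pathway roll-backs, 10,000 Monte Carlo draws, and
10,000-patient-per-arm generator recovery checks.

## Limitations

Beyond the reconstruction caveats above: the cohort is small and
non-randomized (sequential assignment), costs are single-centre Spanish
hospital accounting with limited transferability, the effectiveness unit
(complication-free patient) ignores severity gradations within
complications, and the model has no mortality, no long-term horizon, no
quality-adjustment and no acceptability-curve machinery — dominance makes
a willingness-to-pay threshold unnecessary here, and the package
deliberately stops there.
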
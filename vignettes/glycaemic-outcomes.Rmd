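---
title: "Medication-adjusted glycaemic outcomes: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Medication-adjusted glycaemic outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycman)
```

# Why medication-adjusted outcomes

In pragmatic trials of glucose-lowering interventions run under routine
primary care, prescribers keep titrating medication during follow-up. HbA1c
and drug exposure therefore confound each other: a flat HbA1c on less drug
is a success, a flat HbA1c on more drug is a failure. `glycman` implements
two complementary corrections — a continuous one (the medication effect
score) and a categorical one (the glycaemic-management composite) — together
with the surrounding trial machinery, and a synthetic cohort generator so
the whole pipeline is testable without participant-level data.

# The medication effect score

For one drug, the MES is the HbA1c reduction (percentage points) expected
if the prescribed dose were used as monotherapy:

$$\mathrm{MES} = \min\!\left(\frac{\text{dose}}{\text{max dose}},\, 1\right)
\times \text{adjustment factor}$$

The adjustment factor is the expected maximal HbA1c reduction of the drug as
monotherapy at its maximum recommended dose. Total MES sums over a
multidrug regimen; MES-corrected HbA1c is measured HbA1c (%) plus total MES.

Conventions:

- **Capping.** Doses above the maximum are capped at ratio 1 and flagged.
  The MES is a *maximal expected* reduction; it cannot exceed the
  monotherapy maximum. Whether reference implementations cap is not
  documented anywhere we could verify, so the cap is this package's choice;
  the flag keeps it auditable.
- **Scale.** All MES arithmetic happens on the NGSP % scale. Values on the
  IFCC scale are first converted with the NGSP linear form
  `% = 0.09148 × mmol/mol + 2.152` (and its exact inverse). The conversion
  is tested against published paired values to one decimal.
- **The drug table.** Maximum doses and adjustment factors are not universal
  constants; published tables differ by country and era. The shipped
  defaults (`inst/extdata/drug_table.json`: metformin 3000 mg / 1.5 %,
  sulfonylureas 1.5 %, DPP4 inhibitor 0.75 %, GLP-1 agonist 1.0 %, basal
  insulin 2.5 %) are typical literature values and are deliberately
  user-overridable; no factor is hard-coded in logic. Analyses should report
  which table they used.

# The glycaemic-management composite

Individual HbA1c change is categorised on the mmol/mol scale with an
inclusive 5 mmol/mol (0.5 %) threshold; medication change is categorised by
exact dose comparison (doses are discrete tablet multiples, so no tolerance
band). The composite crosses the two:

| medication \\ HbA1c | improved | stable | deteriorated |
|---|---|---|---|
| decreased | improved | improved | deteriorated (flagged) |
| stable | improved | stable | deteriorated |
| increased | deteriorated | deteriorated | deteriorated |

Three cells deserve comment:

- **(decreased, deteriorated)** is not covered by the verbal category
  definitions; such participants used less medication *and* lost glycaemic
  control. They are conservatively classified deteriorated, and
  `tie_break_applied` is set so they can be counted and reported.
- **Mixed regimen changes** (one drug up, another down) are classified
  *increased*: any escalation signals failed glycaemic control. In
  metformin-dominated cohorts the case is rare, but the rule must be total.
- **Boundary.** Exactly +5 mmol/mol is *deteriorated* and exactly −5 is
  *improved* (the threshold is inclusive on both sides). The composite's
  "not more than 5 mmol/mol higher" clause is interpreted through the three
  HbA1c categories, so exactly +5 remains deteriorated. The 0.5 % threshold
  is never applied independently — % inputs are converted to mmol/mol first
  to avoid double rounding.

# OGTT insulin-sensitivity indices

From 2-hour OGTT curves sampled at 0, 30, 60, 90, 120 min:

- **Matsuda index** $= 10000 / \sqrt{G_0 I_0 \bar G \bar I}$ in conventional
  units (glucose mg/dl, insulin µU/ml), with $\bar G, \bar I$ arithmetic
  means over all samples including fasting (the original formulation); a
  trapezoidal time-weighted mean is available by option.
- **Insulinogenic index** $= (I_{30}-I_0)/(G_{30}-G_0)$, flagged when the
  denominator is negative.
- **Disposition index** = Matsuda × a secretion measure. Because more than
  one composition is in circulation, the secretion measure is configurable:
  the insulinogenic index (default) or the 0–120 min AUC ratio
  (trapezoidal). The choice is recorded in the result. We make no claim that
  either composition reproduces any particular published scale, and the
  package does not tune constants toward one.

Unit conversions use 18.016 (mg/dl per mmol/l glucose) and 6.0 (pmol/l per
µU/ml insulin). The insulin constant varies between 6.0 and 6.945 across
laboratories; 6.0 is used and recorded in the curve's `units_note` so
downstream indices are auditable.

# The statistical layer

- **Test selection.** "Chi-squared assumptions violated" is operationalised
  as any expected cell count < 5. For 2×2 tables that triggers the
  two-sided Fisher exact test; otherwise Pearson chi-squared, with Yates
  continuity correction applied to 2×2 tables only (the common software
  default; it also matters numerically for sparse-but-not-Fisher tables).
- **Fisher convention.** Two-sided p by point-probability ordering: sum of
  the probabilities of all tables (margins fixed) whose point probability is
  at most the observed one, with a 1e-7 relative slack against floating-point
  ties. This is the dominant convention; the tests verify agreement with an
  independent enumeration oracle on every table with N ≤ 40 and with
  `stats::fisher.test`.
- **Mixed models.** Treatment effects for continuous outcomes are fitted by
  REML on the follow-up visits: fixed effects for time (categorical 6/12),
  time×arm, the baseline value of the outcome, sex and the 100-kg weight
  stratum, with a participant random intercept; complete-case per timepoint,
  no imputation. The reported effect is the time×arm contrast at 12 months.
  `lme4` provides no p-values and the CI method was an open choice: Wald
  normal intervals and p-values are used, which at trial sample sizes are
  mildly anti-conservative relative to Satterthwaite but require no extra
  dependency. A post-hoc variant adds concurrent body weight as a fixed
  effect.
- **Multiplicity.** Benjamini–Hochberg step-up over the secondary continuous
  outcomes; implemented in-package (it is part of the specified surface) and
  cross-checked against `stats::p.adjust`.
- **Analysis sets.** ITT keeps everyone with baseline data, as randomised;
  PP keeps intervention-arm participants who were compliant with the full
  programme *and* finished follow-up, plus control-arm completers.

# Randomisation

Stratified permuted blocks, sizes drawn uniformly from {2, 4} (the mixing
ratio is unpublished; uniform is the neutral choice), strata = sex × weight
class. The weight boundary is ambiguous in common phrasings ("<100 or >100");
we define the upper stratum as strictly > 100 kg, so exactly 100 kg falls in
the lower stratum. Completed blocks are perfectly balanced; a partially
filled block of 4 can put one arm ahead by at most 2, which bounds the
within-stratum imbalance at every enrolment prefix — a property the tests
check over 10,000 simulated enrolments. The seed and the drawn block sizes
are stored in the plan for audit.

# The synthetic cohort generator

The generator's defaults state one world, chosen once:

- ~100 participants, sex ~50/50, age 63 ± 8, weight 100 ± 15 kg, HbA1c
  53 ± 10.5 mmol/mol (truncated > 20), fasting glucose 8.5 ± 1.9 mmol/l,
  insulin 150 ± 80 pmol/l; 89 % on metformin with doses on a 500-mg grid
  (median 1000).
- Arm effects at 6/12 months: HbA1c −5.0/−3.2 mmol/mol, weight −3.8/−3.6 kg;
  within-participant structure via random intercepts (HbA1c 5, weight
  2.5 units) sharing a latent factor (r = 0.5) so weight change tracks
  glycaemic change, plus residual noise (4 and 1.5). The correlation and
  noise magnitudes are unpublished for this population; these values are
  plausible for repeated HbA1c/weight measurements and are flagged as
  unvalidated.
- Dropout 16 %/20 % per arm, missing at random by construction (independent
  of outcomes), censoring from a uniformly chosen follow-up visit onward.
  FMD-arm protocol compliance 0.7.
- A **prescribing-policy caricature**: escalate one 500-mg metformin step
  (then add a sulfonylurea) when HbA1c > 53 mmol/mol; de-escalate one step
  (or stop) when HbA1c < 48 *and* weight loss ≥ 3 % of baseline; 80 %
  adherence to the policy. The 3 % threshold was chosen because the
  intervention arm's configured mean loss is ~4–5 %, making roughly half the
  arm eligible for de-intensification — enough for medication categories to
  emerge endogenously in the published direction. The policy reacts to
  single visit values, so it escalates more often than real guideline care;
  consequently the generator matches the published medication-category
  pattern in *direction* only, and the tests assert only direction.
- **OGTT model**: glucose rises by a fixed-shape excursion peaking at
  60 min; insulin rises proportionally, scaled inversely by a lognormal
  per-participant sensitivity multiplier. The insulin gain (4.8) was
  calibrated once, through the package's own baseline generator, so the
  default cohort's mean Matsuda index is ≈ 1.5 — an insulin-resistant type 2
  diabetes population — and then frozen.
- The continuous MES channel in `simulate_trajectories` exists for
  effect-injection studies of the estimator and is deliberately not floored
  at zero: flooring would censor the injected contrast differentially
  between arms. Pipeline MES is computed from regimens and is non-negative
  by construction.

What a green end-to-end test establishes: that the scoring, classification
and testing machinery recovers what the generator injected, at the stated
sample sizes. What it does not establish: that real cohorts share the
generator's distributional forms (truncated normals, MAR dropout, a
single-threshold prescribing policy), nor anything about OGTT index scales
beyond the calibrated mean.

# Degenerate inputs and numerical conventions

- Zero-dose prescriptions are identical to absence of the drug; an empty
  regimen (diet only) is valid and scores 0.
- Degenerate contingency margins: an empty row/column is an error in
  `association_test` (the test is meaningless) but yields p = 1 in
  `fisher_exact_2x2` by convention.
- Undefined OGTT indices (zero fasting insulin, G30 = G0) raise explicit
  errors rather than returning NaN.
- Classification excludes (and logs) participants missing the follow-up
  visit, mirroring loss-to-follow-up accounting; counts always sum to the
  number classified, and reported percentages are `round(100·count/total)`
  with counts co-reported.

# Known limitations

- Adjustment factors are treatment-era and guideline specific; the shipped
  table is a reasonable default, not a standard.
- Wald mixed-model inference is mildly anti-conservative at small n.
- The generator does not model the intervention's physiology (ketosis,
  IGF-1), adverse events, or informative dropout; its prescribing policy is
  a caricature by design.
- Matsuda/disposition values depend on the insulin conversion constant and
  the secretion-measure choice; cross-study comparison requires fixing both.
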
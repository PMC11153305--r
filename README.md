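# glycman

Medication-adjusted glycaemic outcomes for randomised trials of
glucose-lowering interventions in type 2 diabetes.

## The problem

In trials run under routine primary care, HbA1c alone is a misleading
endpoint: general practitioners adjust glucose-lowering medication during
follow-up, so a participant whose HbA1c is unchanged but who stopped
metformin has plainly improved, while one holding the same HbA1c on an
escalated regimen has deteriorated. `glycman` implements the scoring and
analysis machinery for this setting, for trial statisticians and
methodologists who need the whole pipeline testable without access to
participant-level data.

Its core quantities:

- **Medication effect score (MES).** For each drug,
  `MES = min(dose / max_dose, 1) × adjustment factor`, where the adjustment
  factor is the expected maximal HbA1c reduction (percentage points) of that
  drug as monotherapy at maximum dose. Total MES over a regimen is the
  maximal HbA1c reduction the regimen could be expected to produce: a total
  MES of 2.5 reads as "up to 2.5 percentage points of HbA1c are attributable
  to drug support". **MES-corrected HbA1c** = measured HbA1c (%) + total MES.
- **Glycaemic management**, a composite categorical endpoint: HbA1c change
  (±5 mmol/mol = 0.5 %, boundaries inclusive) crossed with medication change
  (any dose increase or added drug = increased; any decrease or stop =
  decreased). Less medication without meaningful HbA1c worsening is
  *improved*; any escalation, or HbA1c worsening without medication change,
  is *deteriorated*; the ambiguous cell (medication down, HbA1c up) is
  conservatively *deteriorated* with an audit flag.
- **OGTT indices**: Matsuda index `10000 / sqrt(G0·I0·Ḡ·Ī)` (conventional
  units), insulinogenic index `(I30−I0)/(G30−G0)`, and their product, the
  disposition index.
- **Trial statistics**: chi-squared association tests with the
  expected-count (< 5) Fisher-exact fallback and Yates correction on 2×2
  tables, Benjamini–Hochberg FDR control, REML linear mixed models for
  longitudinal treatment effects (time, time×arm, baseline and stratifier
  adjustment, participant random intercept), ITT/PP analysis sets, and
  stratified permuted-block randomisation (blocks of 2 and 4, sex × 100-kg
  stratum).
- **A synthetic cohort generator** that emulates such a trial end to end,
  including a caricature general-practitioner prescribing policy so
  medication-change categories emerge endogenously.

## Worked example

```r
library(glycman)

tab <- default_drug_table()
total_mes(regimen("metformin", 1500), tab)
#> <mes_result> total MES = 0.75
#>   metformin: 0.75

mes_corrected_hba1c(6.9, 0.7)
#> [1] 7.6

classify_glycaemic_management("stable", "decreased")
#> $category
#> [1] "improved"
#> $tie_break_applied
#> [1] FALSE

coh <- simulate_cohort(sim_config(n = 100), seed = 7)
rep <- run_pipeline(coh, analysis_set = "ITT", timepoint = 12)
rep$category_tables$glycaemic_management
#>         improved stable deteriorated
#> FMD           15      4           20
#> control        8      8           20
rep$association_tests$glycaemic_management$p_value
#> [1] 0.18739
```

The last table is the arm-by-category count of the composite endpoint at 12
months in a simulated 100-participant trial; the p-value is the 3×2
chi-squared test of association between arm and category. The FMD arm shows
the expected excess of improvements, but a single simulated trial of this
size is — realistically — not guaranteed a significant composite endpoint;
the parameter-recovery tests work at n = 2000 for exactly that reason.

## Analysis workflow

Numbered drivers under `analysis/` run the full study on a simulated
cohort and write their tables under `results/`:

1. `01_simulate_cohort.R` — generate and save the synthetic cohort
2. `02_score_medication.R` — MES / corrected-HbA1c outcome summary
3. `03_classify_outcomes.R` — categorical endpoints, ITT and PP
4. `04_trial_inference.R` — association tests, mixed models, FDR correction
5. `05_reference_counts.R` — encode the reference trial's printed category
   counts and reproduce its reported tests

Run each with `Rscript analysis/<script>` from the repository root.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline worked example from
scratch — the total MES of a two-drug regimen prescribed at full maximum
dose with adjustment factors 1.5 and 1.0, i.e. the maximal expected HbA1c
decrease that regimen implies — and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/glycaemic-outcomes.Rmd`) documents the
models and conventions: category boundary rules, the Fisher two-sided
convention, unit-conversion constants, what the synthetic generator does and
does not emulate, and the package's design decisions.
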
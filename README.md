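# recallval

Validation and cost-effectiveness analysis of interviewer-administered
24-hour dietary recall (24HR) surveys against a weighed food record (WFR)
benchmark, for nutrition researchers comparing survey modalities (e.g.
computer-assisted vs pen-and-paper interviewing, "CAPI" vs "PAPI") in a
paired two-arm design: every respondent is observed for one WFR day and
interviewed the next day with the 24HR modality of their arm.

The package covers the full workflow:

* **Reference data** — load/validate a dietary reference bundle (food list,
  food composition table per 100 g, standard recipes with total prepared
  weight, portion-size conversion factors, FAO/WHO GIFT food-group map) and
  report per-nutrient FCT completeness.
* **Intake conversion** — resolve coded consumption records to grams
  (direct weights or portion-size estimation methods), compute recipe
  nutrient densities (`100 · Σ gᵢ·cᵢ/100 / total prepared g`, no cooking
  losses), and aggregate to daily intakes of energy, fat, protein,
  carbohydrate, fibre, vitamins A/C, Ca, Fe, Zn plus per-group energy.
* **Quality control** — flag days with energy < 500 or > 5000 kcal
  (2092/20920 kJ), exclude respondents with an implausible WFR day, log
  pairs differing by > 1000 kcal for review.
* **Validation statistics** — paired two one-sided t-tests (TOST) on log
  intakes with symmetric bounds ±ln(1.1) (equivalence declared when
  max(p₁,p₂) < 0.05); Bland–Altman bias and 95% limits of agreement;
  difference-in-differences between modalities via a random-intercept mixed
  model on the stacked data; cumulative percentage-error bands
  (±10/20/30/50%); median GIFT-group energy shares with paired signed-rank
  tests; and the design-stage Fisher-z sample size
  `n = ⌈((z₁₋α/₂ + z_pow)/(atanh ρ₁ − atanh ρ₀))² + 3⌉`.
* **Costing** — activity- and ingredients-based cost ledgers (time in
  person-days at wages, respondent time at the minimum wage, non-time
  inputs), group-level accuracy `100 − 100·|1 − mean₂₄ʜʀ/mean_WFR|` (capped
  at 100), composite nutrient accuracy (mean of the ten per-nutrient
  accuracies), cost per accuracy percentage point, and
  reference-data-borrowing scenarios (25/50/75% borrowed for CAPI only).
* **Synthetic data** — a seeded generator of reference bundles and paired
  WFR/24HR records with a controllable recall-error structure (omissions,
  intrusions, multiplicative portion error, recipe swaps,
  implausible-energy outliers) plus a truth table, so every statistic can
  be checked against known parameters.

## Worked example

```r
library(recallval)
res <- run_pipeline(run_config(sim = sim_config(seed = 20260901)))
print(res)
```

```
<pipeline_result>
  respondents: 232 generated, 6 excluded by QC, 226 analysed
<validation_report>
  CAPI: 8/12 outcomes equivalent to WFR at the bound
  PAPI: 9/12 outcomes equivalent to WFR at the bound
  DiD: 0/12 outcomes differ between modalities (p<0.05)
  CAPI accuracy: item 98.1%, gram 94.0%, composite 93.5%
  PAPI accuracy: item 99.3%, gram 91.8%, composite 92.2%
```

Under the default error structure (10% omissions/intrusions, 5% portion
bias with 30% CV, ~3% implausible days) the pipeline reproduces the
qualitative field pattern: macronutrients are mostly equivalent at the 10%
bound, micronutrients often are not, individual-level accuracy is far worse
than group-level (only ~35% of respondents within ±10% for energy), and the
two modalities rarely differ from each other. The same study step by step,
with tables written under `results/simulated_study/`, is in the numbered
scripts:

```sh
Rscript analysis/01_simulate.R            # bundle, records, truth, ledger
Rscript analysis/02_convert_and_qc.R      # intakes, flags, exclusions
Rscript analysis/03_validate.R            # TOST / DiD / bands / food groups
Rscript analysis/04_costeff.R             # costs and borrowing scenarios
Rscript analysis/05_design_and_recovery.R # sample size, parameter recovery
```

For example, stage 4 prints (toy ledger, single currency):

```
base total cost: CAPI 21170 vs PAPI 22610 (difference -1439)
cost per composite accuracy point by scenario:
  borrow_0: CAPI 226.4, PAPI 245.2
  borrow_25: CAPI 219.6, PAPI 245.2
  borrow_50: CAPI 212.8, PAPI 245.2
  borrow_75: CAPI 206.0, PAPI 245.2
```

PAPI's ratio is constant across scenarios because only CAPI's
reference-data preparation is cheapened by borrowing.

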
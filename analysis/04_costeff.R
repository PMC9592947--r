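#!/usr/bin/env Rscript
# Stage 4: cost-effectiveness of the two modalities.
#
# Activity- and ingredients-based cost totals (time in person-days valued at
# wages, respondent time at the minimum wage, plus non-time inputs) are set
# against the three accuracy measures (item count, grams, composite of ten
# nutrient accuracies) as cost per percentage point of accuracy, for the
# base case and for scenarios in which 25/50/75% of the dietary reference
# data is borrowed from a shared repository for the CAPI modality.

library(recallval)

study <- "results/simulated_study"
bundle <- load_reference_bundle(file.path(study, "refdata"))
records <- read_consumption_records(file.path(study, "records.csv"))
intake <- daily_intakes(records, bundle)
qc <- apply_exclusions(intake, flag_records(intake), qc_policy())
ledger <- read_cost_ledger(file.path(study, "costs.csv"))

acc <- list(CAPI = accuracy_measures(qc$intake, "CAPI"),
            PAPI = accuracy_measures(qc$intake, "PAPI"))
ce <- ce_scenarios(ledger, acc, fractions = c(0, 0.25, 0.50, 0.75))
write_ce_result(ce, file.path(study, "costeff"))

for (arm in names(acc)) {
  a <- acc[[arm]]
  cat(sprintf("%s accuracy: items %.1f%%, grams %.1f%%, composite %.1f%%\n",
              arm, a$item_count, a$gram, a$composite))
}
base <- ce$costs[ce$costs$borrow_fraction == 0, ]
cat(sprintf("\nbase total cost: CAPI %.0f vs PAPI %.0f (difference %+.0f)\n",
            base$total_cost[base$modality == "CAPI"],
            base$total_cost[base$modality == "PAPI"],
            base$total_cost[base$modality == "CAPI"] -
              base$total_cost[base$modality == "PAPI"]))
r <- ce$ratios[ce$ratios$measure == "composite_nutrient", ]
cat("cost per composite accuracy point by scenario:\n")
for (s in unique(r$scenario)) {
  cat(sprintf("  %s: CAPI %.1f, PAPI %.1f\n", s,
              r$total_cost_per_point[r$scenario == s & r$modality == "CAPI"],
              r$total_cost_per_point[r$scenario == s & r$modality == "PAPI"]))
}
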
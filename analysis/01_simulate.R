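#!/usr/bin/env Rscript
# Stage 1: generate the synthetic validation study.
#
# Emulates the paired two-arm design: every respondent is observed for one
# weighed-food-record (WFR) day and interviewed the next day with the 24HR
# modality of their arm (CAPI or PAPI). The generator's defaults encode the
# emulated study conditions: 116 respondents per arm, a cereal-staple diet
# around 2000-2300 kcal/d, 10% omissions and intrusions, 5% mean portion
# overestimation (CV 30%), occasional recipe substitution and ~3%
# implausible-energy days. Writes the reference bundle, the consumption
# records, the perturbation truth table and the toy cost ledger.

library(recallval)

out <- "results/simulated_study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260901)
bundle <- generate_reference_bundle(cfg)
stopifnot(nrow(validate_refdata(bundle)) == 0)
write_reference_bundle(bundle, file.path(out, "refdata"))

gen <- generate_paired_records(cfg, bundle)
write_consumption_records(gen$records, file.path(out, "records.csv"))
write.csv(gen$truth, file.path(out, "truth.csv"), row.names = FALSE)
write.csv(generate_cost_ledger(cfg$seed), file.path(out, "costs.csv"),
          row.names = FALSE, na = "")

cat(sprintf("menu: %d foods, %d recipes over %d GIFT groups\n",
            nrow(bundle$foods), nrow(bundle$recipe_meta),
            length(unique(bundle$foods$gift_group))))
cat(sprintf("records: %d rows for %d respondents (events: %s)\n",
            nrow(gen$records), length(unique(gen$records$respondent_id)),
            paste(names(table(gen$truth$event)), table(gen$truth$event),
                  sep = "=", collapse = ", ")))
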
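#!/usr/bin/env Rscript
# Stage 2: convert coded records to nutrient intakes and screen them.
#
# Every consumed item is resolved against the reference bundle (portion
# factors -> grams; food composition or recipe density -> nutrients per
# item), summed to one row per respondent-day, and screened with the energy
# plausibility rules: days under 500 kcal (2092 kJ) or over 5000 kcal
# (20920 kJ) are flagged; respondents with an implausible WFR day are
# excluded; 24HR days more than 1000 kcal from their WFR partner are logged
# for review but kept.

library(recallval)

study <- "results/simulated_study"
bundle <- load_reference_bundle(file.path(study, "refdata"))
records <- read_consumption_records(file.path(study, "records.csv"))

intake <- daily_intakes(records, bundle)
write_intake_table(intake, file.path(study, "intakes.csv"))

flags <- flag_records(intake)
qc <- apply_exclusions(intake, flags, qc_policy())
write_qc_log(qc$log, file.path(study, "qc_log.csv"))

comp <- fct_completeness(bundle, intersect(records$code, bundle$foods$food_code))
cat("FCT completeness (%):\n")
print(round(comp, 1))
cat(sprintf("\n%d respondent-days; %d flags (%s); %d respondents excluded\n",
            nrow(intake$intakes), nrow(flags),
            paste(names(table(flags$flag_kind)), table(flags$flag_kind),
                  sep = "=", collapse = ", "),
            length(qc$excluded_respondents)))
en <- intake$intakes$energy_kcal[intake$intakes$source == "WFR"]
cat(sprintf("WFR energy: median %.0f kcal (IQR %.0f-%.0f)\n",
            median(en), quantile(en, .25), quantile(en, .75)))
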
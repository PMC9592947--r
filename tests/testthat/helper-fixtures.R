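# Fixtures built in code: a tiny hand-checkable reference bundle and small
# record/intake constructors used across the test files.

tiny_foods <- function() {
  data.frame(
    food_code = c("F001", "F002", "F003", "F004"),
    name = c("rice", "oil", "tomato", "fish"),
    gift_group = c("G01", "G10", "G04", "G07"),
    energy_kcal = c(360, 884, 20, 120),
    fat_g = c(1, 100, 0.2, 4),
    protein_g = c(7, 0, 1, 20),
    carb_g = c(79, 0, 4, 0),
    fibre_g = c(2, 0, 1.5, 0),
    vita_mcg_rae = c(0, 0, 50, 10),
    vitc_mg = c(0, NA, 13, 0),   # oil's vitamin C is missing, not zero
    ca_mg = c(10, 0, 12, 60),
    fe_mg = c(1.2, 0, 0.5, 1),
    zn_mg = c(1.1, 0, 0.2, 0.8),
    stringsAsFactors = FALSE)
}

# one standard recipe: 200 g rice + 100 g oil prepared to 600 g
# -> energy density (200*3.6 + 100*8.84) * 100 / 600 = 267.3333 kcal/100 g
tiny_bundle <- function() {
  new_reference_bundle(
    foods = tiny_foods(),
    recipes = data.frame(recipe_code = c("R01", "R01"),
                         food_code = c("F001", "F002"),
                         ingredient_g = c(200, 100), stringsAsFactors = FALSE),
    recipe_meta = data.frame(recipe_code = "R01", total_prepared_g = 600,
                             gift_group = "G01", stringsAsFactors = FALSE),
    portion_factors = data.frame(
      psem_code = c("standard_unit", "photo", "proxy_water"),
      unit_code = c("bottle", "P12", "bowl"),
      size_label = c("small", "small", "full"),
      grams_per_unit = c(300, 85, 350), stringsAsFactors = FALSE),
    groups = data.frame(
      gift_group = c("G01", "G04", "G07", "G10"),
      label = c("Cereals", "Vegetables", "Fish", "Fats and oils"),
      stringsAsFactors = FALSE))
}

# records-schema row with direct grams
rec_row <- function(id, arm, source, code, grams,
                    item_type = if (startsWith(code, "R")) "standard_recipe" else "food") {
  data.frame(respondent_id = id, arm = arm, source = source,
             item_type = item_type, code = code, grams = grams,
             psem_code = NA_character_, unit_code = NA_character_,
             size_label = NA_character_, n_units = NA_real_,
             stringsAsFactors = FALSE)
}

# minimal intake_table with given energies, for qc tests
fake_intake <- function(respondent_id, arm, source, energy) {
  n <- length(respondent_id)
  it <- data.frame(respondent_id = respondent_id, arm = arm, source = source,
                   gram_total = 1000, item_count = 5L,
                   stringsAsFactors = FALSE)
  for (nm in recall_nutrients()) it[[nm]] <- 1
  it$energy_kcal <- energy
  for (nm in paste0("miss_", recall_nutrients())) it[[nm]] <- FALSE
  ge <- data.frame(respondent_id = respondent_id, source = source,
                   gift_group = "G01", energy_kcal = energy,
                   stringsAsFactors = FALSE)
  structure(list(intakes = it, group_energy = ge), class = "intake_table")
}

# stacked long data for diff_in_differences from per-arm difference vectors
# (value.WFR - value.R24 = diff), with real between-respondent spread
did_data <- function(diff_capi, diff_papi, base_start = 1000) {
  d <- c(diff_capi, diff_papi)
  n <- length(d)
  base <- base_start + 100 * seq_len(n)
  data.frame(
    respondent_id = rep(sprintf("S%03d", seq_len(n)), each = 2),
    arm = rep(rep(c("CAPI", "PAPI"), c(length(diff_capi), length(diff_papi))),
              each = 2),
    source = rep(c("WFR", "R24"), n),
    value = as.vector(rbind(base, base - d)),
    stringsAsFactors = FALSE)
}
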
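# Nutrient panel: 10 nutrients per 100 g, column names shared by the FCT
# (foods.csv), computed recipe densities and daily intake tables.

.NUTRIENTS <- c(
  energy_kcal  = "energy (kcal)",
  fat_g        = "fat (g)",
  protein_g    = "protein (g)",
  carb_g       = "carbohydrate (g)",
  fibre_g      = "fibre (g)",
  vita_mcg_rae = "vitamin A (mcg RAE)",
  vitc_mg      = "vitamin C (mg)",
  ca_mg        = "calcium (mg)",
  fe_mg        = "iron (mg)",
  zn_mg        = "zinc (mg)"
)

.KJ_PER_KCAL <- 4.184

#' Nutrient panel used throughout the package
#'
#' The ten nutrients on which intakes are compared: energy, fat, protein,
#' carbohydrate, fibre, vitamin A, vitamin C, calcium, iron and zinc.
#'
#' @param labels if `TRUE`, return human-readable labels named by column name;
#'   otherwise the bare column names used in the FCT and intake tables.
#' @return character vector of length 10.
#' @export
#' @examples
#' recall_nutrients()
recall_nutrients <- function(labels = FALSE) {
  if (labels) .NUTRIENTS else names(.NUTRIENTS)
}

#' Convert energy between kilocalories and kilojoules
#'
#' Energy is stored internally in kcal; the kJ view is derived at
#' 4.184 kJ/kcal (thermochemical calorie).
#'
#' @param x numeric energy values.
#' @return numeric vector of the same length.
#' @export
#' @examples
#' kcal_to_kj(500)   # 2092
#' kj_to_kcal(20920) # 5000
kcal_to_kj <- function(x) x * .KJ_PER_KCAL

#' @rdname kcal_to_kj
#' @export
kj_to_kcal <- function(x) x / .KJ_PER_KCAL

# missing-flag column names paired with the nutrient columns
.miss_cols <- function() paste0("miss_", recall_nutrients())
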
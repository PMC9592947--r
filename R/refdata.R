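# Dietary reference bundle: food list + food composition table (per 100 g),
# standard recipes, portion-size conversion factors and the FAO/WHO GIFT
# food-group map. Blank composition cells are carried as NA (missing), never
# coerced to zero: missingness is reported via fct_completeness() and missing
# values contribute 0 to intake sums while setting a per-nutrient flag.

.PSEM_CODES <- c("direct_weight", "photo", "proxy_playdough", "proxy_sorghum",
                 "proxy_water", "standard_unit")

# PAPI paper-form sentinels for "not found in the food/recipe book"; they must
# be resolved to real codes upstream and are rejected at load.
.SENTINEL_CODES <- c("9999", "99 999", "99999")

.bundle_schemas <- list(
  foods = c("food_code", "name", "gift_group", recall_nutrients()),
  recipes = c("recipe_code", "food_code", "ingredient_g"),
  recipe_meta = c("recipe_code", "total_prepared_g"), # + optional gift_group
  portion_factors = c("psem_code", "unit_code", "size_label", "grams_per_unit"),
  groups = c("gift_group", "label")
)

# foods.csv header uses schema names energy_kcal..zn_mg directly
.read_ref_csv <- function(path, table, numeric_cols) {
  if (!file.exists(path)) stop("reference file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                        fileEncoding = "UTF-8", strip.white = TRUE)
  required <- .bundle_schemas[[table]]  # recipe_meta$gift_group stays optional
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("%s: line %d, column '%s': cannot parse '%s' as a number",
                   basename(path), bad[1] + 1L, col, raw[bad[1]]), call. = FALSE)
    }
    val[!nzchar(raw)] <- NA_real_  # blank cell -> missing, not zero
    df[[col]] <- val
  }
  df
}

.check_unique <- function(keys, what, file) {
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    stop(sprintf("%s: duplicate %s: %s", file, what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
}

.check_sentinels <- function(codes, file) {
  hit <- intersect(unique(codes), .SENTINEL_CODES)
  if (length(hit)) {
    stop(sprintf("%s: unresolved sentinel code(s) %s; resolve to real codes before loading",
                 file, paste(shQuote(hit), collapse = ", ")), call. = FALSE)
  }
}

#' Load a dietary reference bundle from CSV tables
#'
#' Reads the five tables that make up the dietary reference data: the food
#' list with its food composition table (nutrients per 100 g), standard
#' recipes (ingredient grams as used plus total prepared weight), portion-size
#' conversion factors for the portion size estimation methods (PSEM), and the
#' FAO/WHO GIFT food-group map.
#'
#' Blank composition cells become `NA` (missing) and are tracked separately
#' from zeros. Duplicate keys, unparseable numeric cells and the pen-and-paper
#' sentinel codes `"9999"` / `"99 999"` are rejected with an error naming the
#' file and offending key or cell.
#'
#' @param dir directory containing `foods.csv`, `recipes.csv`,
#'   `recipe_meta.csv`, `portion_factors.csv` and `groups.csv`; ignored when
#'   `paths` is given.
#' @param paths optional named list/character vector with elements `foods`,
#'   `recipes`, `recipe_meta`, `portion_factors`, `groups` giving each file's
#'   location.
#' @return an object of class `reference_bundle`: a list with data frames
#'   `foods`, `recipes`, `recipe_meta`, `portion_factors`, `groups`.
#' @seealso [validate_refdata()], [write_reference_bundle()],
#'   [fct_completeness()]
#' @export
load_reference_bundle <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- file.path(dir, paste0(names(.bundle_schemas), ".csv"))
    names(paths) <- names(.bundle_schemas)
  }
  foods <- .read_ref_csv(paths[["foods"]], "foods", recall_nutrients())
  recipes <- .read_ref_csv(paths[["recipes"]], "recipes", "ingredient_g")
  recipe_meta <- .read_ref_csv(paths[["recipe_meta"]], "recipe_meta",
                               "total_prepared_g")
  portion_factors <- .read_ref_csv(paths[["portion_factors"]], "portion_factors",
                                   "grams_per_unit")
  groups <- .read_ref_csv(paths[["groups"]], "groups", character())

  .check_unique(foods$food_code, "food_code", "foods.csv")
  .check_sentinels(foods$food_code, "foods.csv")
  .check_unique(recipe_meta$recipe_code, "recipe_code", "recipe_meta.csv")
  .check_sentinels(recipe_meta$recipe_code, "recipe_meta.csv")
  .check_unique(groups$gift_group, "gift_group", "groups.csv")
  key <- interaction(portion_factors$psem_code, portion_factors$unit_code,
                     portion_factors$size_label, drop = TRUE)
  .check_unique(as.character(key), "(psem_code, unit_code, size_label)",
                "portion_factors.csv")

  bad_psem <- setdiff(unique(portion_factors$psem_code), .PSEM_CODES)
  if (length(bad_psem)) {
    stop("portion_factors.csv: unknown psem_code(s): ",
         paste(bad_psem, collapse = ", "), call. = FALSE)
  }
  if (!"gift_group" %in% names(recipe_meta)) recipe_meta$gift_group <- NA_character_

  new_reference_bundle(foods, recipes, recipe_meta, portion_factors, groups)
}

#' Construct a reference bundle from in-memory tables
#'
#' @param foods,recipes,recipe_meta,portion_factors,groups data frames
#'   following the CSV schemas of [load_reference_bundle()].
#' @return a `reference_bundle` object.
#' @export
new_reference_bundle <- function(foods, recipes, recipe_meta, portion_factors,
                                 groups) {
  if (!"gift_group" %in% names(recipe_meta)) recipe_meta$gift_group <- NA_character_
  b <- structure(
    list(foods = foods, recipes = recipes, recipe_meta = recipe_meta,
         portion_factors = portion_factors, groups = groups),
    class = "reference_bundle")
  b
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("<reference_bundle>\n")
  cat(sprintf("  foods: %d  recipes: %d  portion factors: %d  GIFT groups: %d\n",
              nrow(x$foods), nrow(x$recipe_meta), nrow(x$portion_factors),
              nrow(x$groups)))
  nv <- colSums(is.na(x$foods[recall_nutrients()]))
  if (any(nv > 0)) {
    cat("  missing FCT cells:",
        paste(sprintf("%s=%d", names(nv[nv > 0]), nv[nv > 0]), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write a reference bundle back to its CSV tables
#'
#' Inverse of [load_reference_bundle()]: `load(write(b))` round-trips
#' losslessly (missing composition cells are written as blank).
#'
#' @param bundle a `reference_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "reference_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tbl in names(.bundle_schemas)) {
    df <- bundle[[tbl]]
    if (tbl == "recipe_meta" && all(is.na(df$gift_group))) df$gift_group <- NULL
    utils::write.csv(df, file.path(dir, paste0(tbl, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(dir)
}

#' Check referential integrity of a reference bundle
#'
#' Verifies that every recipe ingredient resolves in the food list, every
#' GIFT group code used by a food or recipe is present in the group map,
#' every recipe has exactly one meta row with a positive total prepared
#' weight, ingredient grams and grams-per-unit factors are positive.
#'
#' Violations are returned, not raised, so a bundle can be repaired
#' interactively; an empty result means the bundle is internally consistent.
#'
#' @param bundle a `reference_bundle`.
#' @return data frame with columns `kind`, `key` (the offending code or
#'   value) and `referenced_by` (the object that points at it); zero rows if
#'   the bundle is consistent.
#' @export
validate_refdata <- function(bundle) {
  stopifnot(inherits(bundle, "reference_bundle"))
  v <- list()
  add <- function(kind, key, ref) {
    v[[length(v) + 1L]] <<- data.frame(kind = kind, key = as.character(key),
                                       referenced_by = as.character(ref))
  }
  foods <- bundle$foods; recipes <- bundle$recipes
  meta <- bundle$recipe_meta; groups <- bundle$groups

  dangling <- !(recipes$food_code %in% foods$food_code)
  for (i in which(dangling)) {
    add("dangling_ingredient", recipes$food_code[i], recipes$recipe_code[i])
  }
  bad_grp <- !(foods$gift_group %in% groups$gift_group)
  for (i in which(bad_grp)) add("unknown_group", foods$gift_group[i], foods$food_code[i])
  known_meta_grp <- !is.na(meta$gift_group)
  bad_rgrp <- known_meta_grp & !(meta$gift_group %in% groups$gift_group)
  for (i in which(bad_rgrp)) add("unknown_group", meta$gift_group[i], meta$recipe_code[i])

  no_meta <- setdiff(unique(recipes$recipe_code), meta$recipe_code)
  for (k in no_meta) add("missing_recipe_meta", k, k)
  orphan <- setdiff(meta$recipe_code, unique(recipes$recipe_code))
  for (k in orphan) add("recipe_without_ingredients", k, k)

  for (i in which(!is.na(meta$total_prepared_g) & meta$total_prepared_g <= 0)) {
    add("nonpositive_quantity", meta$total_prepared_g[i], meta$recipe_code[i])
  }
  for (i in which(!is.na(recipes$ingredient_g) & recipes$ingredient_g <= 0)) {
    add("nonpositive_quantity", recipes$ingredient_g[i], recipes$recipe_code[i])
  }
  pf <- bundle$portion_factors
  for (i in which(!is.na(pf$grams_per_unit) & pf$grams_per_unit <= 0)) {
    add("nonpositive_quantity", pf$grams_per_unit[i],
        paste(pf$psem_code[i], pf$unit_code[i], pf$size_label[i], sep = "/"))
  }
  if (!length(v)) {
    return(data.frame(kind = character(), key = character(),
                      referenced_by = character()))
  }
  do.call(rbind, v)
}

#' Food composition table completeness for a set of consumed foods
#'
#' For each nutrient, the percentage of the consumed food codes whose FCT
#' entry carries a non-missing value. Reported alongside validation results
#' so readers can judge how much of each nutrient comparison rests on
#' complete composition data.
#'
#' @param bundle a `reference_bundle`.
#' @param consumed_codes character vector of food codes actually reported
#'   (duplicates are ignored; completeness is over distinct foods).
#' @return named numeric vector (one element per nutrient), values in
#'   `[0, 100]`.
#' @export
#' @examples
#' b <- generate_reference_bundle(sim_config(menu_size = 10, seed = 1))
#' fct_completeness(b, b$foods$food_code)
fct_completeness <- function(bundle, consumed_codes) {
  stopifnot(inherits(bundle, "reference_bundle"))
  codes <- unique(as.character(consumed_codes))
  if (!length(codes)) stop("consumed_codes is empty", call. = FALSE)
  unknown <- setdiff(codes, bundle$foods$food_code)
  if (length(unknown)) {
    stop("unknown food code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  comp <- bundle$foods[match(codes, bundle$foods$food_code), recall_nutrients(),
                       drop = FALSE]
  100 * colSums(!is.na(comp)) / length(codes)
}
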
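# Conversion of coded consumption records into gram amounts, nutrient
# intakes, item counts and per-GIFT-group energy, per respondent and source
# (WFR benchmark day vs 24HR recall day).
#
# Missing-value convention: an FCT cell that is missing contributes 0 to any
# sum it enters and raises the corresponding miss_<nutrient> flag; the flag
# propagates from food to recipe density to daily total.

.RECORD_COLS <- c("respondent_id", "arm", "source", "item_type", "code",
                  "grams", "psem_code", "unit_code", "size_label", "n_units")

#' Convert a portion quantity specification to grams
#'
#' A quantity is either a directly weighed/reported gram amount, or a portion
#' size estimation method (PSEM) reference: the consumed number of units
#' (possibly fractional, e.g. half a bottle) of a `(psem_code, unit_code,
#' size_label)` entry in the portion-factor table.
#'
#' @param quantity a list with either element `grams` (> 0), or elements
#'   `psem_code`, `unit_code`, `size_label`, `n_units` (> 0).
#' @param factors the `portion_factors` data frame of a
#'   [reference bundle][load_reference_bundle].
#' @return gram amount (positive scalar).
#' @export
#' @examples
#' pf <- data.frame(psem_code = "standard_unit", unit_code = "bottle",
#'                  size_label = "small", grams_per_unit = 300)
#' portion_to_grams(list(grams = 250), pf)
#' portion_to_grams(list(psem_code = "standard_unit", unit_code = "bottle",
#'                       size_label = "small", n_units = 0.5), pf)
portion_to_grams <- function(quantity, factors) {
  has_g <- !is.null(quantity$grams) && !is.na(quantity$grams)
  has_psem <- !is.null(quantity$psem_code) && !is.na(quantity$psem_code)
  if (has_g == has_psem) {
    stop("exactly one of 'grams' or the PSEM quadruple must be given",
         call. = FALSE)
  }
  if (has_g) {
    if (quantity$grams <= 0) stop("grams must be > 0", call. = FALSE)
    return(as.numeric(quantity$grams))
  }
  if (is.na(quantity$n_units) || quantity$n_units <= 0) {
    stop("n_units must be > 0", call. = FALSE)
  }
  hit <- factors$psem_code == quantity$psem_code &
    factors$unit_code == quantity$unit_code &
    factors$size_label == quantity$size_label
  if (!any(hit)) {
    stop(sprintf("no portion factor for (%s, %s, %s)", quantity$psem_code,
                 quantity$unit_code, quantity$size_label), call. = FALSE)
  }
  factors$grams_per_unit[which(hit)[1]] * quantity$n_units
}

# Vectorised gram resolution over a records data frame.
.records_grams <- function(records, factors) {
  g <- records$grams
  need <- is.na(g)
  if (any(need)) {
    key_rec <- paste(records$psem_code[need], records$unit_code[need],
                     records$size_label[need], sep = "\r")
    key_fac <- paste(factors$psem_code, factors$unit_code, factors$size_label,
                     sep = "\r")
    idx <- match(key_rec, key_fac)
    if (anyNA(idx)) {
      miss <- which(need)[which(is.na(idx))[1]]
      stop(sprintf("no portion factor for (%s, %s, %s) [respondent %s, code %s]",
                   records$psem_code[miss], records$unit_code[miss],
                   records$size_label[miss], records$respondent_id[miss],
                   records$code[miss]), call. = FALSE)
    }
    g[need] <- factors$grams_per_unit[idx] * records$n_units[need]
  }
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("resolved gram amounts must be positive and finite", call. = FALSE)
  }
  g
}

#' Nutrient density per 100 g of a prepared recipe
#'
#' Sums each ingredient's contribution (`ingredient_g` x composition / 100)
#' and rescales to 100 g of prepared dish. Nutrients are conserved: no
#' cooking losses or retention factors are applied, so density x
#' `total_prepared_g` / 100 equals the sum of raw-ingredient contributions.
#' A nutrient missing for any contributing ingredient adds 0 and flags the
#' output nutrient as missing.
#'
#' Works identically for standard recipes and for non-standard recipes
#' described inline by the respondent.
#'
#' @param ingredients data frame with columns `food_code`, `ingredient_g`
#'   (grams of each ingredient as used).
#' @param total_prepared_g total prepared weight of the dish (> 0).
#' @param foods the `foods` table of a reference bundle.
#' @return list with `density` (named numeric, per 100 g prepared) and
#'   `missing` (named logical).
#' @export
resolve_recipe_density <- function(ingredients, total_prepared_g, foods) {
  if (is.na(total_prepared_g) || total_prepared_g <= 0) {
    stop("total_prepared_g must be > 0", call. = FALSE)
  }
  if (!nrow(ingredients)) stop("recipe has no ingredients", call. = FALSE)
  if (any(is.na(ingredients$ingredient_g) | ingredients$ingredient_g <= 0)) {
    stop("ingredient grams must be > 0", call. = FALSE)
  }
  idx <- match(ingredients$food_code, foods$food_code)
  if (anyNA(idx)) {
    stop("recipe ingredient not in food list: ",
         paste(ingredients$food_code[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  comp <- as.matrix(foods[idx, recall_nutrients(), drop = FALSE])
  miss <- is.na(comp)
  comp[miss] <- 0
  contrib <- ingredients$ingredient_g * comp / 100
  density <- 100 * colSums(contrib) / total_prepared_g
  list(density = density, missing = apply(miss, 2, any))
}

# Build a density lookup for every resolvable code: foods, standard recipes
# and (optionally) per-dataset non-standard recipes. Returns a list with a
# density matrix, a missing-flag matrix (rownames = code) and a gift group
# per code.
.density_table <- function(bundle, nsr = NULL) {
  foods <- bundle$foods
  comp <- as.matrix(foods[, recall_nutrients(), drop = FALSE])
  miss <- is.na(comp)
  comp[miss] <- 0
  codes <- foods$food_code
  grp <- foods$gift_group

  resolve_set <- function(ingredients, meta) {
    dens <- matrix(0, nrow(meta), length(recall_nutrients()),
                   dimnames = list(meta$recipe_code, recall_nutrients()))
    mis <- dens > 1
    g <- character(nrow(meta))
    for (i in seq_len(nrow(meta))) {
      ing <- ingredients[ingredients$recipe_code == meta$recipe_code[i], ,
                         drop = FALSE]
      r <- resolve_recipe_density(ing, meta$total_prepared_g[i], foods)
      dens[i, ] <- r$density
      mis[i, ] <- r$missing
      g[i] <- if (!is.null(meta$gift_group) && !is.na(meta$gift_group[i])) {
        meta$gift_group[i]
      } else {
        # dish-level GIFT group defaults to the dominant-energy ingredient
        idx <- match(ing$food_code, foods$food_code)
        en <- ing$ingredient_g * ifelse(is.na(foods[[recall_nutrients()[1]]][idx]),
                                        0, foods[[recall_nutrients()[1]]][idx])
        foods$gift_group[idx[which.max(en)]]
      }
    }
    list(dens = dens, mis = mis, grp = g)
  }

  if (nrow(bundle$recipe_meta)) {
    r <- resolve_set(bundle$recipes, bundle$recipe_meta)
    comp <- rbind(comp, r$dens); miss <- rbind(miss, r$mis)
    codes <- c(codes, bundle$recipe_meta$recipe_code); grp <- c(grp, r$grp)
  }
  if (!is.null(nsr) && nrow(nsr$meta)) {
    r <- resolve_set(nsr$ingredients, nsr$meta)
    comp <- rbind(comp, r$dens); miss <- rbind(miss, r$mis)
    codes <- c(codes, nsr$meta$recipe_code); grp <- c(grp, r$grp)
  }
  rownames(comp) <- codes
  rownames(miss) <- codes
  list(density = comp, missing = miss, gift_group = stats::setNames(grp, codes))
}

#' Grams and nutrients contributed by a single consumption record
#'
#' @param record one-row data frame (or list) following the records schema:
#'   `respondent_id, arm, source, item_type, code, grams, psem_code,
#'   unit_code, size_label, n_units`.
#' @param bundle a `reference_bundle`.
#' @param nsr optional non-standard recipe detail: a list with data frames
#'   `ingredients` (`recipe_code, food_code, ingredient_g`) and `meta`
#'   (`recipe_code, total_prepared_g[, gift_group]`) keyed by the record's
#'   `code`.
#' @return list with `grams`, `nutrients` (named numeric; missing components
#'   contribute 0), `missing` (named logical) and `gift_group`.
#' @export
item_nutrients <- function(record, bundle, nsr = NULL) {
  record <- as.data.frame(record, stringsAsFactors = FALSE)
  dt <- .density_table(bundle, nsr)
  if (!record$code %in% rownames(dt$density)) {
    stop(sprintf("respondent %s: unresolvable code '%s'",
                 record$respondent_id, record$code), call. = FALSE)
  }
  g <- .records_grams(record, bundle$portion_factors)
  dens <- dt$density[record$code, ]
  list(grams = g,
       nutrients = g * dens / 100,
       missing = dt$missing[record$code, ],
       gift_group = unname(dt$gift_group[record$code]))
}

#' Daily intakes per respondent and source
#'
#' Aggregates consumption records into one row per `(respondent_id, source)`:
#' total grams, item count, the 10-nutrient daily total (with per-nutrient
#' missing-data flags) and energy by FAO/WHO GIFT food group. A mixed dish's
#' whole energy is attributed to the dish's own GIFT group, not disaggregated
#' to its ingredients.
#'
#' @param records data frame following the records schema (see
#'   [read_consumption_records()]); exactly one of `grams` or the PSEM
#'   quadruple must be populated per row.
#' @param bundle a `reference_bundle`.
#' @param nsr optional non-standard recipe detail (see [item_nutrients()]).
#' @return an object of class `intake_table`: list with `intakes` (one row
#'   per respondent x source: `respondent_id, arm, source, gram_total,
#'   item_count`, nutrient columns, `miss_*` flags) and `group_energy`
#'   (long data frame `respondent_id, source, gift_group, energy_kcal`).
#' @export
daily_intakes <- function(records, bundle, nsr = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.RECORD_COLS, names(records))
  if (length(missing_cols)) {
    stop("records: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(records)) stop("no consumption records", call. = FALSE)
  arm_per_resp <- tapply(records$arm, records$respondent_id,
                         function(a) length(unique(a)))
  if (any(arm_per_resp > 1)) {
    stop("respondent(s) with records in both arms: ",
         paste(names(arm_per_resp)[arm_per_resp > 1], collapse = ", "),
         call. = FALSE)
  }
  has_g <- !is.na(records$grams)
  has_psem <- !is.na(records$psem_code)
  if (any(has_g == has_psem)) {
    stop("records: exactly one of grams or the PSEM quadruple must be set (rows ",
         paste(utils::head(which(has_g == has_psem), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  .check_sentinels(records$code, "records")

  dt <- .density_table(bundle, nsr)
  hit <- match(records$code, rownames(dt$density))
  if (anyNA(hit)) {
    i <- which(is.na(hit))[1]
    stop(sprintf("respondent %s (%s): unresolvable code '%s'",
                 records$respondent_id[i], records$source[i], records$code[i]),
         call. = FALSE)
  }
  g <- .records_grams(records, bundle$portion_factors)
  nut <- (g / 100) * dt$density[hit, , drop = FALSE]
  mis <- dt$missing[hit, , drop = FALSE]
  grp <- dt$gift_group[hit]

  key <- paste(records$respondent_id, records$source, sep = "\r")
  ord <- !duplicated(key)
  nut_sum <- rowsum(nut, key, reorder = FALSE)
  mis_sum <- rowsum(mis + 0, key, reorder = FALSE) > 0
  gram_total <- rowsum(g, key, reorder = FALSE)[, 1]
  item_count <- as.integer(rowsum(rep(1L, length(g)), key, reorder = FALSE)[, 1])

  intakes <- data.frame(
    respondent_id = records$respondent_id[ord],
    arm = records$arm[ord],
    source = records$source[ord],
    gram_total = gram_total,
    item_count = item_count,
    stringsAsFactors = FALSE
  )
  intakes <- cbind(intakes, as.data.frame(nut_sum),
                   stats::setNames(as.data.frame(mis_sum), .miss_cols()))
  rownames(intakes) <- NULL

  gkey <- paste(key, grp, sep = "\r")
  gfirst <- !duplicated(gkey)
  ge <- rowsum(nut[, "energy_kcal"], gkey, reorder = FALSE)[, 1]
  group_energy <- data.frame(
    respondent_id = records$respondent_id[gfirst],
    source = records$source[gfirst],
    gift_group = unname(grp[gfirst]),
    energy_kcal = unname(ge),
    stringsAsFactors = FALSE
  )
  structure(list(intakes = intakes, group_energy = group_energy),
            class = "intake_table")
}

#' @export
print.intake_table <- function(x, ...) {
  cat("<intake_table>\n")
  cat(sprintf("  %d respondent-days (%d respondents), sources: %s\n",
              nrow(x$intakes), length(unique(x$intakes$respondent_id)),
              paste(sort(unique(x$intakes$source)), collapse = ", ")))
  invisible(x)
}

#' Percentage of daily energy from each GIFT food group
#'
#' @param intake an `intake_table` (all rows) or its `group_energy` subset.
#' @return data frame `respondent_id, source, gift_group, share` with shares
#'   in percent summing to 100 within each respondent-day.
#' @export
food_group_energy_shares <- function(intake) {
  ge <- if (inherits(intake, "intake_table")) intake$group_energy else intake
  key <- paste(ge$respondent_id, ge$source, sep = "\r")
  tot <- tapply(ge$energy_kcal, key, sum)
  if (any(tot <= 0)) {
    bad <- strsplit(names(tot)[tot <= 0][1], "\r")[[1]]
    stop(sprintf("zero-energy day for respondent %s (%s): shares undefined",
                 bad[1], bad[2]), call. = FALSE)
  }
  data.frame(respondent_id = ge$respondent_id, source = ge$source,
             gift_group = ge$gift_group,
             share = 100 * ge$energy_kcal / as.numeric(tot[key]),
             stringsAsFactors = FALSE)
}

#' Read and write consumption records
#'
#' `records.csv` has one row per consumed item:
#' `respondent_id, arm, source, item_type, code, grams, psem_code, unit_code,
#' size_label, n_units`, with exactly one of `grams` or the PSEM quadruple
#' populated per row. `arm` is `CAPI`/`PAPI`; `source` is `WFR`/`R24`;
#' `item_type` is `food`, `standard_recipe` or `nonstandard_recipe`.
#'
#' @param path CSV file.
#' @return data frame following the records schema.
#' @export
read_consumption_records <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8",
                        strip.white = TRUE)
  missing_cols <- setdiff(.RECORD_COLS, names(df))
  if (length(missing_cols)) {
    stop("records.csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("grams", "n_units")) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("records.csv: line %d, column '%s': cannot parse '%s'",
                   bad[1] + 1L, col, raw[bad[1]]), call. = FALSE)
    }
    val[!nzchar(raw)] <- NA_real_
    df[[col]] <- val
  }
  for (col in c("psem_code", "unit_code", "size_label")) {
    df[[col]][!nzchar(df[[col]])] <- NA_character_
  }
  df
}

#' @rdname read_consumption_records
#' @param records data frame of consumption records.
#' @export
write_consumption_records <- function(records, path) {
  utils::write.csv(records[, .RECORD_COLS], path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an intake table to CSV
#'
#' @param intake an `intake_table`.
#' @param path output CSV for the per-respondent-day table; the group-energy
#'   table is written alongside with suffix `_groups`.
#' @export
write_intake_table <- function(intake, path) {
  stopifnot(inherits(intake, "intake_table"))
  utils::write.csv(intake$intakes, path, row.names = FALSE)
  gpath <- sub("(\\.[^.]+)?$", "_groups\\1", path)
  utils::write.csv(intake$group_energy, gpath, row.names = FALSE)
  invisible(path)
}
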
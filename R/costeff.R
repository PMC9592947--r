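# Activity- and ingredients-based costing of the two survey modalities,
# accuracy of each recall modality against the WFR on group means, and
# cost per percentage point of accuracy under reference-data-borrowing
# scenarios.

.ACTIVITIES <- c("reference_data_prep", "survey_prep", "training",
                 "survey_execution", "data_entry", "cleaning_processing")

#' Read a cost ledger from CSV
#'
#' `costs.csv` has one row per modality x activity x input: columns
#' `modality` (`CAPI`/`PAPI`), `activity`, `category` (`time` in person-days
#' or `non_time`), `quantity`, `unit`, `unit_value` (currency per unit; a
#' wage rate for time rows, respondent time at the minimum wage), and
#' `whose_time`.
#'
#' @param path CSV file.
#' @export
read_cost_ledger <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("modality", "activity", "category", "quantity", "unit_value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("costs.csv: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Total, time and non-time costs per modality
#'
#' Sums `quantity * unit_value` within modality, split into time cost
#' (person-days valued at wages) and non-time monetary cost, with total
#' person-days tallied separately. The partition `total = time + non_time`
#' holds by construction.
#'
#' @param ledger cost ledger data frame (see [read_cost_ledger()]).
#' @return list with `summary` (one row per modality: `person_days`,
#'   `time_cost`, `non_time_cost`, `total_cost`) and `by_activity`
#'   (modality x activity x category subtotals).
#' @export
total_costs <- function(ledger) {
  if (!nrow(ledger)) stop("empty cost ledger", call. = FALSE)
  if (any(ledger$quantity < 0)) stop("negative quantity in ledger", call. = FALSE)
  ledger$cost <- ledger$quantity * ledger$unit_value
  by_act <- stats::aggregate(
    cbind(quantity, cost) ~ modality + activity + category, data = ledger,
    FUN = sum)
  mods <- sort(unique(ledger$modality))
  rows <- lapply(mods, function(m) {
    sub <- ledger[ledger$modality == m, ]
    tc <- sum(sub$cost[sub$category == "time"])
    nt <- sum(sub$cost[sub$category == "non_time"])
    data.frame(modality = m,
               person_days = sum(sub$quantity[sub$category == "time"]),
               time_cost = tc, non_time_cost = nt, total_cost = tc + nt,
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), by_activity = by_act)
}

#' Group-level percentage error and accuracy of a recall mean
#'
#' Error is the absolute relative deviation of the *ratio of group means*
#' (not the mean of individual errors): `100 |1 - mean_24hr / mean_wfr|`,
#' capped at 100 so accuracy (`100 - error`) stays non-negative and
#' cost-per-accuracy-point ratios stay defined.
#'
#' @param mean_24hr,mean_wfr group means of the same outcome under the
#'   recall and the WFR benchmark; `mean_wfr` must be positive.
#' @return named numeric vector `c(error, accuracy)` in percent.
#' @export
#' @examples
#' group_accuracy(3500, 4000)  # error 12.5, accuracy 87.5
group_accuracy <- function(mean_24hr, mean_wfr) {
  if (is.na(mean_wfr) || mean_wfr <= 0) {
    stop("mean_wfr must be > 0", call. = FALSE)
  }
  err <- min(100, 100 * abs(1 - mean_24hr / mean_wfr))
  c(error = err, accuracy = 100 - err)
}

#' Composite nutrient accuracy
#'
#' Arithmetic mean of the ten per-nutrient group-level accuracies.
#'
#' @param accuracies named numeric vector containing an accuracy for each
#'   nutrient of [recall_nutrients()].
#' @return scalar percentage.
#' @export
composite_nutrient_accuracy <- function(accuracies) {
  missing_n <- setdiff(recall_nutrients(), names(accuracies))
  if (length(missing_n)) {
    stop("missing per-nutrient accuracy for: ",
         paste(missing_n, collapse = ", "), call. = FALSE)
  }
  mean(accuracies[recall_nutrients()])
}

#' The three accuracy measures of a recall modality, from an intake table
#'
#' Group means of item count, total grams and each nutrient are formed over
#' the respondents of the given arm (each mean over its source's rows), and
#' turned into percentage accuracies with [group_accuracy()]; the composite
#' is the mean of the ten per-nutrient accuracies.
#'
#' @param intake an `intake_table` (after QC exclusions).
#' @param arm which arm's respondents to use (`"CAPI"` or `"PAPI"`).
#' @return list with `item_count`, `gram`, `per_nutrient` (named vector of
#'   10), `composite`.
#' @export
accuracy_measures <- function(intake, arm) {
  stopifnot(inherits(intake, "intake_table"))
  it <- intake$intakes[intake$intakes$arm == arm, ]
  if (!nrow(it)) stop("no rows for arm ", arm, call. = FALSE)
  w <- it[it$source == "WFR", ]; r <- it[it$source == "R24", ]
  acc <- function(col) group_accuracy(mean(r[[col]]), mean(w[[col]]))[["accuracy"]]
  per_nut <- vapply(recall_nutrients(), acc, numeric(1))
  list(item_count = acc("item_count"),
       gram = acc("gram_total"),
       per_nutrient = per_nut,
       composite = composite_nutrient_accuracy(per_nut))
}

#' Cost per percentage point of accuracy
#'
#' Each cost aggregate (total cost, person-days, time cost, non-time cost)
#' divided by each of the three primary accuracy measures.
#'
#' @param cost_row one modality's row of `total_costs()$summary`.
#' @param accuracy output of [accuracy_measures()] for the same modality.
#' @return data frame: one row per accuracy measure with columns for each
#'   cost-per-point ratio.
#' @export
cost_effectiveness <- function(cost_row, accuracy) {
  meas <- c(item_count = accuracy$item_count, gram = accuracy$gram,
            composite_nutrient = accuracy$composite)
  if (any(meas <= 0)) {
    stop("zero accuracy: cost per accuracy point undefined", call. = FALSE)
  }
  data.frame(
    modality = cost_row$modality,
    measure = names(meas),
    accuracy = unname(meas),
    total_cost_per_point = cost_row$total_cost / unname(meas),
    person_days_per_point = cost_row$person_days / unname(meas),
    time_cost_per_point = cost_row$time_cost / unname(meas),
    non_time_cost_per_point = cost_row$non_time_cost / unname(meas),
    stringsAsFactors = FALSE)
}

#' Scale reference-data preparation costs under an FMDB-borrowing scenario
#'
#' When a fraction of the dietary reference data (food composition,
#' recipes, conversion factors) is borrowed from a shared repository, the
#' computer-assisted modality's reference-data-preparation quantities shrink
#' by that fraction; the paper modality's ledger is unchanged (its reference
#' data must still be prepared by hand), and accuracy is assumed unchanged.
#'
#' @param ledger cost ledger data frame.
#' @param borrow_fraction fraction in `[0, 1)` of reference data borrowed.
#' @return the modified ledger.
#' @export
apply_borrowing_scenario <- function(ledger, borrow_fraction) {
  if (borrow_fraction < 0 || borrow_fraction >= 1) {
    stop("borrow_fraction must be in [0, 1)", call. = FALSE)
  }
  hit <- ledger$modality == "CAPI" & ledger$activity == "reference_data_prep"
  if (!any(hit)) {
    stop("ledger has no CAPI reference_data_prep rows", call. = FALSE)
  }
  ledger$quantity[hit] <- ledger$quantity[hit] * (1 - borrow_fraction)
  ledger
}

#' Cost-effectiveness across reference-data-borrowing scenarios
#'
#' @param ledger base cost ledger.
#' @param accuracy_by_modality named list (`CAPI`, `PAPI`) of
#'   [accuracy_measures()] outputs.
#' @param fractions borrowing fractions to evaluate.
#' @return object of class `ce_result`: list with `costs` (per scenario x
#'   modality cost summary) and `ratios` (per scenario cost-per-point
#'   table).
#' @export
ce_scenarios <- function(ledger, accuracy_by_modality,
                         fractions = c(0, 0.25, 0.50, 0.75)) {
  costs <- list(); ratios <- list()
  for (f in fractions) {
    led <- apply_borrowing_scenario(ledger, f)
    tc <- total_costs(led)
    lab <- sprintf("borrow_%d", round(100 * f))
    costs[[lab]] <- cbind(scenario = lab, borrow_fraction = f, tc$summary)
    rr <- lapply(tc$summary$modality, function(m) {
      cost_effectiveness(tc$summary[tc$summary$modality == m, ],
                         accuracy_by_modality[[m]])
    })
    ratios[[lab]] <- cbind(scenario = lab, borrow_fraction = f,
                           do.call(rbind, rr))
  }
  out <- list(costs = do.call(rbind, costs), ratios = do.call(rbind, ratios))
  rownames(out$costs) <- rownames(out$ratios) <- NULL
  structure(out, class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("<ce_result>\n")
  base <- x$costs[x$costs$borrow_fraction == min(x$costs$borrow_fraction), ]
  for (i in seq_len(nrow(base))) {
    cat(sprintf("  %s base total cost: %.0f (%.1f person-days)\n",
                base$modality[i], base$total_cost[i], base$person_days[i]))
  }
  cat(sprintf("  scenarios: %s\n",
              paste(unique(x$costs$scenario), collapse = ", ")))
  invisible(x)
}

#' Write cost-effectiveness results to CSV/JSON
#'
#' @param ce a `ce_result`.
#' @param dir output directory.
#' @export
write_ce_result <- function(ce, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(ce$costs, file.path(dir, "costs_by_scenario.csv"),
                   row.names = FALSE)
  utils::write.csv(ce$ratios, file.path(dir, "cost_effectiveness.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(unclass(ce), function(df) df),
                       file.path(dir, "ce_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
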
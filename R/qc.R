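# Energy-implausibility screening before the validation comparison.
#
# Convention (strict inequalities, boundary values pass): a day is flagged
# when energy < 500 kcal (2092 kJ) or > 5000 kcal (20920 kJ); a 24HR day is
# additionally flagged for review when it differs from its paired WFR by
# more than 1000 kcal (4184 kJ) in either direction. Respondents whose WFR
# day is implausible are excluded from the comparison; pair-discrepancy
# flags are logged but the respondents are retained.

.ENERGY_LOW_KCAL <- 500
.ENERGY_HIGH_KCAL <- 5000
.PAIR_DISCREPANCY_KCAL <- 1000

#' Energy plausibility and pair-discrepancy thresholds
#'
#' @param units `"kcal"` or `"kJ"` (derived at 4.184 kJ/kcal).
#' @return named numeric vector with `low`, `high` (daily plausibility
#'   bounds) and `pair_discrepancy` (review threshold on the absolute
#'   24HR-WFR energy difference).
#' @export
#' @examples
#' energy_outlier_bounds("kJ")  # low = 2092, high = 20920
energy_outlier_bounds <- function(units = c("kcal", "kJ")) {
  units <- match.arg(units)
  b <- c(low = .ENERGY_LOW_KCAL, high = .ENERGY_HIGH_KCAL,
         pair_discrepancy = .PAIR_DISCREPANCY_KCAL)
  if (units == "kJ") kcal_to_kj(b) else b
}

#' Flag implausible and discrepant energy intakes
#'
#' Applies the daily plausibility bounds to every respondent-day (both
#' sources) and the pair-discrepancy rule to each 24HR day against its WFR
#' partner. Pairing is mandatory: a 24HR day without a WFR partner is an
#' error.
#'
#' @param intake an `intake_table` from [daily_intakes()].
#' @return data frame of flags: `respondent_id, source, flag_kind
#'   (energy_low / energy_high / pair_discrepancy), value` (the energy, or
#'   the signed pair difference, in kcal); zero rows when nothing is flagged.
#' @export
flag_records <- function(intake) {
  stopifnot(inherits(intake, "intake_table"))
  it <- intake$intakes
  flags <- list()
  add <- function(id, src, kind, val) {
    flags[[length(flags) + 1L]] <<- data.frame(
      respondent_id = id, source = src, flag_kind = kind, value = val,
      stringsAsFactors = FALSE)
  }
  en <- it$energy_kcal
  low <- en < .ENERGY_LOW_KCAL
  high <- en > .ENERGY_HIGH_KCAL
  for (i in which(low)) add(it$respondent_id[i], it$source[i], "energy_low", en[i])
  for (i in which(high)) add(it$respondent_id[i], it$source[i], "energy_high", en[i])

  r24 <- it[it$source == "R24", ]
  wfr <- it[it$source == "WFR", ]
  part <- match(r24$respondent_id, wfr$respondent_id)
  if (anyNA(part)) {
    stop("24HR day without a WFR partner: ",
         paste(r24$respondent_id[is.na(part)], collapse = ", "), call. = FALSE)
  }
  d <- r24$energy_kcal - wfr$energy_kcal[part]
  for (i in which(abs(d) > .PAIR_DISCREPANCY_KCAL)) {
    add(r24$respondent_id[i], "R24", "pair_discrepancy", d[i])
  }
  if (!length(flags)) {
    return(data.frame(respondent_id = character(), source = character(),
                      flag_kind = character(), value = numeric()))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}

#' Exclusion policy for flagged respondents
#'
#' The default reproduces the study convention: a respondent is excluded
#' (both days) when the *WFR* day breaches the plausibility bounds;
#' implausible 24HR-only days and pair discrepancies are logged for review
#' but the respondents are kept in the comparison.
#'
#' @param exclude_kinds flag kinds that trigger exclusion.
#' @param exclude_source source whose flags trigger exclusion.
#' @export
qc_policy <- function(exclude_kinds = c("energy_low", "energy_high"),
                      exclude_source = "WFR") {
  structure(list(exclude_kinds = exclude_kinds,
                 exclude_source = exclude_source), class = "qc_policy")
}

#' Apply an exclusion policy to a flagged intake table
#'
#' @param intake an `intake_table`.
#' @param flags output of [flag_records()].
#' @param policy a [qc_policy()].
#' @return list with `intake` (filtered `intake_table`), `log` (one row per
#'   flag with an `action` column: `exclude` or `retain`) and
#'   `excluded_respondents`.
#' @export
apply_exclusions <- function(intake, flags, policy = qc_policy()) {
  stopifnot(inherits(intake, "intake_table"), inherits(policy, "qc_policy"))
  trigger <- flags$flag_kind %in% policy$exclude_kinds &
    flags$source %in% policy$exclude_source
  excl <- unique(flags$respondent_id[trigger])
  log <- flags
  log$action <- ifelse(trigger, "exclude", "retain")
  keep <- !(intake$intakes$respondent_id %in% excl)
  out <- structure(list(
    intakes = intake$intakes[keep, , drop = FALSE],
    group_energy = intake$group_energy[
      !(intake$group_energy$respondent_id %in% excl), , drop = FALSE]),
    class = "intake_table")
  rownames(out$intakes) <- rownames(out$group_energy) <- NULL
  list(intake = out, log = log, excluded_respondents = excl)
}

#' Skewness-correcting transform for intake vectors
#'
#' Nutrient intakes are right-skewed; comparisons are made on a transformed
#' scale. The natural log is used whenever all values are strictly positive;
#' the cube root (which tolerates zeros, e.g. zero vitamin C days) otherwise.
#'
#' @param values non-negative finite numeric vector.
#' @return list with `transform` (`"log"` or `"cube_root"`) and `values`
#'   (transformed elementwise).
#' @export
#' @examples
#' select_transform(c(1, exp(1)))$transform   # "log"
#' select_transform(c(0, 8))$values           # 0, 2
select_transform <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  if (any(values < 0)) stop("negative intake value", call. = FALSE)
  if (all(values > 0)) {
    list(transform = "log", values = log(values))
  } else {
    list(transform = "cube_root", values = values^(1 / 3))
  }
}

#' Write the QC log to CSV
#'
#' @param log the `log` element of [apply_exclusions()].
#' @param path output file.
#' @export
write_qc_log <- function(log, path) {
  utils::write.csv(log, path, row.names = FALSE)
  invisible(path)
}
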
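# End-to-end orchestration: simulate (or load) -> convert -> qc ->
# validate -> cost-effectiveness -> report, with a manifest that reconciles
# counts at every stage boundary.

#' Run configuration for the full pipeline
#'
#' @param sim a [sim_config()] (synthetic run), or `NULL` when `paths` are
#'   given.
#' @param paths optional named list for a data-driven run: `refdata` (dir
#'   with the bundle CSVs), `records` (records.csv), `costs` (costs.csv).
#' @param policy a [qc_policy()].
#' @param bound_fraction TOST equivalence bound.
#' @param bands error-band edges (percent).
#' @param min_consumer_fraction food-group test suppression threshold.
#' @param design a list of [sample_size_correlation()] arguments recorded
#'   with the run (design-stage parameters).
#' @param scenarios reference-data borrowing fractions.
#' @param output_dir optional directory; when set, every table plus the
#'   manifest and a serialised copy of the configuration are written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), paths = NULL,
                       policy = qc_policy(), bound_fraction = 0.10,
                       bands = c(10, 20, 30, 50),
                       min_consumer_fraction = 0.10,
                       design = list(rho0 = 0.6, rho1 = 0.75, alpha = 0.05,
                                     power = 0.80, inflation = 0.125),
                       scenarios = c(0, 0.25, 0.50, 0.75),
                       output_dir = NULL) {
  stopifnot(is.null(sim) || inherits(sim, "sim_config"))
  if (is.null(sim) && is.null(paths)) {
    stop("either sim or paths must be given", call. = FALSE)
  }
  structure(list(sim = sim, paths = paths, policy = policy,
                 bound_fraction = bound_fraction, bands = bands,
                 min_consumer_fraction = min_consumer_fraction,
                 design = design, scenarios = scenarios,
                 output_dir = output_dir), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file may set any [run_config()] argument; `sim` is given as a mapping
#' of [sim_config()] arguments.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- list()
  if (!is.null(raw$sim)) args$sim <- do.call(sim_config, raw$sim)
  if (!is.null(raw$policy)) args$policy <- do.call(qc_policy, raw$policy)
  for (f in c("paths", "bound_fraction", "bands", "min_consumer_fraction",
              "design", "scenarios", "output_dir")) {
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  }
  do.call(run_config, args)
}

#' Run the full validation and cost-effectiveness pipeline
#'
#' Stages: (1) generate or load the reference bundle, consumption records
#' and cost ledger; (2) convert records to daily intakes; (3) flag and
#' exclude implausible-energy respondents; (4) compute the validation
#' report (equivalence, DiD, error bands, Bland-Altman, food-group shares);
#' (5) compute accuracy measures and cost-effectiveness across borrowing
#' scenarios. Deterministic given the simulation seed.
#'
#' @param config a [run_config()].
#' @return object of class `pipeline_result`: list with `bundle`,
#'   `records`, `intake_raw`, `intake`, `qc` (flags/log/excluded),
#'   `report`, `accuracy`, `ce`, `design` (sample-size calculation) and
#'   `manifest` (stage-boundary counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$sim)) {
    bundle <- generate_reference_bundle(config$sim)
    gen <- generate_paired_records(config$sim, bundle)
    records <- gen$records
    truth <- gen$truth
    ledger <- generate_cost_ledger(config$sim$seed)
  } else {
    bundle <- load_reference_bundle(config$paths$refdata)
    records <- read_consumption_records(config$paths$records)
    truth <- NULL
    ledger <- read_cost_ledger(config$paths$costs)
  }
  viol <- validate_refdata(bundle)
  if (nrow(viol)) {
    stop("stage refdata: bundle has ", nrow(viol), " integrity violation(s); ",
         "first: ", viol$kind[1], " ", viol$key[1], call. = FALSE)
  }

  intake_raw <- daily_intakes(records, bundle)
  flags <- flag_records(intake_raw)
  qc <- apply_exclusions(intake_raw, flags, config$policy)
  report <- validation_report(qc$intake,
                              bound_fraction = config$bound_fraction,
                              bands = config$bands,
                              min_consumer_fraction = config$min_consumer_fraction)
  accuracy <- list(CAPI = accuracy_measures(qc$intake, "CAPI"),
                   PAPI = accuracy_measures(qc$intake, "PAPI"))
  ce <- ce_scenarios(ledger, accuracy, config$scenarios)
  design <- do.call(sample_size_correlation, config$design)

  n_resp <- length(unique(intake_raw$intakes$respondent_id))
  manifest <- list(
    n_respondents_generated = n_resp,
    n_records = nrow(records),
    n_respondent_days = nrow(intake_raw$intakes),
    n_flags = nrow(flags),
    n_excluded = length(qc$excluded_respondents),
    n_analysed = length(unique(qc$intake$intakes$respondent_id)),
    n_analysed_by_arm = as.list(table(
      unique(qc$intake$intakes[c("respondent_id", "arm")])$arm)),
    fct_completeness = as.list(
      fct_completeness(bundle,
                       intersect(records$code, bundle$foods$food_code))),
    seed = if (!is.null(config$sim)) config$sim$seed else NA
  )
  stopifnot(manifest$n_analysed + manifest$n_excluded == n_resp)

  result <- structure(list(bundle = bundle, records = records, truth = truth,
                           intake_raw = intake_raw, intake = qc$intake,
                           qc = qc, report = report, accuracy = accuracy,
                           ce = ce, design = design, manifest = manifest,
                           config = config), class = "pipeline_result")
  if (!is.null(config$output_dir)) write_pipeline_result(result, config$output_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  m <- x$manifest
  cat(sprintf("  respondents: %d generated, %d excluded by QC, %d analysed\n",
              m$n_respondents_generated, m$n_excluded, m$n_analysed))
  print(x$report)
  for (arm in names(x$accuracy)) {
    a <- x$accuracy[[arm]]
    cat(sprintf("  %s accuracy: item %.1f%%, gram %.1f%%, composite %.1f%%\n",
                arm, a$item_count, a$gram, a$composite))
  }
  invisible(x)
}

#' Write every pipeline output table to a directory
#'
#' Emits the intake tables, QC log, validation report tables, cost tables,
#' the run manifest and a serialised copy of the configuration.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_consumption_records(result$records, file.path(dir, "records.csv"))
  if (!is.null(result$truth)) {
    utils::write.csv(result$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  write_intake_table(result$intake_raw, file.path(dir, "intakes.csv"))
  write_qc_log(result$qc$log, file.path(dir, "qc_log.csv"))
  write_validation_report(result$report, dir)
  write_ce_result(result$ce, dir)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  cfg_ser <- list(sim = if (!is.null(cfg$sim)) unclass(cfg$sim),
                  policy = unclass(cfg$policy),
                  bound_fraction = cfg$bound_fraction, bands = cfg$bands,
                  min_consumer_fraction = cfg$min_consumer_fraction,
                  design = cfg$design, scenarios = cfg$scenarios)
  yaml::write_yaml(cfg_ser, file.path(dir, "run_config.yaml"))
  invisible(dir)
}
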
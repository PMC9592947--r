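# Group- and individual-level accuracy statistics for the paired
# WFR / 24HR comparison, plus the design-stage sample-size calculation.

#' Paired two one-sided t-test (TOST) for equivalence on the log scale
#'
#' Equivalence of a recall method with the WFR benchmark at a multiplicative
#' bound: with paired log differences `d_i = ln(24HR_i) - ln(WFR_i)` and
#' symmetric bounds `theta = +/- ln(1 + bound_fraction)`, both one-sided
#' tests (mean d > -theta and mean d < theta) must reject; the reported p is
#' the larger of the two one-sided p-values, and `p < alpha` declares
#' equivalence of the geometric means within the bound.
#'
#' Pairs with a zero on either side cannot enter a log-scale test; they are
#' excluded and tallied in `n_zero_excluded`.
#'
#' @param wfr,r24 paired positive intake vectors (same length/order;
#'   benchmark first).
#' @param bound_fraction equivalence bound as a fraction of the geometric
#'   mean (default 0.10, i.e. bounds of +/- ln(1.1)).
#' @param alpha significance level for the equivalence call.
#' @return object of class `tost_result`: list with `n`, `n_zero_excluded`,
#'   `geomean_wfr`, `geomean_r24`, `mean_log_diff`, `sd_log_diff`, `theta`,
#'   `p_lower`, `p_upper`, `p` (= max), `equivalent`.
#' @export
#' @examples
#' set.seed(1)
#' w <- rlnorm(100, 7, 0.5)
#' tost_equivalence(w, w * rlnorm(100, 0, 0.2))
tost_equivalence <- function(wfr, r24, bound_fraction = 0.10, alpha = 0.05) {
  stopifnot(length(wfr) == length(r24))
  if (any(wfr < 0 | r24 < 0, na.rm = TRUE)) {
    stop("intakes must be non-negative", call. = FALSE)
  }
  ok <- !is.na(wfr) & !is.na(r24) & wfr > 0 & r24 > 0
  n_zero <- sum(!is.na(wfr) & !is.na(r24)) - sum(ok)
  w <- wfr[ok]; r <- r24[ok]
  n <- length(w)
  if (n < 2) stop("need at least 2 positive pairs", call. = FALSE)
  d <- log(r) - log(w)
  dbar <- mean(d); s <- stats::sd(d)
  theta <- log1p(bound_fraction)
  if (s == 0) {
    eq <- abs(dbar) < theta
    p_low <- p_up <- p <- if (eq) 0 else 1
  } else {
    se <- s / sqrt(n)
    p_low <- stats::pt((dbar + theta) / se, n - 1, lower.tail = FALSE)
    p_up <- stats::pt((dbar - theta) / se, n - 1)
    p <- max(p_low, p_up)
    eq <- p < alpha
  }
  structure(list(
    n = n, n_zero_excluded = n_zero,
    geomean_wfr = exp(mean(log(w))), geomean_r24 = exp(mean(log(r))),
    mean_log_diff = dbar, sd_log_diff = s, theta = theta,
    p_lower = p_low, p_upper = p_up, p = p, equivalent = eq,
    bound_fraction = bound_fraction, alpha = alpha), class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf(
    "TOST equivalence (bound %.0f%%): n=%d, GM ratio %.3f, p=%.4g -> %s\n",
    100 * x$bound_fraction, x$n, x$geomean_r24 / x$geomean_wfr, x$p,
    if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `24HR - WFR`, so a positive bias means the
#' recall overestimates the benchmark. Limits of agreement are
#' `bias +/- 1.96 sd`.
#'
#' @param wfr,r24 paired numeric vectors.
#' @return list with `bias`, `sd`, `loa` (lower, upper) and `points`
#'   (data frame of per-pair means and differences, for plotting).
#' @export
bland_altman <- function(wfr, r24) {
  stopifnot(length(wfr) == length(r24))
  ok <- !is.na(wfr) & !is.na(r24)
  w <- wfr[ok]; r <- r24[ok]
  if (length(w) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- r - w
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s,
       loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       points = data.frame(mean = (w + r) / 2, difference = d))
}

#' Difference-in-differences between two recall modalities
#'
#' Each arm contributes per-respondent (WFR - 24HR) differences; the
#' estimate is `mean diff(CAPI) - mean diff(PAPI)`, fitted as the
#' source-by-arm interaction of a random-intercept mixed model on the
#' stacked two-row-per-respondent data (untransformed scale). On balanced
#' complete pairs this interaction test coincides with a pooled two-sample
#' t-test on the per-respondent differences.
#'
#' @param data long data frame with columns `respondent_id`, `arm`
#'   (`CAPI`/`PAPI`), `source` (`WFR`/`R24`) and `value`; one WFR and one
#'   R24 row per respondent, each respondent in exactly one arm.
#' @return list with `estimate` (DiD, benchmark-minuend convention),
#'   `mean_diff_capi`, `mean_diff_papi`, `se`, `df`, `p`.
#' @export
diff_in_differences <- function(data) {
  need <- c("respondent_id", "arm", "source", "value")
  stopifnot(all(need %in% names(data)))
  n_arm <- tapply(data$arm, data$respondent_id, function(a) length(unique(a)))
  if (any(n_arm > 1)) {
    stop("respondent(s) in both arms: ",
         paste(names(n_arm)[n_arm > 1], collapse = ", "), call. = FALSE)
  }
  cnt <- table(data$respondent_id, data$source)
  if (!all(cnt == 1) || !all(c("WFR", "R24") %in% colnames(cnt))) {
    stop("each respondent needs exactly one WFR and one R24 row", call. = FALSE)
  }
  df <- data.frame(
    respondent_id = data$respondent_id,
    arm = factor(data$arm, levels = c("CAPI", "PAPI")),
    source = factor(data$source, levels = c("WFR", "R24")),
    value = data$value)
  wide0 <- stats::reshape(df, idvar = c("respondent_id", "arm"),
                          timevar = "source", direction = "wide")
  d0 <- wide0$value.WFR - wide0$value.R24
  if (stats::sd(d0) == 0) {
    # degenerate: every respondent has the same difference (e.g. noise-free
    # recall); the interaction contrast is exact, no model needed
    est <- mean(d0[wide0$arm == "CAPI"]) - mean(d0[wide0$arm == "PAPI"])
    return(list(estimate = est,
                mean_diff_capi = mean(d0[wide0$arm == "CAPI"]),
                mean_diff_papi = mean(d0[wide0$arm == "PAPI"]),
                se = 0, df = length(d0) - 2,
                p = if (est == 0) 1 else 0))
  }
  fit <- nlme::lme(value ~ source * arm, random = ~ 1 | respondent_id,
                   data = df, method = "REML",
                   control = nlme::lmeControl(tolerance = 1e-10, msTol = 1e-10,
                                              niterEM = 50, returnObject = TRUE))
  tt <- summary(fit)$tTable["sourceR24:armPAPI", ]
  wide <- stats::reshape(df, idvar = c("respondent_id", "arm"),
                         timevar = "source", direction = "wide")
  d <- wide$value.WFR - wide$value.R24
  list(estimate = unname(tt["Value"]),
       mean_diff_capi = mean(d[wide$arm == "CAPI"]),
       mean_diff_papi = mean(d[wide$arm == "PAPI"]),
       se = unname(tt["Std.Error"]), df = unname(tt["DF"]),
       p = unname(tt["p-value"]))
}

#' Individual-level percentage-error bands
#'
#' Percentage error of each respondent's recall against their own WFR,
#' `e_i = 100 (24HR_i - WFR_i) / WFR_i`, tabulated as the cumulative share
#' of respondents within +/-10, 20, 30 and 50% (boundary inclusive), plus
#' the shares overestimating beyond +50% and underestimating beyond -50%.
#'
#' @param wfr,r24 paired vectors; `wfr` must be strictly positive.
#' @param bands increasing positive band edges in percent.
#' @param ids optional respondent identifiers for error messages.
#' @return list with `within` (named cumulative percentages), `over`,
#'   `under`, `n` and the raw `errors`.
#' @export
error_band_table <- function(wfr, r24, bands = c(10, 20, 30, 50),
                             ids = NULL) {
  stopifnot(length(wfr) == length(r24), all(diff(bands) > 0))
  if (any(wfr <= 0)) {
    who <- if (is.null(ids)) which(wfr <= 0) else ids[wfr <= 0]
    stop("zero/negative WFR value for respondent(s): ",
         paste(utils::head(who, 5), collapse = ", "), call. = FALSE)
  }
  e <- 100 * (r24 - wfr) / wfr
  n <- length(e)
  within <- vapply(bands, function(b) 100 * sum(abs(e) <= b) / n, numeric(1))
  names(within) <- paste0("within_", bands)
  wmax <- bands[length(bands)]
  list(within = within,
       over = 100 * sum(e > wmax) / n,
       under = 100 * sum(e < -wmax) / n,
       n = n, errors = e)
}

#' Food-group energy-share comparison between WFR and a recall method
#'
#' For each GIFT group: the median (with quartiles) percentage of daily
#' energy from that group under each method, and a paired Wilcoxon
#' signed-rank test on the within-respondent share differences
#' (zero differences dropped; exact null distribution when at most
#' `exact_max` nonzero untied pairs, normal approximation otherwise).
#' Groups consumed by fewer than `min_consumer_fraction` of respondents
#' under either method keep their medians but have the test suppressed
#' (`reported = FALSE`), since significance tests on so few consumers are
#' unreliable.
#'
#' @param shares long data frame from [food_group_energy_shares()] covering
#'   both sources for one arm.
#' @param min_consumer_fraction suppression threshold (default 0.10).
#' @param exact_max largest number of nonzero pairs for which the exact
#'   signed-rank distribution is used.
#' @return data frame, one row per group: medians/quartiles per method,
#'   consumer fractions, `p`, `p_method`, `reported`.
#' @export
foodgroup_comparison <- function(shares, min_consumer_fraction = 0.10,
                                 exact_max = 25) {
  stopifnot(all(c("respondent_id", "source", "gift_group", "share")
                %in% names(shares)))
  resp <- unique(shares$respondent_id)
  if (!length(resp)) stop("no respondents", call. = FALSE)
  groups <- sort(unique(shares$gift_group))
  get_share <- function(src, grp) {
    sub <- shares[shares$source == src & shares$gift_group == grp, ]
    out <- stats::setNames(rep(0, length(resp)), resp)
    out[sub$respondent_id] <- sub$share  # absent group = 0% share that day
    out
  }
  rows <- lapply(groups, function(grp) {
    w <- get_share("WFR", grp); r <- get_share("R24", grp)
    qs_w <- stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE)
    qs_r <- stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
    frac_w <- mean(w > 0); frac_r <- mean(r > 0)
    d <- r - w
    nz <- sum(d != 0)
    if (nz == 0) {
      p <- NA_real_; pm <- "undefined: all differences zero"
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(r, w, paired = TRUE, exact = nz <= exact_max,
                           correct = TRUE))
      p <- wt$p.value
      pm <- if (nz <= exact_max && !any(duplicated(abs(d[d != 0])))) {
        "exact signed-rank"
      } else "signed-rank, normal approximation"
    }
    reported <- frac_w >= min_consumer_fraction & frac_r >= min_consumer_fraction
    data.frame(gift_group = grp,
               median_wfr = qs_w[2], q25_wfr = qs_w[1], q75_wfr = qs_w[3],
               median_r24 = qs_r[2], q25_r24 = qs_r[1], q75_r24 = qs_r[3],
               consumer_fraction_wfr = frac_w, consumer_fraction_r24 = frac_r,
               p = if (reported) p else NA_real_,
               p_method = if (reported) pm else "suppressed: <10% consumers",
               reported = reported, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sample size for detecting an improvement in correlation (Fisher z)
#'
#' Design-stage calculation: the smallest n per arm for which a two-sided
#' level-`alpha` test of `rho = rho0` attains the target power when the true
#' correlation is `rho1`, via the Fisher z transformation:
#' `n = ceil(((z_{1-alpha/2} + z_{power}) / (atanh(rho1) - atanh(rho0)))^2 + 3)`.
#'
#' @param rho0 correlation regarded as unsatisfactory (null), default 0.6.
#' @param rho1 correlation regarded as a practically important improvement,
#'   default 0.75.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param inflation non-response inflation applied multiplicatively to the
#'   analytic n (reported separately).
#' @return list with `n` (per arm), `n_inflated`, and the inputs.
#' @export
#' @examples
#' sample_size_correlation()$n  # 104
sample_size_correlation <- function(rho0 = 0.6, rho1 = 0.75, alpha = 0.05,
                                    power = 0.80, inflation = 0.125) {
  stopifnot(alpha > 0, alpha < 1, power > 0, power < 1,
            abs(rho0) < 1, abs(rho1) < 1)
  q <- atanh(rho1) - atanh(rho0)
  if (q == 0) stop("rho0 and rho1 must differ", call. = FALSE)
  n <- ceiling(((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / q)^2 + 3)
  list(n = as.integer(n),
       n_inflated = as.integer(ceiling(n * (1 + inflation))),
       rho0 = rho0, rho1 = rho1, alpha = alpha, power = power,
       inflation = inflation)
}

# outcomes compared between sources: item count, total grams, 10 nutrients
.val_outcomes <- function() c("item_count", "gram_total", recall_nutrients())

#' Full validation report for one or both arms
#'
#' Assembles, per arm and outcome (item count, total grams and the ten
#' nutrients): TOST equivalence on the log scale, Bland-Altman agreement,
#' individual-level error bands; across arms a difference-in-differences
#' contrast per outcome; and the food-group energy-share comparison per arm.
#'
#' @param intake an `intake_table` (after QC exclusions).
#' @param bound_fraction TOST equivalence bound.
#' @param bands error-band edges in percent.
#' @param min_consumer_fraction suppression threshold for food-group tests.
#' @return object of class `validation_report`: list with data frames
#'   `equivalence` (per arm x outcome), `did` (per outcome), `bands`
#'   (per arm x outcome), `bland_altman` point sets, and `food_groups`
#'   (per arm).
#' @export
validation_report <- function(intake, bound_fraction = 0.10,
                              bands = c(10, 20, 30, 50),
                              min_consumer_fraction = 0.10) {
  stopifnot(inherits(intake, "intake_table"))
  it <- intake$intakes
  arms <- sort(unique(it$arm))
  outcomes <- .val_outcomes()

  pairs_for <- function(arm, outcome) {
    sub <- it[it$arm == arm, c("respondent_id", "source", outcome)]
    wide <- stats::reshape(sub, idvar = "respondent_id", timevar = "source",
                           direction = "wide")
    wide <- wide[stats::complete.cases(wide), ]
    list(ids = wide$respondent_id,
         wfr = wide[[paste0(outcome, ".WFR")]],
         r24 = wide[[paste0(outcome, ".R24")]])
  }

  eq_rows <- list(); band_rows <- list(); ba <- list()
  for (arm in arms) {
    for (oc in outcomes) {
      p <- pairs_for(arm, oc)
      ts <- tost_equivalence(p$wfr, p$r24, bound_fraction = bound_fraction)
      b <- bland_altman(p$wfr, p$r24)
      eq_rows[[paste(arm, oc)]] <- data.frame(
        arm = arm, outcome = oc, n = ts$n,
        n_zero_excluded = ts$n_zero_excluded,
        geomean_wfr = ts$geomean_wfr, geomean_r24 = ts$geomean_r24,
        mean_wfr = mean(p$wfr), mean_r24 = mean(p$r24),
        mean_diff = mean(p$wfr - p$r24),  # WFR is the minuend
        tost_p = ts$p, equivalent = ts$equivalent,
        ba_bias = b$bias, ba_lower = b$loa[["lower"]],
        ba_upper = b$loa[["upper"]], stringsAsFactors = FALSE)
      pos <- p$wfr > 0
      eb <- error_band_table(p$wfr[pos], p$r24[pos], bands = bands,
                             ids = p$ids[pos])
      band_rows[[paste(arm, oc)]] <- data.frame(
        arm = arm, outcome = oc, n = eb$n,
        as.list(eb$within), over = eb$over, under = eb$under,
        stringsAsFactors = FALSE)
      ba[[paste(arm, oc, sep = "_")]] <- cbind(arm = arm, outcome = oc,
                                               b$points)
    }
  }

  did_rows <- lapply(outcomes, function(oc) {
    long <- it[, c("respondent_id", "arm", "source", oc)]
    names(long)[4] <- "value"
    d <- diff_in_differences(long)
    data.frame(outcome = oc, mean_diff_capi = d$mean_diff_capi,
               mean_diff_papi = d$mean_diff_papi, estimate = d$estimate,
               se = d$se, df = d$df, p = d$p, stringsAsFactors = FALSE)
  })

  shares <- food_group_energy_shares(intake)
  fg <- lapply(arms, function(arm) {
    sub <- shares[shares$respondent_id %in%
                    it$respondent_id[it$arm == arm], ]
    cbind(arm = arm, foodgroup_comparison(sub, min_consumer_fraction))
  })

  structure(list(
    equivalence = do.call(rbind, eq_rows),
    did = do.call(rbind, did_rows),
    bands = do.call(rbind, band_rows),
    bland_altman = do.call(rbind, ba),
    food_groups = do.call(rbind, fg)), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  eq <- x$equivalence
  for (arm in unique(eq$arm)) {
    n_eq <- sum(eq$equivalent[eq$arm == arm])
    cat(sprintf("  %s: %d/%d outcomes equivalent to WFR at the bound\n",
                arm, n_eq, sum(eq$arm == arm)))
  }
  sig <- sum(x$did$p < 0.05)
  cat(sprintf("  DiD: %d/%d outcomes differ between modalities (p<0.05)\n",
              sig, nrow(x$did)))
  invisible(x)
}

#' Write a validation report to CSV tables and JSON
#'
#' @param report a `validation_report`.
#' @param dir output directory.
#' @export
write_validation_report <- function(report, dir) {
  stopifnot(inherits(report, "validation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$equivalence, file.path(dir, "equivalence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$did, file.path(dir, "diff_in_differences.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bands, file.path(dir, "error_bands.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bland_altman, file.path(dir, "bland_altman_points.csv"),
                   row.names = FALSE)
  utils::write.csv(report$food_groups, file.path(dir, "food_group_shares.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    lapply(unclass(report), function(df) df),
    file.path(dir, "validation_report.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
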
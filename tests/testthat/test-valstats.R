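# oracle for the TOST p-value: closed-form t CDF arithmetic, independent of
# the implementation under test
tost_oracle <- function(d, bound = 0.10) {
  n <- length(d); se <- sd(d) / sqrt(n); theta <- log(1 + bound)
  max(pt((mean(d) + theta) / se, n - 1, lower.tail = FALSE),
      pt((mean(d) - theta) / se, n - 1))
}

test_that("TOST equivalence matches the closed-form t-CDF oracle", {
  # exact mean 0, sd 0.2 over 100 pairs
  set.seed(7)
  d <- as.vector(scale(rnorm(100))) * 0.2
  wfr <- rep(100, 100); r24 <- wfr * exp(d)
  ts <- tost_equivalence(wfr, r24)
  expect_equal(ts$p, tost_oracle(d), tolerance = 1e-12)
  expect_lt(ts$p, 1e-5)
  expect_true(ts$equivalent)

  # mean log-ratio beyond the bound can never be declared equivalent
  d2 <- 0.15 + as.vector(scale(rnorm(50))) * 0.1
  ts2 <- tost_equivalence(rep(50, 50), 50 * exp(d2))
  expect_gt(ts2$p, 0.5)
  expect_false(ts2$equivalent)

  # degenerate identical pairs: equivalent with p reported as 0
  ts3 <- tost_equivalence(c(10, 20, 30), c(10, 20, 30))
  expect_true(ts3$equivalent)
  expect_equal(ts3$p, 0)

  expect_error(tost_equivalence(5, 5), "at least 2")
})

test_that("TOST p is monotone in n, minimised at zero shift, sign-symmetric", {
  set.seed(11)
  base <- as.vector(scale(rnorm(40))) * 0.3
  p_at <- function(d) tost_equivalence(rep(1, length(d)), exp(d))$p
  # growing n at fixed mean/sd
  p_small <- p_at(base)
  p_big <- p_at(rep(base, 4))  # same mean and (population) spread, 4x n
  expect_lt(p_big, p_small)
  # shifting the mean away from 0 cannot reduce p
  for (shift in c(0.02, 0.05, 0.08)) {
    expect_gte(p_at(base + shift), p_at(base))
  }
  # negating all log differences leaves p unchanged
  skewed <- base + 0.04
  expect_equal(p_at(-skewed), p_at(skewed), tolerance = 1e-12)
})

test_that("Bland-Altman bias and limits follow mean +/- 1.96 sd", {
  w <- c(10, 10, 10); r <- w + c(-2, 0, 2)
  ba <- bland_altman(w, r)
  expect_equal(ba$bias, 0)
  expect_equal(unname(ba$loa), c(-3.92, 3.92))  # sd of differences is 2

  ba0 <- bland_altman(c(5, 6, 7), c(5, 6, 7))
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))

  set.seed(3)
  w <- rnorm(30, 100, 10); r <- w + rnorm(30)
  expect_equal(bland_altman(w, r + 5)$bias, bland_altman(w, r)$bias + 5)
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("difference-in-differences matches the pooled two-sample t oracle", {
  # per-arm differences {0,1,2} vs {1,2,3}
  d <- diff_in_differences(did_data(c(0, 1, 2), c(1, 2, 3)))
  o <- t.test(c(0, 1, 2), c(1, 2, 3), var.equal = TRUE)
  expect_equal(d$estimate, -1, tolerance = 1e-9)
  expect_equal(d$p, o$p.value, tolerance = 1e-6)
  expect_equal(d$df, 4)

  # identical difference distributions: estimate 0
  d0 <- diff_in_differences(did_data(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(d0$estimate, 0, tolerance = 1e-9)

  # balanced random fixtures: mixed-model p equals pooled-t p to 1e-6
  for (s in 1:4) {
    set.seed(s)
    n <- 20
    dc <- rnorm(n, 50, 100); dp <- rnorm(n, 90, 100)
    fit <- diff_in_differences(did_data(dc, dp))
    o <- t.test(dc, dp, var.equal = TRUE)
    expect_equal(fit$estimate, mean(dc) - mean(dp), tolerance = 1e-8)
    expect_equal(fit$p, o$p.value, tolerance = 1e-6)
  }

  # translating one arm's recall values shifts the estimate exactly
  dat <- did_data(rnorm(10, 0, 5), rnorm(10, 0, 5))
  shifted <- dat
  idx <- shifted$arm == "CAPI" & shifted$source == "R24"
  shifted$value[idx] <- shifted$value[idx] + 100
  expect_equal(diff_in_differences(shifted)$estimate,
               diff_in_differences(dat)$estimate - 100, tolerance = 1e-6)

  bad <- did_data(c(1, 2), c(1, 2))
  bad$arm[bad$respondent_id == "S001"] <- c("CAPI", "PAPI")
  expect_error(diff_in_differences(bad), "both arms|exactly one")
})

test_that("error bands are cumulative, boundary-inclusive and partition", {
  eb <- error_band_table(rep(100, 4), c(105, 115, 150, 300))
  expect_equal(unname(eb$within), c(25, 50, 50, 75))
  expect_equal(eb$over, 25)
  expect_equal(eb$under, 0)

  expect_equal(unname(error_band_table(c(10, 20), c(10, 20))$within[1]), 100)

  # exactly 20% error counts as within the 20% band
  eb2 <- error_band_table(c(100, 200), 1.2 * c(100, 200))
  expect_equal(unname(eb2$within), c(0, 100, 100, 100))

  expect_error(error_band_table(c(0, 10), c(5, 10), ids = c("a", "b")), "a")

  set.seed(5)
  for (i in 1:20) {
    w <- rlnorm(50, 5, 0.5); r <- w * rlnorm(50, 0, 0.6)
    eb <- error_band_table(w, r)
    expect_true(all(diff(eb$within) >= 0))
    expect_equal(unname(eb$within["within_50"]) + eb$over + eb$under, 100,
                 tolerance = 1e-9)
  }
})

test_that("food-group comparison reports medians, signed-rank p and suppression", {
  shares <- data.frame(
    respondent_id = rep(c("r1", "r2", "r3"), each = 2),
    source = rep(c("WFR", "R24"), 3),
    gift_group = "G01",
    share = c(10, 20, 10, 30, 10, 40))
  fg <- foodgroup_comparison(shares)
  expect_equal(fg$median_wfr, 10)
  expect_equal(fg$median_r24, 30)
  # all three differences positive: exact two-tailed signed-rank p = 2/8
  expect_equal(fg$p, 0.25, tolerance = 1e-12)
  expect_true(fg$reported)

  # group consumed by <10% of respondents: medians kept, test suppressed
  n <- 40
  rare <- data.frame(
    respondent_id = rep(sprintf("r%02d", 1:n), each = 2),
    source = rep(c("WFR", "R24"), n),
    gift_group = "G05",
    share = c(rep(0, 2 * n - 2), 5, 8))  # only one consumer
  fg2 <- foodgroup_comparison(rare)
  expect_false(fg2$reported)
  expect_true(is.na(fg2$p))
  expect_match(fg2$p_method, "suppressed")
  expect_equal(fg2$median_wfr, 0)

  # identical shares: test undefined with stated reason
  same <- shares; same$share <- 15
  fg3 <- foodgroup_comparison(same)
  expect_true(is.na(fg3$p))
  expect_match(fg3$p_method, "all differences zero")
})

test_that("Fisher-z sample size reproduces the design calculation", {
  ss <- sample_size_correlation(rho0 = 0.6, rho1 = 0.75, alpha = 0.05,
                                power = 0.80)
  expect_equal(ss$n, 104L)
  expect_equal(ss$n_inflated, 117L)
  expect_equal(sample_size_correlation(power = 0.90)$n, 138L)
  expect_error(sample_size_correlation(rho0 = 0.7, rho1 = 0.7), "differ")
})

test_that("the assembled validation report is internally consistent", {
  cfg <- sim_config(n_per_arm = 25, seed = 8)
  b <- generate_reference_bundle(cfg)
  it <- daily_intakes(generate_paired_records(cfg, b)$records, b)
  qc <- apply_exclusions(it, flag_records(it))
  rep <- validation_report(qc$intake)

  outcomes <- c("item_count", "gram_total", recall_nutrients())
  expect_setequal(unique(rep$equivalence$outcome), outcomes)
  expect_setequal(unique(rep$equivalence$arm), c("CAPI", "PAPI"))
  expect_equal(nrow(rep$did), length(outcomes))
  # WFR is the minuend in the reported mean differences
  eq <- rep$equivalence
  expect_equal(eq$mean_diff, eq$mean_wfr - eq$mean_r24, tolerance = 1e-9)
  # band partition identity holds for every arm x outcome
  expect_true(all(abs(rep$bands$within_50 + rep$bands$over +
                        rep$bands$under - 100) < 1e-9))
})
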
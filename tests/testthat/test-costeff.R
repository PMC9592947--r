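toy_ledger <- function() {
  data.frame(
    modality = c("CAPI", "CAPI", "PAPI"),
    activity = c("survey_execution", "survey_prep", "survey_execution"),
    category = c("time", "non_time", "time"),
    quantity = c(2, 1, 4),
    unit = c("person_day", "lump", "person_day"),
    unit_value = c(50, 100, 50),
    whose_time = c("staff", NA, "staff"),
    stringsAsFactors = FALSE)
}

test_that("cost totals partition into time and non-time components", {
  tc <- total_costs(toy_ledger())
  capi <- tc$summary[tc$summary$modality == "CAPI", ]
  expect_equal(capi$time_cost, 100)
  expect_equal(capi$non_time_cost, 100)
  expect_equal(capi$total_cost, 200)
  expect_equal(capi$person_days, 2)
  papi <- tc$summary[tc$summary$modality == "PAPI", ]
  expect_equal(papi$non_time_cost, 0)  # no non-time rows for that modality

  bad <- toy_ledger(); bad$quantity[1] <- -1
  expect_error(total_costs(bad), "negative")
  expect_error(total_costs(toy_ledger()[0, ]), "empty")
})

test_that("activity subtotals of the generated ledger equal hand sums", {
  led <- generate_cost_ledger(seed = 5)
  tc <- total_costs(led)
  # independent spreadsheet-style oracle over the raw rows
  for (m in c("CAPI", "PAPI")) {
    sub <- led[led$modality == m, ]
    expect_equal(tc$summary$total_cost[tc$summary$modality == m],
                 sum(sub$quantity * sub$unit_value))
    for (a in unique(sub$activity)) {
      for (cat in unique(sub$category[sub$activity == a])) {
        rows <- sub[sub$activity == a & sub$category == cat, ]
        got <- tc$by_activity[tc$by_activity$modality == m &
                                tc$by_activity$activity == a &
                                tc$by_activity$category == cat, "cost"]
        expect_equal(got, sum(rows$quantity * rows$unit_value))
      }
    }
  }
  s <- tc$summary
  expect_equal(s$total_cost, s$time_cost + s$non_time_cost)
})

test_that("group accuracy is 100 minus the capped ratio-of-means error", {
  expect_equal(group_accuracy(3500, 4000), c(error = 12.5, accuracy = 87.5))
  expect_equal(group_accuracy(7, 7), c(error = 0, accuracy = 100))
  expect_equal(group_accuracy(300, 100), c(error = 100, accuracy = 0))
  # scale invariance
  expect_equal(group_accuracy(3500 * 17, 4000 * 17), group_accuracy(3500, 4000))
  expect_error(group_accuracy(10, 0), "> 0")
})

test_that("composite nutrient accuracy is the plain mean of ten values", {
  acc <- setNames(rep(80, 10), recall_nutrients())
  expect_equal(composite_nutrient_accuracy(acc), 80)
  acc2 <- setNames(rep(c(100, 60), each = 5), recall_nutrients())
  expect_equal(composite_nutrient_accuracy(acc2), 80)
  expect_error(composite_nutrient_accuracy(acc[-3]), "protein_g")
})

test_that("cost-effectiveness ratios are homogeneous and monotone in accuracy", {
  row <- data.frame(modality = "CAPI", person_days = 10, time_cost = 4000,
                    non_time_cost = 4750, total_cost = 8750)
  acc <- list(item_count = 87.5, gram = 87.5,
              per_nutrient = setNames(rep(87.5, 10), recall_nutrients()),
              composite = 87.5)
  ce <- cost_effectiveness(row, acc)
  expect_equal(unique(ce$total_cost_per_point), 100)

  row2 <- row; row2[, c("time_cost", "non_time_cost", "total_cost",
                        "person_days")] <-
    2 * row[, c("time_cost", "non_time_cost", "total_cost", "person_days")]
  ce2 <- cost_effectiveness(row2, acc)
  expect_equal(ce2$total_cost_per_point, 2 * ce$total_cost_per_point)

  acc80 <- lapply(acc, function(x) x * 80 / 87.5)
  ce80 <- cost_effectiveness(row, acc80)
  expect_true(all(ce80$total_cost_per_point > ce$total_cost_per_point))

  expect_error(cost_effectiveness(row, lapply(acc, function(x) 0)), "undefined")
})

test_that("borrowing scenarios scale only CAPI reference-data preparation", {
  led <- data.frame(
    modality = c("CAPI", "PAPI", "CAPI"),
    activity = c("reference_data_prep", "reference_data_prep", "training"),
    category = c("time", "time", "time"),
    quantity = c(1000, 800, 50), unit = "person_day",
    unit_value = 1, whose_time = "staff", stringsAsFactors = FALSE)
  out <- apply_borrowing_scenario(led, 0.5)
  expect_equal(out$quantity, c(500, 800, 50))
  expect_equal(apply_borrowing_scenario(led, 0), led)
  expect_error(apply_borrowing_scenario(led, 1), "\\[0, 1\\)")
  expect_error(apply_borrowing_scenario(led[2, ], 0.5), "no CAPI")

  # CAPI total cost is non-increasing in the borrow fraction on any ledger
  set.seed(2)
  for (i in 1:5) {
    led$quantity <- runif(3, 0, 500)
    tots <- sapply(c(0, 0.25, 0.5, 0.75), function(f) {
      tc <- total_costs(apply_borrowing_scenario(led, f))$summary
      tc$total_cost[tc$modality == "CAPI"]
    })
    expect_true(all(diff(tots) <= 1e-12))
  }
})

test_that("scenario table keeps PAPI constant while CAPI weakly improves", {
  led <- generate_cost_ledger(seed = 4)
  acc <- list(
    CAPI = list(item_count = 90, gram = 85,
                per_nutrient = setNames(rep(80, 10), recall_nutrients()),
                composite = 80),
    PAPI = list(item_count = 88, gram = 83,
                per_nutrient = setNames(rep(78, 10), recall_nutrients()),
                composite = 78))
  ce <- ce_scenarios(led, acc)
  papi <- ce$ratios[ce$ratios$modality == "PAPI", ]
  for (m in unique(papi$measure)) {
    expect_equal(length(unique(papi$total_cost_per_point[papi$measure == m])), 1)
  }
  capi <- ce$ratios[ce$ratios$modality == "CAPI", ]
  for (m in unique(capi$measure)) {
    v <- capi$total_cost_per_point[capi$measure == m]
    expect_true(all(diff(v) <= 1e-9))
  }
  expect_equal(ce$costs$total_cost, ce$costs$time_cost + ce$costs$non_time_cost)
})

test_that("accuracy measures recover the known ratio under pure bias", {
  cfg <- zero_noise_config(n_per_arm = 12, portion_bias = 1.2, seed = 6)
  b <- generate_reference_bundle(cfg)
  it <- daily_intakes(generate_paired_records(cfg, b)$records, b)
  for (arm in c("CAPI", "PAPI")) {
    a <- accuracy_measures(it, arm)
    expect_equal(a$gram, 80, tolerance = 1e-3)       # 100 - 100|1 - 1.2|
    expect_equal(a$item_count, 100, tolerance = 1e-9)
  }
})
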
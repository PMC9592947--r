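test_that("bundle round-trips through CSV with counts and missingness intact", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_reference_bundle(b, dir)
  b2 <- load_reference_bundle(dir)

  expect_equal(nrow(b2$foods), 4)
  expect_equal(nrow(b2$recipe_meta), 1)
  # blank vitamin C cell came back as missing, not zero
  expect_true(is.na(b2$foods$vitc_mg[b2$foods$food_code == "F002"]))
  expect_false(is.na(b2$foods$vitc_mg[b2$foods$food_code == "F001"]))
  for (tbl in c("foods", "recipes", "recipe_meta", "portion_factors", "groups")) {
    expect_equal(b2[[tbl]], b[[tbl]], ignore_attr = TRUE)
  }
  # second round trip is byte-stable
  dir2 <- withr::local_tempdir()
  write_reference_bundle(b2, dir2)
  expect_identical(readLines(file.path(dir, "foods.csv")),
                   readLines(file.path(dir2, "foods.csv")))
})

test_that("load rejects duplicate keys, sentinels and malformed cells by name", {
  b <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_reference_bundle(b, dir)

  foods <- utils::read.csv(file.path(dir, "foods.csv"), colClasses = "character")
  utils::write.csv(rbind(foods, foods[1, ]), file.path(dir, "foods.csv"),
                   row.names = FALSE, na = "")
  expect_error(load_reference_bundle(dir), "F001")

  write_reference_bundle(b, dir)
  foods <- utils::read.csv(file.path(dir, "foods.csv"), colClasses = "character")
  foods$energy_kcal[2] <- "lots"
  utils::write.csv(foods, file.path(dir, "foods.csv"), row.names = FALSE, na = "")
  err <- tryCatch(load_reference_bundle(dir), error = conditionMessage)
  expect_match(err, "foods.csv")
  expect_match(err, "line 3")
  expect_match(err, "energy_kcal")

  write_reference_bundle(b, dir)
  foods <- utils::read.csv(file.path(dir, "foods.csv"), colClasses = "character")
  foods$food_code[1] <- "9999"
  utils::write.csv(foods, file.path(dir, "foods.csv"), row.names = FALSE, na = "")
  expect_error(load_reference_bundle(dir), "sentinel")
})

test_that("validate_refdata reports dangling references and unknown groups", {
  expect_equal(nrow(validate_refdata(tiny_bundle())), 0)

  b <- tiny_bundle()
  b$recipes <- rbind(b$recipes,
                     data.frame(recipe_code = "R01", food_code = "F999",
                                ingredient_g = 10))
  v <- validate_refdata(b)
  expect_equal(nrow(v), 1)
  expect_equal(v$kind, "dangling_ingredient")
  expect_equal(v$key, "F999")

  b <- tiny_bundle()
  b$foods$gift_group[1] <- "ZZ"
  v <- validate_refdata(b)
  expect_equal(v$kind, "unknown_group")
  expect_equal(v$key, "ZZ")
  expect_equal(v$referenced_by, "F001")

  b <- tiny_bundle()
  b$recipe_meta$total_prepared_g <- -5
  expect_true("nonpositive_quantity" %in% validate_refdata(b)$kind)
})

test_that("fct_completeness counts non-missing cells per nutrient", {
  b <- tiny_bundle()
  codes <- b$foods$food_code
  comp <- fct_completeness(b, codes)
  expect_equal(unname(comp["vitc_mg"]), 75)   # 1 of 4 missing
  expect_equal(unname(comp["energy_kcal"]), 100)
  expect_true(all(comp[setdiff(names(comp), "vitc_mg")] == 100))

  # 10 foods, 2 missing fibre and 1 missing vitamin A: hand-counted shares
  foods10 <- do.call(rbind, replicate(3, tiny_foods(), simplify = FALSE))[1:10, ]
  foods10$food_code <- sprintf("F%03d", 1:10)
  foods10$vitc_mg <- 1
  foods10$fibre_g <- c(NA, NA, rep(1, 8))
  foods10$vita_mcg_rae <- c(rep(1, 9), NA)
  b10 <- new_reference_bundle(foods10, tiny_bundle()$recipes,
                              tiny_bundle()$recipe_meta,
                              tiny_bundle()$portion_factors,
                              tiny_bundle()$groups)
  comp10 <- fct_completeness(b10, foods10$food_code)
  expect_equal(unname(comp10["fibre_g"]), 80)
  expect_equal(unname(comp10["vita_mcg_rae"]), 90)

  # permutation invariance
  expect_equal(fct_completeness(b, rev(codes)), comp)
  expect_error(fct_completeness(b, c("F001", "F999")), "F999")
  expect_error(fct_completeness(b, character()), "empty")
})
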
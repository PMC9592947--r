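test_that("portion quantities resolve to grams", {
  pf <- tiny_bundle()$portion_factors
  expect_equal(portion_to_grams(list(grams = 250), pf), 250)
  expect_equal(portion_to_grams(list(psem_code = "standard_unit",
                                     unit_code = "bottle", size_label = "small",
                                     n_units = 0.5), pf), 150)
  expect_equal(portion_to_grams(list(psem_code = "photo", unit_code = "P12",
                                     size_label = "small", n_units = 2), pf), 170)
  expect_error(portion_to_grams(list(psem_code = "photo", unit_code = "P99",
                                     size_label = "small", n_units = 1), pf),
               "P99")
  expect_error(portion_to_grams(list(grams = 100, psem_code = "photo",
                                     unit_code = "P12", size_label = "small",
                                     n_units = 1), pf), "exactly one")
  expect_error(portion_to_grams(list(grams = -5), pf), "> 0")
})

test_that("recipe density conserves raw-ingredient nutrients", {
  b <- tiny_bundle()
  ing <- b$recipes[b$recipes$recipe_code == "R01", ]

  r <- resolve_recipe_density(ing, 600, b$foods)
  expect_equal(unname(r$density["energy_kcal"]), (720 + 884) / 6,
               tolerance = 1e-12)
  # oil's missing vitamin C propagates as a flag, contributing zero
  expect_true(r$missing[["vitc_mg"]])
  expect_equal(unname(r$density["vitc_mg"]), 0)
  expect_false(r$missing[["energy_kcal"]])

  # single ingredient, prepared weight equal to ingredient weight: identity
  one <- data.frame(food_code = "F003", ingredient_g = 100)
  r1 <- resolve_recipe_density(one, 100, b$foods)
  expect_equal(unname(r1$density),
               unname(unlist(b$foods[3, recall_nutrients()])))

  # halving the prepared weight doubles the density
  r300 <- resolve_recipe_density(ing, 300, b$foods)
  expect_equal(r300$density, 2 * r$density)

  expect_error(resolve_recipe_density(ing, 0, b$foods), "total_prepared_g")
  bad <- data.frame(food_code = "F999", ingredient_g = 10)
  expect_error(resolve_recipe_density(bad, 100, b$foods), "F999")
})

test_that("single-item nutrients follow grams x density / 100", {
  b <- tiny_bundle()
  r <- item_nutrients(rec_row("S1", "CAPI", "R24", "R01", 150), b)
  expect_equal(unname(r$nutrients["energy_kcal"]), 401, tolerance = 1e-10)
  expect_equal(r$gift_group, "G01")

  r100 <- item_nutrients(rec_row("S1", "CAPI", "R24", "F003", 100), b)
  expect_equal(unname(r100$nutrients),
               unname(unlist(b$foods[3, recall_nutrients()])))

  roil <- item_nutrients(rec_row("S1", "CAPI", "R24", "F002", 200), b)
  expect_equal(unname(roil$nutrients["vitc_mg"]), 0)
  expect_true(roil$missing[["vitc_mg"]])
})

test_that("daily intakes are additive and match a brute-force oracle", {
  b <- tiny_bundle()
  recs <- rbind(rec_row("S1", "CAPI", "WFR", "F003", 500),   # 100 kcal
                rec_row("S1", "CAPI", "WFR", "F001", 83 + 1 / 3)) # 300 kcal
  it <- daily_intakes(recs, b)
  expect_equal(nrow(it$intakes), 1)
  expect_equal(it$intakes$energy_kcal, 400, tolerance = 1e-9)
  expect_equal(it$intakes$item_count, 2L)
  expect_equal(it$intakes$gram_total, 500 + 83 + 1 / 3)

  # a respondent with no records simply has no row
  expect_false("S9" %in% it$intakes$respondent_id)

  # 3 respondents x 2 sources x 2 items vs an independent per-record loop
  set.seed(42)
  codes <- c("F001", "F002", "F003", "F004", "R01")
  recs <- do.call(rbind, lapply(sprintf("S%d", 1:3), function(id) {
    do.call(rbind, lapply(c("WFR", "R24"), function(src) {
      rbind(rec_row(id, "CAPI", src, sample(codes, 1), round(runif(1, 10, 400), 1)),
            rec_row(id, "CAPI", src, sample(codes, 1), round(runif(1, 10, 400), 1)))
    }))
  }))
  it <- daily_intakes(recs, b)
  expect_equal(nrow(it$intakes), 6)

  dens_oracle <- function(code) {
    if (code == "R01") {
      comp <- b$foods[match(c("F001", "F002"), b$foods$food_code),
                      recall_nutrients()]
      comp[is.na(comp)] <- 0
      100 * colSums(c(200, 100) * comp / 100) / 600
    } else {
      v <- unlist(b$foods[match(code, b$foods$food_code), recall_nutrients()])
      v[is.na(v)] <- 0
      v
    }
  }
  for (i in seq_len(nrow(it$intakes))) {
    row <- it$intakes[i, ]
    sub <- recs[recs$respondent_id == row$respondent_id &
                  recs$source == row$source, ]
    exp_nut <- Reduce(`+`, lapply(seq_len(nrow(sub)), function(j) {
      sub$grams[j] * unlist(dens_oracle(sub$code[j])) / 100
    }))
    expect_equal(unlist(row[recall_nutrients()]), exp_nut,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(row$gram_total, sum(sub$grams))
  }
})

test_that("intakes are scale-equivariant and shares scale-invariant", {
  b <- tiny_bundle()
  recs <- rbind(rec_row("S1", "CAPI", "WFR", "F001", 120),
                rec_row("S1", "CAPI", "WFR", "F004", 80),
                rec_row("S1", "CAPI", "WFR", "R01", 200))
  it1 <- daily_intakes(recs, b)
  recs2 <- recs; recs2$grams <- recs2$grams * 2
  it2 <- daily_intakes(recs2, b)
  expect_equal(it2$intakes$gram_total, 2 * it1$intakes$gram_total)
  expect_equal(unlist(it2$intakes[recall_nutrients()]),
               2 * unlist(it1$intakes[recall_nutrients()]))
  expect_equal(food_group_energy_shares(it2)$share,
               food_group_energy_shares(it1)$share, tolerance = 1e-12)
})

test_that("food-group shares partition daily energy", {
  b <- tiny_bundle()
  # 300 kcal cereals (rice), 100 kcal vegetables (tomato)
  recs <- rbind(rec_row("S1", "CAPI", "WFR", "F001", 250 / 3),
                rec_row("S1", "CAPI", "WFR", "F003", 500))
  sh <- food_group_energy_shares(daily_intakes(recs, b))
  expect_equal(sh$share[sh$gift_group == "G01"], 75, tolerance = 1e-9)
  expect_equal(sh$share[sh$gift_group == "G04"], 25, tolerance = 1e-9)
  expect_equal(sum(sh$share), 100, tolerance = 1e-9)

  one <- daily_intakes(rec_row("S1", "CAPI", "WFR", "F001", 100), b)
  expect_equal(food_group_energy_shares(one)$share, 100)

  # a zero-energy day has undefined shares
  b0 <- b; b0$foods$energy_kcal[3] <- 0
  z <- daily_intakes(rec_row("S1", "CAPI", "WFR", "F003", 100), b0)
  expect_error(food_group_energy_shares(z), "zero-energy")
})

test_that("record validation catches mixed arms, bad quantities, bad codes", {
  b <- tiny_bundle()
  both <- rbind(rec_row("S1", "CAPI", "WFR", "F001", 100),
                rec_row("S1", "PAPI", "R24", "F001", 100))
  expect_error(daily_intakes(both, b), "both arms")

  r <- rec_row("S1", "CAPI", "WFR", "F001", 100)
  r$psem_code <- "photo"; r$unit_code <- "P12"; r$size_label <- "small"
  r$n_units <- 1
  expect_error(daily_intakes(r, b), "exactly one")
  expect_error(daily_intakes(rec_row("S1", "CAPI", "WFR", "F999", 100), b),
               "F999")
})

test_that("non-standard recipes resolve through inline ingredient detail", {
  b <- tiny_bundle()
  nsr <- list(
    ingredients = data.frame(recipe_code = "NSR1",
                             food_code = c("F003", "F004"),
                             ingredient_g = c(300, 200)),
    meta = data.frame(recipe_code = "NSR1", total_prepared_g = 400,
                      gift_group = NA_character_))
  rec <- rec_row("S1", "CAPI", "R24", "NSR1", 200)
  rec$item_type <- "nonstandard_recipe"
  it <- daily_intakes(rec, b, nsr = nsr)
  # (300*0.2 + 200*1.2) kcal in 400 g prepared -> 75 kcal/100 g; 200 g -> 150
  expect_equal(it$intakes$energy_kcal, 150, tolerance = 1e-10)
  # dish group defaults to the dominant-energy ingredient (fish)
  expect_equal(it$group_energy$gift_group, "G07")
})
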
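# Seeded generator for reference bundles, paired WFR/24HR consumption
# records with a controllable recall-error structure, and toy cost ledgers.
#
# The 24HR day is generated *conditionally on* the WFR day (the design is
# paired): items are dropped (omissions), extra menu items appear
# (intrusions), portions are multiplied by portion_bias x a mean-one
# lognormal error, standard recipes are swapped for a near neighbour, and a
# small fraction of respondents have their WFR day scaled to breach the
# 500/5000 kcal plausibility bounds so the quality-control stage has
# something to catch.

.GIFT_GROUPS <- data.frame(
  gift_group = sprintf("G%02d", 1:12),
  label = c("Cereals and their products", "Roots, tubers and plantains",
            "Pulses, seeds and nuts", "Vegetables and their products",
            "Fruits and their products", "Meat and meat products",
            "Fish, shellfish and their products", "Milk and milk products",
            "Eggs and their products", "Fats and oils",
            "Beverages", "Spices and condiments"),
  stringsAsFactors = FALSE
)

# plausible per-100 g composition ranges by GIFT group:
# energy kcal, fat g, protein g, carb g, fibre g, vitA mcg, vitC mg,
# Ca mg, Fe mg, Zn mg -- each row c(lo, hi)
.GROUP_COMP_RANGES <- list(
  G01 = rbind(c(320, 380), c(1, 6), c(6, 13), c(65, 80), c(2, 12),
              c(0, 20), c(0, 1), c(5, 50), c(1, 6), c(1, 4)),
  G02 = rbind(c(80, 160), c(0, 1), c(1, 3), c(18, 38), c(1, 5),
              c(0, 100), c(5, 30), c(10, 50), c(0.3, 2), c(0.2, 1)),
  G03 = rbind(c(300, 580), c(1, 45), c(18, 28), c(15, 60), c(5, 15),
              c(0, 10), c(0, 3), c(40, 200), c(2, 9), c(2, 6)),
  G04 = rbind(c(20, 60), c(0, 1), c(1, 4), c(3, 10), c(1, 5),
              c(10, 600), c(5, 60), c(20, 200), c(0.3, 3), c(0.2, 1)),
  G05 = rbind(c(40, 120), c(0, 1), c(0.5, 2), c(10, 30), c(1, 6),
              c(5, 300), c(10, 60), c(5, 40), c(0.2, 1.5), c(0.1, 0.5)),
  G06 = rbind(c(120, 280), c(5, 22), c(17, 28), c(0, 1), c(0, 0.01),
              c(0, 50), c(0, 2), c(5, 20), c(1, 4), c(2, 6)),
  G07 = rbind(c(90, 200), c(2, 12), c(16, 26), c(0, 1), c(0, 0.01),
              c(5, 60), c(0, 2), c(20, 400), c(0.5, 3), c(0.5, 2)),
  G08 = rbind(c(40, 90), c(1, 5), c(3, 6), c(4, 7), c(0, 0.01),
              c(20, 80), c(0, 3), c(100, 180), c(0, 0.3), c(0.3, 0.7)),
  G09 = rbind(c(130, 160), c(9, 12), c(11, 14), c(0.5, 1.5), c(0, 0.01),
              c(100, 250), c(0, 1), c(40, 70), c(1.2, 2.5), c(1, 1.5)),
  G10 = rbind(c(860, 900), c(95, 100), c(0, 0.2), c(0, 0.2), c(0, 0.01),
              c(0, 800), c(0, 0.5), c(0, 5), c(0, 0.3), c(0, 0.1)),
  G11 = rbind(c(20, 60), c(0, 0.3), c(0, 1), c(5, 15), c(0, 0.5),
              c(0, 10), c(0, 30), c(2, 20), c(0, 0.5), c(0, 0.2)),
  G12 = rbind(c(200, 350), c(2, 12), c(5, 12), c(30, 60), c(3, 15),
              c(0, 30), c(0, 5), c(20, 150), c(1, 8), c(0.5, 3))
)

# mean portion (g) and item-sampling weight per GIFT group; cereals dominate
# both so that roughly three quarters of energy comes from the cereal group,
# as is typical of a rural West African diet.
.GROUP_PORTION_MEAN <- c(G01 = 170, G02 = 90, G03 = 60, G04 = 60, G05 = 60,
                         G06 = 40, G07 = 60, G08 = 90, G09 = 45, G10 = 12,
                         G11 = 150, G12 = 6)
.GROUP_WEIGHT_CEREAL <- c(G01 = 8, G02 = 0.6, G03 = 2, G04 = 2, G05 = 1,
                          G06 = 0.5, G07 = 1.5, G08 = 0.4, G09 = 0.3, G10 = 3,
                          G11 = 1, G12 = 1.5)

#' Configuration for the synthetic paired-recall study
#'
#' Defaults describe the emulated validation study: two arms of 116
#' respondents, each observed for one weighed-food-record day and interviewed
#' for one 24HR day, with recall error of realistic size (10% omissions and
#' intrusions, 5% mean portion overestimation with 30% coefficient of
#' variation, occasional recipe substitution, ~3% implausible-energy days).
#'
#' @param n_per_arm respondents per arm.
#' @param menu_size number of foods on the synthetic food list (>= 2).
#' @param mean_items_per_day mean number of consumed items per day.
#' @param omission_prob probability that a WFR item is not recalled.
#' @param intrusion_prob probability (per WFR item) that an extra menu item
#'   is erroneously recalled.
#' @param portion_bias multiplicative bias of recalled portions (> 0); 1 means
#'   unbiased.
#' @param portion_cv lognormal coefficient of variation of recalled portions;
#'   the noise term has mean exactly 1 so `portion_bias` alone controls the
#'   expected gram ratio.
#' @param recipe_swap_prob probability that a recalled standard recipe is
#'   reported as a different (near-neighbour) standard recipe.
#' @param outlier_prob probability that a respondent's WFR day is scaled to
#'   an implausible energy total (< 500 or > 5000 kcal).
#' @param psem_fraction fraction of recalled items expressed through a
#'   portion-size estimation method (photo/standard unit) instead of direct
#'   grams; conversion is exact, so this exercises the portion-factor path
#'   without adding error.
#' @param cereal_heavy if `TRUE`, item sampling is weighted so cereals
#'   dominate energy intake.
#' @param seed integer seed; everything downstream is reproducible given it.
#' @return a validated object of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 116, menu_size = 40, mean_items_per_day = 8,
                       omission_prob = 0.10, intrusion_prob = 0.10,
                       portion_bias = 1.05, portion_cv = 0.30,
                       recipe_swap_prob = 0.05, outlier_prob = 0.03,
                       psem_fraction = 0.30, cereal_heavy = TRUE, seed = 1L) {
  cfg <- list(n_per_arm = as.integer(n_per_arm), menu_size = as.integer(menu_size),
              mean_items_per_day = mean_items_per_day,
              omission_prob = omission_prob, intrusion_prob = intrusion_prob,
              portion_bias = portion_bias, portion_cv = portion_cv,
              recipe_swap_prob = recipe_swap_prob, outlier_prob = outlier_prob,
              psem_fraction = psem_fraction, cereal_heavy = isTRUE(cereal_heavy),
              seed = as.integer(seed))
  probs <- c("omission_prob", "intrusion_prob", "recipe_swap_prob",
             "outlier_prob", "psem_fraction")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] >= 1) stop(p, " must be in [0, 1)", call. = FALSE)
  }
  if (cfg$portion_bias <= 0) stop("portion_bias must be > 0", call. = FALSE)
  if (cfg$portion_cv < 0) stop("portion_cv must be >= 0", call. = FALSE)
  if (cfg$menu_size < 2) stop("menu_size must be >= 2", call. = FALSE)
  if (cfg$n_per_arm < 1) stop("n_per_arm must be >= 1", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' A noise-free variant of a simulation configuration
#'
#' All error channels off: the 24HR day reproduces the WFR day record for
#' record, so the full pipeline must report 100% accuracy everywhere.
#'
#' @param ... overrides passed to [sim_config()].
#' @export
zero_noise_config <- function(...) {
  args <- list(omission_prob = 0, intrusion_prob = 0, portion_bias = 1,
               portion_cv = 0, recipe_swap_prob = 0, outlier_prob = 0,
               psem_fraction = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# run expr with a private RNG stream derived from (seed, step), restoring
# the caller's RNG state afterwards
.with_stream <- function(seed, step, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + step) %% .Machine$integer.max)
  expr
}

#' Generate a synthetic dietary reference bundle
#'
#' Foods spread over the 12 GIFT groups with group-typical compositions,
#' a handful of standard recipes (with total prepared weight), portion
#' factors for three PSEM families (photo, standard unit, proxy water),
#' and the GIFT group map. Micronutrient cells are left missing with small
#' probability to exercise the missing-data pathway, mirroring real food
#' composition tables which are rarely complete.
#'
#' @param config a [sim_config()].
#' @return a valid `reference_bundle` ([validate_refdata()] returns no rows).
#' @export
generate_reference_bundle <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_stream(config$seed, 0L, {
    m <- config$menu_size
    grp_codes <- .GIFT_GROUPS$gift_group
    # guarantee coverage of at least min(12, m) groups, then fill by weight
    grps <- c(grp_codes[seq_len(min(length(grp_codes), m))],
              sample(grp_codes, max(0L, m - length(grp_codes)), replace = TRUE))
    grps <- grps[seq_len(m)]
    comp <- t(vapply(grps, function(g) {
      r <- .GROUP_COMP_RANGES[[g]]
      stats::runif(nrow(r), r[, 1], r[, 2])
    }, numeric(10)))
    colnames(comp) <- recall_nutrients()
    # sparse missingness on micronutrients only (energy/macros complete)
    micro <- c("fibre_g", "vita_mcg_rae", "vitc_mg", "fe_mg", "zn_mg")
    for (col in micro) {
      drop <- stats::runif(m) < 0.05
      comp[drop, col] <- NA
    }
    foods <- data.frame(
      food_code = sprintf("F%03d", seq_len(m)),
      name = paste0("food_", seq_len(m), "_", tolower(sub("G", "g", grps))),
      gift_group = grps, stringsAsFactors = FALSE)
    foods <- cbind(foods, as.data.frame(comp))

    n_rec <- max(1L, m %/% 10L)
    rec_rows <- list(); meta_rows <- list()
    for (j in seq_len(n_rec)) {
      k <- sample(2:4, 1)
      ing <- sample(foods$food_code, k)
      gr <- round(stats::runif(k, 40, 300), 1)
      rec_rows[[j]] <- data.frame(recipe_code = sprintf("R%02d", j),
                                  food_code = ing, ingredient_g = gr,
                                  stringsAsFactors = FALSE)
      idx <- match(ing, foods$food_code)
      en <- gr * ifelse(is.na(foods$energy_kcal[idx]), 0, foods$energy_kcal[idx])
      meta_rows[[j]] <- data.frame(
        recipe_code = sprintf("R%02d", j),
        total_prepared_g = round(sum(gr) * stats::runif(1, 0.9, 1.4), 1),
        gift_group = foods$gift_group[idx[which.max(en)]],
        stringsAsFactors = FALSE)
    }
    recipes <- do.call(rbind, rec_rows)
    recipe_meta <- do.call(rbind, meta_rows)

    portion_factors <- rbind(
      data.frame(psem_code = "photo", unit_code = sprintf("P%02d", 1:6),
                 size_label = rep(c("small", "large"), 3),
                 grams_per_unit = round(stats::runif(6, 40, 350), 1)),
      data.frame(psem_code = "standard_unit",
                 unit_code = rep(c("bottle", "cup", "ladle"), each = 2),
                 size_label = rep(c("small", "large"), 3),
                 grams_per_unit = c(300, 500, 150, 250, 60, 120)),
      data.frame(psem_code = "proxy_water", unit_code = "bowl",
                 size_label = c("half", "full"), grams_per_unit = c(175, 350))
    )
    new_reference_bundle(foods, recipes, recipe_meta, portion_factors,
                         .GIFT_GROUPS)
  })
}

# sampling weights over menu items (foods + recipes): group-level weights
# split evenly over the menu entries of each group, so the dietary mix does
# not depend on how many foods a random menu happens to list per group
.item_weights <- function(bundle, cereal_heavy) {
  grp <- c(bundle$foods$gift_group, bundle$recipe_meta$gift_group)
  w <- if (cereal_heavy) .GROUP_WEIGHT_CEREAL[grp] else
    stats::setNames(rep(1, length(grp)), grp)
  unname(w / table(grp)[grp])
}

#' Generate paired WFR/24HR consumption records with known error structure
#'
#' For every respondent a weighed-food-record day is drawn from the bundle's
#' menu (direct gram weights, as a WFR produces), and the paired 24HR day is
#' derived from it: each item is omitted with `omission_prob`, an extra menu
#' item intrudes with probability `intrusion_prob` per true item, each
#' recalled portion is multiplied by `portion_bias * exp(rnorm(.,
#' -portion_cv^2/2, portion_cv))` (a mean-one lognormal, so the expected gram
#' ratio equals `portion_bias`), and a recalled standard recipe is swapped
#' for another with probability `recipe_swap_prob`. With probability
#' `outlier_prob` a respondent's WFR day is rescaled to an implausible energy
#' total. Arms alternate deterministically (respondent 1 CAPI, 2 PAPI, ...)
#' so arms are balanced, emulating the randomised allocation.
#'
#' @param config a [sim_config()].
#' @param bundle a `reference_bundle`, typically from
#'   [generate_reference_bundle()].
#' @return list with `records` (records-schema data frame for both sources)
#'   and `truth` (one row per record slot: respondent, source, code, event
#'   in kept/omitted/intruded/swapped/outlier_scaled, multiplier applied).
#' @export
generate_paired_records <- function(config, bundle) {
  stopifnot(inherits(config, "sim_config"), inherits(bundle, "reference_bundle"))
  .with_stream(config$seed, 1L, {
    n <- 2L * config$n_per_arm
    ids <- sprintf("S%04d", seq_len(n))
    arms <- rep(c("CAPI", "PAPI"), length.out = n)
    menu <- c(bundle$foods$food_code, bundle$recipe_meta$recipe_code)
    menu_type <- rep(c("food", "standard_recipe"),
                     c(nrow(bundle$foods), nrow(bundle$recipe_meta)))
    menu_grp <- c(bundle$foods$gift_group, bundle$recipe_meta$gift_group)
    w <- .item_weights(bundle, config$cereal_heavy)
    n_recipes <- nrow(bundle$recipe_meta)

    # energy density per code (missing -> 0) for outlier scaling
    dt <- .density_table(bundle)
    edens <- dt$density[, "energy_kcal"]

    pf <- bundle$portion_factors

    recs <- list(); truths <- list(); ri <- 0L
    push <- function(df, tr) {
      ri <<- ri + 1L
      recs[[ri]] <<- df
      truths[[ri]] <<- tr
    }

    is_cereal <- menu_grp == "G01"
    stratified <- config$cereal_heavy && any(is_cereal) && any(!is_cereal)

    for (i in seq_len(n)) {
      k <- max(1L, as.integer(round(stats::rnorm(1, config$mean_items_per_day, 1.5))))
      if (stratified) {
        # staple-based diet: each day carries 2-4 cereal servings (the staple
        # of every main meal), the rest drawn from the non-cereal menu
        k_cer <- 2L + stats::rbinom(1, 2, 0.5)
        k_oth <- max(0L, k - k_cer)
        k <- k_cer + k_oth
        oth <- which(!is_cereal)
        pick <- c(sample(which(is_cereal), k_cer, replace = TRUE),
                  if (k_oth > 0) oth[sample.int(length(oth), k_oth,
                                                replace = TRUE, prob = w[oth])])
      } else {
        pick <- sample(length(menu), k, replace = TRUE, prob = w)
      }
      codes <- menu[pick]
      types <- menu_type[pick]
      grams <- round(stats::rlnorm(k,
        meanlog = log(.GROUP_PORTION_MEAN[menu_grp[pick]]) - 0.125,
        sdlog = 0.35), 1)
      grams <- pmax(grams, 1)

      out_mult <- 1
      outlier <- stats::runif(1) < config$outlier_prob
      if (outlier) {
        day_energy <- sum(grams * edens[codes] / 100)
        target <- if (stats::runif(1) < 0.5) 300 else 6000
        out_mult <- target / max(day_energy, 1e-9)
        grams <- round(grams * out_mult, 2)
        grams <- pmax(grams, 0.1)
      }

      wfr <- data.frame(respondent_id = ids[i], arm = arms[i], source = "WFR",
                        item_type = types, code = codes, grams = grams,
                        psem_code = NA_character_, unit_code = NA_character_,
                        size_label = NA_character_, n_units = NA_real_,
                        stringsAsFactors = FALSE)
      push(wfr, data.frame(respondent_id = ids[i], source = "WFR",
                           code = codes,
                           event = if (outlier) "outlier_scaled" else "kept",
                           multiplier = out_mult, stringsAsFactors = FALSE))

      # ---- 24HR day, conditional on the WFR day ----
      omit <- stats::runif(k) < config$omission_prob
      r_codes <- codes; r_types <- types; r_grams <- grams
      event <- rep("kept", k)
      swap <- r_types == "standard_recipe" &
        stats::runif(k) < config$recipe_swap_prob & n_recipes > 1L
      if (any(swap)) {
        for (s in which(swap)) {
          alt <- setdiff(bundle$recipe_meta$recipe_code, r_codes[s])
          r_codes[s] <- alt[sample.int(length(alt), 1)]
          event[s] <- "swapped"
        }
      }
      mult <- config$portion_bias *
        stats::rlnorm(k, meanlog = -config$portion_cv^2 / 2,
                      sdlog = config$portion_cv)
      r_grams <- r_grams * mult
      event[omit] <- "omitted"

      n_intr <- stats::rbinom(1, k, config$intrusion_prob)
      if (n_intr > 0) {
        ipick <- sample(length(menu), n_intr, replace = TRUE, prob = w)
        igrams <- pmax(round(stats::rlnorm(n_intr,
          meanlog = log(.GROUP_PORTION_MEAN[menu_grp[ipick]]) - 0.125,
          sdlog = 0.35), 1), 1)
        r_codes <- c(r_codes[!omit], menu[ipick])
        r_types <- c(r_types[!omit], menu_type[ipick])
        r_grams <- c(r_grams[!omit], igrams)
        r_event <- c(event[!omit], rep("intruded", n_intr))
        r_mult <- c(mult[!omit], rep(1, n_intr))
      } else {
        r_codes <- r_codes[!omit]; r_types <- r_types[!omit]
        r_grams <- r_grams[!omit]
        r_event <- event[!omit]; r_mult <- mult[!omit]
      }
      if (!length(r_codes)) {  # everything omitted: recall at least one item
        keep1 <- sample.int(k, 1)
        r_codes <- codes[keep1]; r_types <- types[keep1]
        r_grams <- grams[keep1] * mult[keep1]
        r_event <- "kept"; r_mult <- mult[keep1]
      }
      r_grams <- round(r_grams, 4)

      # express a fraction of recalled items through a PSEM factor
      # (grams_per_unit x fractional n_units reproduces the grams exactly)
      m2 <- length(r_codes)
      use_psem <- stats::runif(m2) < config$psem_fraction
      psem <- rep(NA_character_, m2); unit <- rep(NA_character_, m2)
      size <- rep(NA_character_, m2); nu <- rep(NA_real_, m2)
      if (any(use_psem)) {
        fi <- sample.int(nrow(pf), sum(use_psem), replace = TRUE)
        psem[use_psem] <- pf$psem_code[fi]
        unit[use_psem] <- pf$unit_code[fi]
        size[use_psem] <- pf$size_label[fi]
        nu[use_psem] <- r_grams[use_psem] / pf$grams_per_unit[fi]
      }
      g_col <- ifelse(use_psem, NA_real_, r_grams)

      r24 <- data.frame(respondent_id = ids[i], arm = arms[i], source = "R24",
                        item_type = r_types, code = r_codes, grams = g_col,
                        psem_code = psem, unit_code = unit, size_label = size,
                        n_units = nu, stringsAsFactors = FALSE)
      push(r24, data.frame(respondent_id = ids[i], source = "R24",
                           code = r_codes, event = r_event,
                           multiplier = r_mult, stringsAsFactors = FALSE))
      if (any(omit)) {
        push(NULL, data.frame(respondent_id = ids[i], source = "R24",
                              code = codes[omit], event = "omitted",
                              multiplier = 0, stringsAsFactors = FALSE))
      }
    }
    records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
    truth <- do.call(rbind, truths)
    rownames(records) <- rownames(truth) <- NULL
    list(records = records, truth = truth)
  })
}

#' Generate a toy activity-level cost ledger for both survey modalities
#'
#' One currency, six activities (reference data preparation, survey
#' preparation, training, survey execution, data entry, cleaning/processing),
#' with time rows in person-days (valued at role wages; respondent time at
#' the minimum wage) and non-time rows (supplies, equipment, transport). The
#' computer-assisted modality carries higher equipment costs and substantial
#' reference-data preparation; the paper modality is more personnel-intensive
#' (data entry and cleaning), echoing the typical cost structure of the two
#' designs.
#'
#' @param seed integer seed for the small random perturbations of quantities.
#' @return data frame `modality, activity, category, quantity, unit,
#'   unit_value, whose_time` suitable for [total_costs()].
#' @export
generate_cost_ledger <- function(seed = 1L) {
  .with_stream(as.integer(seed), 2L, {
    acts <- c("reference_data_prep", "survey_prep", "training",
              "survey_execution", "data_entry", "cleaning_processing")
    base <- list(
      #          activity              capi_pd papi_pd capi_ntc papi_ntc
      reference_data_prep = c(60, 60, 1200, 900),
      survey_prep         = c(25, 22, 2500, 1400),
      training            = c(110, 140, 1800, 1500),
      survey_execution    = c(210, 260, 5200, 2600),
      data_entry          = c(8, 85, 300, 900),
      cleaning_processing = c(30, 100, 200, 300)
    )
    jitter <- function(x) x * stats::runif(length(x), 0.95, 1.05)
    rows <- list()
    for (a in acts) {
      v <- jitter(base[[a]])
      rows[[length(rows) + 1L]] <- data.frame(
        modality = c("CAPI", "PAPI"), activity = a, category = "time",
        quantity = round(v[1:2], 1), unit = "person_day",
        unit_value = 22, whose_time = "staff", stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        modality = c("CAPI", "PAPI"), activity = a, category = "non_time",
        quantity = 1, unit = "lump", unit_value = round(v[3:4], 0),
        whose_time = NA_character_, stringsAsFactors = FALSE)
    }
    # respondent time during execution, valued at minimum wage
    rows[[length(rows) + 1L]] <- data.frame(
      modality = c("CAPI", "PAPI"), activity = "survey_execution",
      category = "time", quantity = c(29, 29), unit = "person_day",
      unit_value = 3.1, whose_time = "respondent", stringsAsFactors = FALSE)
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
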
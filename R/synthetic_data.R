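# Synthetic product-label generator with known ground truth. Every pipeline
# stage is testable without proprietary label data: products are constructed
# so the categorizer's composition/name/texture rules yield the intended
# subcategory, and injected violations trip exactly the intended
# requirements. Violations are injected as certainties per product (the
# Bernoulli draw decides the intent; construction realizes it exactly), so
# the assessed statuses must reproduce the stored ground truth.

# Per-subcategory nutrient anchors: median and quartiles per 100 g for total
# sugar (g), sodium (mg), protein (g) and total fat (g) from the reference
# market's nutrient summary; energy (kcal/100 g) anchors are the package's
# own choice, set so each subcategory's energy-density pass rate is
# plausible for its market segment (e.g. vegetable-only purees mostly below
# 60 kcal/100 g, dairy desserts mostly above).
DEFAULT_NUTRIENT_ANCHORS <- list(
  dairy_dessert = list(
    total_sugar = c(8.0, 6.4, 10.0), sodium = c(23, 22, 40),
    protein = c(2.1, 1.7, 3.3), total_fat = c(3.1, 2.8, 3.9),
    energy = c(90, 80, 100)),
  fruit_puree = list(
    total_sugar = c(10.6, 8.8, 12.1), sodium = c(6, 2, 17),
    protein = c(0.9, 0.4, 1.0), total_fat = c(0.2, 0.0, 0.4),
    energy = c(65, 55, 75)),
  vegetable_only_puree = list(
    total_sugar = c(3.3, 2.8, 4.9), sodium = c(18, 7, 27),
    protein = c(0.9, 0.9, 1.1), total_fat = c(0.1, 0.0, 0.6),
    energy = c(45, 38, 55)),
  vegetable_puree_with_cereal = list(
    total_sugar = c(2.8, 2.1, 4.6), sodium = c(14, 8, 22),
    protein = c(1.7, 1.1, 1.8), total_fat = c(0.4, 0.3, 1.0),
    energy = c(60, 50, 72)),
  pureed_meal_cheese = list(
    total_sugar = c(2.8, 1.6, 2.8), sodium = c(36, 32, 58),
    protein = c(2.5, 2.5, 2.9), total_fat = c(2.4, 2.4, 2.6),
    energy = c(80, 70, 90)),
  pureed_meal_meat_fish = list(
    total_sugar = c(1.6, 0.8, 3.2), sodium = c(23, 15, 52),
    protein = c(2.9, 2.2, 3.7), total_fat = c(1.2, 0.6, 1.6),
    energy = c(60, 50, 72)),
  pureed_meal_no_meat_fish = list(
    total_sugar = c(2.4, 0.8, 3.5), sodium = c(28, 20, 60),
    protein = c(2.7, 2.2, 3.2), total_fat = c(1.3, 0.8, 2.2),
    energy = c(58, 48, 70)),
  chunky_meal_meat_fish_cheese = list(
    total_sugar = c(1.1, 0.7, 1.6), sodium = c(46, 23, 66),
    protein = c(3.0, 2.3, 3.7), total_fat = c(1.6, 1.2, 2.2),
    energy = c(75, 60, 90)),
  chunky_meal_vegetable = list(
    total_sugar = c(1.4, NA, NA), sodium = c(22, NA, NA),
    protein = c(2.8, NA, NA), total_fat = c(0.9, NA, NA),
    energy = c(70, 60, 85))
)

# Violation prevalences: probability a generated product is constructed to
# fail each requirement, anchored to the reference market's overall failure
# proportions among applicable products.
DEFAULT_FAILURE_PREVALENCES <- c(
  added_sugar = 79 / 459,
  fruit_content = 34 / 214,
  energy_density = 152 / 424,
  sodium = 111 / 459,
  total_fat = 16 / 459,
  protein = 64 / 125
)

DEFAULT_LABELLING_FAIL_PREVALENCES <- c(
  bf_min_age_6mo = 126 / 459,
  bf_not_marketed_under_6mo = 132 / 459,
  bf_breastfeeding_message = 381 / 459,
  bf_no_superiority_claim = 16 / 459,
  bf_no_bottle_feeding = 0,
  cl_no_nonpermitted_compositional = 436 / 459,
  cl_no_nutrient_content = 115 / 459,
  cl_no_nutrient_function = 18 / 459,
  cl_no_disease_risk_reduction = 0,
  cl_no_other = 371 / 459,
  nc_name_reflects_order = 187 / 459,
  nc_pct_fruit_stated = 105 / 307,
  nc_pct_water_stated = 190 / 260,
  nc_pct_protein_stated = 20 / 116,
  sp_no_suck_message = 206 / 250,
  sp_choke_warning = 60 / 250,
  ar_max_age_12mo = 422 / 424
)

# Missingness of nutrient declarations, from the reference market's
# "n declaring" columns (459 products).
DEFAULT_MISSINGNESS <- c(
  energy = 0, total_sugar = 61 / 459, sodium = 27 / 459,
  total_fat = 10 / 459, protein = 0
)

DEFAULT_SPOUT_RATE <- 250 / 424  # pureed products with a spout

CLAIM_TEXT_POOL <- list(
  nonpermitted_compositional = c(
    "no added salt", "no artificial colours",
    "contains naturally occurring sugars", "100% natural", "organic"),
  nutrient_content = c("high in vitamin C", "source of fibre", "rich in iron"),
  nutrient_function = c("calcium supports healthy bones",
                        "iron contributes to brain development"),
  disease_risk_reduction = c("helps reduce the risk of anaemia"),
  other = c("easy to carry anywhere", "fresh and delicious as mom cooks",
            "easy to swallow texture")
)

#' Configure a synthetic market
#'
#' The defaults are the study conditions the generator emulates: the
#' subcategory mix of a 459-product Southeast Asian market, per-subcategory
#' lognormal nutrient distributions anchored to the published median [IQR]
#' values, violation prevalences matching the published failure proportions,
#' and declaration missingness matching the published "n declaring" counts.
#'
#' @param n_products number of products to generate.
#' @param category_mix probability vector over the nine subcategories (must
#'   sum to 1; names must be the subcategory codes).
#' @param nutrient_anchors per-subcategory list of `c(median, q1, q3)` per
#'   nutrient (total_sugar, sodium, protein, total_fat, energy).
#' @param failure_prevalences named probabilities of injecting a violation
#'   per nutrient requirement.
#' @param labelling_fail_prevalences named probabilities per labelling
#'   requirement.
#' @param missingness_rates named probabilities a nutrient declaration is
#'   absent.
#' @param spout_rate probability a pureed product has a spout.
#' @param seed integer seed; all randomness flows from this single stream.
#' @return a validated `cpcf_market_config` list.
#' @export
market_config <- function(n_products = 459,
                          category_mix = NULL,
                          nutrient_anchors = DEFAULT_NUTRIENT_ANCHORS,
                          failure_prevalences = DEFAULT_FAILURE_PREVALENCES,
                          labelling_fail_prevalences = DEFAULT_LABELLING_FAIL_PREVALENCES,
                          missingness_rates = DEFAULT_MISSINGNESS,
                          spout_rate = DEFAULT_SPOUT_RATE,
                          seed = 1L) {
  if (is.null(category_mix)) {
    category_mix <- stats::setNames(
      c(42, 245, 25, 22, 9, 51, 30, 34, 1) / 459, SUBCATEGORIES)
  }
  stopifnot(
    n_products >= 0,
    setequal(names(category_mix), SUBCATEGORIES),
    abs(sum(category_mix) - 1) < 1e-8,
    all(category_mix >= 0),
    all(failure_prevalences >= 0 & failure_prevalences <= 1),
    all(labelling_fail_prevalences >= 0 & labelling_fail_prevalences <= 1),
    all(missingness_rates >= 0 & missingness_rates <= 1),
    spout_rate >= 0 && spout_rate <= 1
  )
  miss_req <- setdiff(NUTRIENT_REQUIREMENTS, names(failure_prevalences))
  if (length(miss_req)) stop("failure_prevalences lacks: ", paste(miss_req, collapse = ", "))
  miss_lab <- setdiff(names(LABELLING_REQUIREMENTS), names(labelling_fail_prevalences))
  if (length(miss_lab)) stop("labelling_fail_prevalences lacks: ",
                             paste(miss_lab, collapse = ", "))
  # a vegetable-only puree with any fruit ingredient would no longer satisfy
  # its own composition definition: that intent combination is infeasible
  fruit_veg_only <- if ("fruit_content_vegetable_only_puree" %in% names(failure_prevalences)) {
    failure_prevalences[["fruit_content_vegetable_only_puree"]]
  } else NA
  if (!is.na(fruit_veg_only) && fruit_veg_only > 0) {
    stop("infeasible intent: fruit-content violations cannot be injected into ",
         "vegetable_only_puree (any fruit ingredient voids the subcategory)")
  }
  structure(list(
    n_products = as.integer(n_products),
    category_mix = category_mix[SUBCATEGORIES],
    nutrient_anchors = nutrient_anchors,
    failure_prevalences = failure_prevalences,
    labelling_fail_prevalences = labelling_fail_prevalences,
    missingness_rates = missingness_rates,
    spout_rate = spout_rate,
    seed = as.integer(seed)
  ), class = "cpcf_market_config")
}

# Lognormal parameters from a median and quartile anchor; sigma from the
# quartile ratio (qnorm(0.75) - qnorm(0.25) = 1.349 standard deviations).
# Degenerate or zero quartiles fall back to sigma = 0.4.
lognormal_params <- function(anchor) {
  m <- anchor[1]; q1 <- anchor[2]; q3 <- anchor[3]
  mu <- log(max(m, 1e-6))
  sigma <- if (is.na(q1) || is.na(q3) || q1 <= 0 || q3 <= q1) 0.4
    else log(q3 / q1) / (2 * stats::qnorm(0.75))
  c(mu = mu, sigma = sigma)
}

# One lognormal draw satisfying `cond`; after `tries` rejections fall back to
# a value just inside the admissible region.
draw_conditional <- function(mu, sigma, cond = NULL, fallback = NULL, tries = 100) {
  for (i in seq_len(tries)) {
    v <- stats::rlnorm(1, mu, sigma)
    if (is.null(cond) || cond(v)) return(v)
  }
  fallback
}

rbern <- function(p) stats::runif(1) < p

# ---- label construction per subcategory ------------------------------------

# Build name + ingredient list realizing the intended subcategory and the
# added-sugar / fruit-content / named-protein-weight intents. Percentages
# always sum to 100 and are always stated (unstated-percentage behaviour is
# exercised by unit tests, not by the generator).
build_label_body <- function(subcat, sugar_violation, fruit_violation,
                             protein_weight_fail, with_water) {
  sugar_pct <- if (sugar_violation) 2 else 0
  sugar_row <- if (sugar_violation) list(c("sugar", "2")) else list()
  out <- switch(subcat,
    dairy_dessert = {
      fruit_pct <- if (fruit_violation) 8 else 4
      water_pct <- if (with_water) 10 else 0
      yog <- 100 - fruit_pct - water_pct - 8 - sugar_pct
      rows <- c(list(c("whole milk yogurt", yog), c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)),
                list(c("oats", 8)), sugar_row)
      list(name = "Apple and oat yogurt dessert", rows = rows)
    },
    fruit_puree = {
      water_pct <- if (with_water) 8 else 0
      rice <- 8 - water_pct  # rice takes the slack so percentages sum to 100
      rows <- c(list(c("apple", 62 - sugar_pct), c("banana", 30)),
                if (with_water) list(c("water", water_pct)),
                if (rice > 0) list(c("rice", rice)), sugar_row)
      list(name = "Apple and banana puree", rows = rows)
    },
    vegetable_only_puree = {
      oil <- if (sugar_violation) 3 else 5
      water_pct <- if (with_water) 15 else 0
      carrot <- 95 - 20 - water_pct
      rows <- c(list(c("carrot", carrot), c("peas", 20)),
                if (with_water) list(c("water", water_pct)),
                list(c("rapeseed oil", oil)), sugar_row)
      list(name = "Carrot and pea puree", rows = rows)
    },
    vegetable_puree_with_cereal = {
      fruit_pct <- if (fruit_violation) 8 else 0
      water_pct <- if (with_water) 7 else 0
      tomato <- 100 - 25 - 15 - fruit_pct - water_pct - sugar_pct
      rows <- c(list(c("tomato", tomato), c("rice", 25), c("carrot", 15)),
                if (fruit_violation) list(c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)), sugar_row)
      list(name = "Tomato and rice medley", rows = rows)
    },
    pureed_meal_cheese = {
      fruit_pct <- if (fruit_violation) 8 else 0
      water_pct <- if (with_water) 14 else 0
      cauli <- 100 - 20 - 12 - fruit_pct - water_pct - sugar_pct
      rows <- c(list(c("cauliflower", cauli), c("macaroni", 20),
                     c("cheese", 12)),
                if (fruit_violation) list(c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)), sugar_row)
      list(name = "Cauliflower cheese bake", rows = rows)
    },
    pureed_meal_meat_fish = {
      meat <- if (protein_weight_fail) 6 else 12
      fruit_pct <- if (fruit_violation) 8 else 0
      water_pct <- if (with_water) 12 else 0
      potato <- 100 - meat - 20 - fruit_pct - water_pct - sugar_pct
      rows <- c(list(c("chicken", meat), c("potato", potato), c("carrot", 20)),
                if (fruit_violation) list(c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)), sugar_row)
      list(name = "Chicken and potato pie", rows = rows)
    },
    pureed_meal_no_meat_fish = {
      meat <- if (protein_weight_fail) 5 else 10
      fruit_pct <- if (fruit_violation) 8 else 0
      water_pct <- if (with_water) 12 else 0
      carrot <- 100 - meat - 25 - fruit_pct - water_pct - sugar_pct
      rows <- c(list(c("carrot", carrot), c("potato", 25), c("lamb", meat)),
                if (fruit_violation) list(c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)), sugar_row)
      list(name = "Carrot potato and lamb hotpot", rows = rows)
    },
    chunky_meal_meat_fish_cheese = {
      fish <- if (protein_weight_fail) 6 else 12
      fruit_pct <- if (fruit_violation) 8 else 0
      water_pct <- if (with_water) 13 else 0
      pea <- 100 - fish - 25 - fruit_pct - water_pct - sugar_pct
      rows <- c(list(c("salmon", fish), c("rice", 25), c("peas", pea)),
                if (fruit_violation) list(c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)), sugar_row)
      list(name = "Salmon and pea risotto", rows = rows)
    },
    chunky_meal_vegetable = {
      fruit_pct <- if (fruit_violation) 8 else 0
      water_pct <- if (with_water) 12 else 0
      carrot <- 100 - 25 - 15 - fruit_pct - water_pct - sugar_pct
      rows <- c(list(c("carrot", carrot), c("potato", 25), c("beans", 15)),
                if (fruit_violation) list(c("apple", fruit_pct)),
                if (with_water) list(c("water", water_pct)), sugar_row)
      list(name = "Garden vegetable casserole", rows = rows)
    },
    stop("unknown subcategory: ", subcat)
  )
  list(name = out$name, ingredients = data.frame(
    name = vapply(out$rows, `[[`, character(1), 1),
    pct_by_weight = as.numeric(vapply(out$rows, `[[`, character(1), 2)),
    stringsAsFactors = FALSE
  ))
}

#' Generate a synthetic market with known ground truth
#'
#' Seeded and reproducible: each product's ingredients, name, texture and
#' nutrient panel are constructed so the categorizer yields the intended
#' subcategory and injected violations trip exactly the intended
#' requirements. Fruit-content violations are never injected into
#' vegetable-only purees (any fruit ingredient would void that subcategory's
#' own definition), and nutrient declarations drawn as missing make the
#' affected requirement fail with reason "undeclared", mirroring the
#' assessment rule.
#'
#' @param config a `cpcf_market_config` from [market_config()].
#' @param profile threshold profile used to condition the injected values.
#' @param ingredient_lexicon ingredient lexicon (loaded once and reused).
#' @return a list with `products` (a `cpcf_products` list) and
#'   `ground_truth` (a tibble: one row per product with the intended
#'   subcategory, the intended status of every nutrient and labelling
#'   requirement, the intended high-sugar state and the implied overall
#'   verdicts).
#' @export
generate_market <- function(config = market_config(), profile = load_profile(),
                            ingredient_lexicon = load_ingredient_lexicon()) {
  stopifnot(inherits(config, "cpcf_market_config"))
  set.seed(config$seed)
  n <- config$n_products
  subcats <- if (n > 0) sample(SUBCATEGORIES, n, replace = TRUE,
                               prob = config$category_mix) else character()
  prev <- config$failure_prevalences
  lab_prev <- config$labelling_fail_prevalences
  miss <- config$missingness_rates

  products <- vector("list", n)
  gt_rows <- vector("list", n)

  for (i in seq_len(n)) {
    sc <- subcats[i]
    th <- profile$subcategories[[sc]]
    anchors <- config$nutrient_anchors[[sc]]
    chunky <- sc %in% CHUNKY_SUBCATEGORIES
    meal <- sc %in% MEAL_SUBCATEGORIES

    # --- nutrient intents -----------------------------------------------
    sugar_violation <- rbern(prev[["added_sugar"]])
    fruit_rule <- th$fruit_rule %||% "none"
    fruit_violation <- fruit_rule != "none" && sc != "vegetable_only_puree" &&
      rbern(prev[["fruit_content"]])
    energy_violation <- !is.null(th$energy_density_min) && rbern(prev[["energy_density"]])
    sodium_violation <- rbern(prev[["sodium"]])
    fat_violation <- rbern(prev[["total_fat"]])
    protein_violation <- meal && rbern(prev[["protein"]])
    protein_weight_mode <- protein_violation &&
      !is.null(th$named_protein_min_pct_weight) && rbern(0.5)

    miss_energy <- rbern(miss[["energy"]])
    miss_sugar <- rbern(miss[["total_sugar"]])
    miss_sodium <- rbern(miss[["sodium"]])
    miss_fat <- rbern(miss[["total_fat"]])
    miss_protein <- rbern(miss[["protein"]])

    with_water <- rbern(0.6)
    body <- build_label_body(sc, sugar_violation, fruit_violation,
                             protein_weight_mode, with_water)

    # --- nutrient values conditioned on intents ---------------------------
    ep <- lognormal_params(anchors$energy)
    energy <- if (miss_energy) NA_real_
      else if (is.null(th$energy_density_min)) {
        draw_conditional(ep["mu"], ep["sigma"], function(v) v > 20, 70)
      } else if (energy_violation) {
        draw_conditional(ep["mu"], ep["sigma"], function(v) v < th$energy_density_min,
                         th$energy_density_min * 0.8)
      } else {
        draw_conditional(ep["mu"], ep["sigma"], function(v) v >= th$energy_density_min,
                         th$energy_density_min * 1.2)
      }

    sp <- lognormal_params(anchors$total_sugar)
    sugar <- if (miss_sugar) NA_real_ else stats::rlnorm(1, sp["mu"], sp["sigma"])

    na_limit <- th$sodium_max
    if (!is.null(th$sodium_max_if_cheese_named) &&
        "cheese" %in% named_food_classes(body$name, ingredient_lexicon)) {
      na_limit <- th$sodium_max_if_cheese_named
    }
    nap <- lognormal_params(anchors$sodium)
    sodium <- if (miss_sodium) NA_real_
      else if (is.na(energy)) stats::rlnorm(1, nap["mu"], nap["sigma"])
      else {
        bound <- na_limit * min(1, energy / 100)
        if (sodium_violation) {
          draw_conditional(nap["mu"], nap["sigma"], function(v) v >= bound, bound * 1.5)
        } else {
          draw_conditional(nap["mu"], nap["sigma"], function(v)
            v < na_limit && v * 100 / energy < na_limit, bound * 0.5)
        }
      }

    fp <- lognormal_params(anchors$total_fat)
    fat <- if (miss_fat) NA_real_
      else if (is.na(energy)) stats::rlnorm(1, fp["mu"], fp["sigma"])
      else {
        bound <- th$fat_max * energy / 100
        if (fat_violation) {
          draw_conditional(fp["mu"], fp["sigma"], function(v) v > bound, bound * 1.5)
        } else {
          draw_conditional(fp["mu"], fp["sigma"], function(v) v <= bound, bound * 0.5)
        }
      }

    pp <- lognormal_params(anchors$protein)
    protein <- if (miss_protein) NA_real_
      else if (!meal || is.na(energy)) stats::rlnorm(1, pp["mu"], pp["sigma"])
      else {
        bound <- th$protein_min * energy / 100
        if (protein_violation && !protein_weight_mode) {
          draw_conditional(pp["mu"], pp["sigma"], function(v) v < bound, bound * 0.6)
        } else {
          draw_conditional(pp["mu"], pp["sigma"], function(v) v >= bound, bound * 1.3)
        }
      }

    # report energy in kJ for some products to exercise unit conversion
    in_kj <- !is.na(energy) && rbern(0.3)
    panel <- nutrient_panel(
      energy = if (is.na(energy)) NA else if (in_kj) energy * 4.184 else energy,
      energy_unit = if (is.na(energy)) NA else if (in_kj) "kJ" else "kcal",
      total_sugar = sugar, sodium = sodium, total_fat = fat, protein = protein
    )

    # --- labelling intents -----------------------------------------------
    lab_fail <- vapply(names(LABELLING_REQUIREMENTS), function(r) rbern(lab_prev[[r]]),
                       logical(1))
    has_fruit <- any(classify_ingredient(body$ingredients$name,
                                         ingredient_lexicon) == "fruit")
    has_spout <- !chunky && rbern(config$spout_rate)
    protein_lab_applicable <- sc %in% c("pureed_meal_meat_fish",
                                        "pureed_meal_no_meat_fish",
                                        "chunky_meal_meat_fish_cheese",
                                        "chunky_meal_vegetable")

    claims <- do.call(rbind, lapply(CLAIM_CLASSES, function(cc) {
      id <- switch(cc,
                   nonpermitted_compositional = "cl_no_nonpermitted_compositional",
                   nutrient_content = "cl_no_nutrient_content",
                   nutrient_function = "cl_no_nutrient_function",
                   disease_risk_reduction = "cl_no_disease_risk_reduction",
                   other = "cl_no_other")
      if (!lab_fail[[id]]) return(NULL)
      pool <- CLAIM_TEXT_POOL[[cc]]
      data.frame(text = pool[sample.int(length(pool), 1)],
                 claim_class = NA_character_, stringsAsFactors = FALSE)
    }))

    min_age_missing <- lab_fail[["bf_min_age_6mo"]] && rbern(0.25)
    features <- label_features(
      min_age_months_stated = if (min_age_missing) NA
        else if (lab_fail[["bf_min_age_6mo"]]) 4
        else sample(c(6, 8, 12), 1),
      marketed_under_6mo = lab_fail[["bf_not_marketed_under_6mo"]],
      breastfeeding_2yr_message = !lab_fail[["bf_breastfeeding_message"]],
      suggests_superiority_to_breastmilk = lab_fail[["bf_no_superiority_claim"]],
      recommends_bottle_feeding = lab_fail[["bf_no_bottle_feeding"]],
      claims = claims,
      name_reflects_ingredient_order = !lab_fail[["nc_name_reflects_order"]],
      pct_fruit_stated = if (has_fruit) !lab_fail[["nc_pct_fruit_stated"]] else NA,
      pct_water_stated = if (with_water) !lab_fail[["nc_pct_water_stated"]] else NA,
      pct_protein_stated = if (protein_lab_applicable)
        !lab_fail[["nc_pct_protein_stated"]] else NA,
      has_spout = has_spout,
      spout_no_suck_message = if (has_spout) !lab_fail[["sp_no_suck_message"]] else NA,
      spout_choke_warning = if (has_spout) !lab_fail[["sp_choke_warning"]] else NA,
      max_age_12mo_stated = if (!chunky) !lab_fail[["ar_max_age_12mo"]] else NA,
      texture = if (chunky) "chunky" else "pureed"
    )

    products[[i]] <- product_label(
      product_id = sprintf("SYN%05d", i),
      name = body$name, country = "SYN",
      ingredients = body$ingredients, panel = panel, features = features
    )

    # --- ground truth -----------------------------------------------------
    st <- function(applicable, fail) {
      if (!applicable) "not_applicable" else if (fail) "fail" else "pass"
    }
    energy_na <- is.na(energy)
    nutr <- c(
      added_sugar = st(TRUE, sugar_violation),
      fruit_content = st(fruit_rule != "none",
                         fruit_rule != "none" && fruit_violation),
      energy_density = st(!is.null(th$energy_density_min),
                          energy_violation || (!is.null(th$energy_density_min) && energy_na)),
      sodium = st(TRUE, sodium_violation || miss_sodium || energy_na),
      total_fat = st(TRUE, fat_violation || miss_fat || energy_na),
      protein = st(meal, protein_violation || (meal && (miss_protein || energy_na)))
    )
    hs <- if (is.na(sugar) || energy_na) "sugar_undeclared"
      else if (sugar * 4 / energy * 100 >= th$high_sugar_pct_energy) "warning_required"
      else "not_required"
    lab <- vapply(names(LABELLING_REQUIREMENTS), function(r) {
      applicable <- switch(r,
        nc_pct_fruit_stated = has_fruit,
        nc_pct_water_stated = with_water,
        nc_pct_protein_stated = protein_lab_applicable,
        sp_no_suck_message = has_spout,
        sp_choke_warning = has_spout,
        ar_max_age_12mo = !chunky,
        TRUE)
      st(applicable, lab_fail[[r]])
    }, character(1))
    applicable_n <- nutr[nutr != "not_applicable"]
    applicable_l <- lab[lab != "not_applicable"]
    gt_rows[[i]] <- c(
      list(product_id = sprintf("SYN%05d", i), subcategory = sc),
      as.list(stats::setNames(nutr, paste0("nutr_", names(nutr)))),
      list(nutrient_overall_pass = all(applicable_n == "pass"), high_sugar = hs),
      as.list(stats::setNames(lab, paste0("lab_", names(lab)))),
      list(labelling_overall_pass = all(applicable_l == "pass"))
    )
  }

  ground_truth <- tibble::as_tibble(do.call(rbind, lapply(gt_rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE))))
  list(products = structure(products, class = "cpcf_products"),
       ground_truth = ground_truth)
}
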
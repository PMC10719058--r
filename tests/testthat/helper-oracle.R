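# Independent straight-line oracles. These re-implement the subcategory
# definitions and the six nutrient rules directly from the printed
# requirement text, with their own hard-coded ingredient vocabulary and
# threshold table, deliberately sharing no code or configuration with the
# package implementation.

ORACLE_VOCAB <- c(
  "whole milk yogurt" = "dairy", yogurt = "dairy", custard = "dairy",
  apple = "fruit", banana = "fruit", pear = "fruit", mango = "fruit",
  carrot = "vegetable", tomato = "vegetable", cauliflower = "vegetable",
  potato = "vegetable", spinach = "vegetable", pumpkin = "vegetable",
  peas = "legume", lentils = "legume", beans = "legume",
  rice = "cereal", oats = "cereal", macaroni = "cereal", pasta = "cereal",
  quinoa = "pseudocereal", buckwheat = "pseudocereal",
  chicken = "meat", beef = "meat", lamb = "meat",
  salmon = "fish", cod = "fish", tuna = "fish",
  cheese = "cheese", cheddar = "cheese",
  water = "water",
  "rapeseed oil" = "oil_fat", "olive oil" = "oil_fat",
  sugar = "sugar_sweetener", honey = "sugar_sweetener"
)

oracle_class <- function(nm) {
  nm <- tolower(trimws(nm))
  if (nm %in% names(ORACLE_VOCAB)) unname(ORACLE_VOCAB[[nm]]) else "other"
}

# First vocabulary food word in a product name, scanning left to right.
oracle_first_food <- function(name) {
  words <- strsplit(tolower(gsub("[^a-z ]", " ", tolower(name))), " +")[[1]]
  for (w in words) {
    if (w %in% names(ORACLE_VOCAB)) return(unname(ORACLE_VOCAB[[w]]))
    if (w == "cheesy") return("cheese")
  }
  NA_character_
}

# Direct evaluation of the nine subcategory definitions. Returns the code, or
# "error" where no puree definition applies.
oracle_categorize <- function(ingredients, name, texture) {
  cls <- vapply(ingredients$name, oracle_class, character(1))
  pct <- ingredients$pct_by_weight
  ff <- oracle_first_food(name)
  if (texture == "chunky") {
    if (!is.na(ff) && ff %in% c("meat", "fish")) return("chunky_meal_meat_fish_cheese")
    return("chunky_meal_vegetable")
  }
  if (any(cls %in% c("meat", "fish"))) {
    if (!is.na(ff) && ff %in% c("meat", "fish")) return("pureed_meal_meat_fish")
    return("pureed_meal_no_meat_fish")
  }
  if (grepl("chees", tolower(name))) return("pureed_meal_cheese")
  sums <- sapply(unique(cls), function(k) sum(pct[cls == k]))
  all_stated <- !anyNA(pct)
  largest <- if (all_stated) {
    mx <- names(sums)[sums == max(sums)]
    if (length(mx) > 1) cls[cls %in% mx][1] else mx
  } else cls[1]
  if (largest == "dairy") return("dairy_dessert")
  if (all_stated) {
    vw <- sum(pct[cls %in% c("vegetable", "legume", "water")])
    rest <- sum(pct[!cls %in% c("vegetable", "legume", "water")])
    if (vw >= 95 && !any(cls == "fruit") && rest <= 5) return("vegetable_only_puree")
    cer <- sum(pct[cls %in% c("cereal", "pseudocereal")])
    if (largest %in% c("vegetable", "legume", "cereal", "pseudocereal") && cer > 5) {
      return("vegetable_puree_with_cereal")
    }
  }
  if (largest == "fruit") return("fruit_puree")
  "error"
}

# Threshold table re-typed from the printed requirement definitions.
ORACLE_THRESHOLDS <- list(
  dairy_dessert = list(e = 60, na = 50, na_ch = NA, fat = 4.5, pro = NA, w = NA, fruit = "max5", hs = 40),
  fruit_puree = list(e = 60, na = 50, na_ch = NA, fat = 4.5, pro = NA, w = NA, fruit = "none", hs = 30),
  vegetable_only_puree = list(e = 60, na = 50, na_ch = NA, fat = 4.5, pro = NA, w = NA, fruit = "nofruit", hs = 30),
  vegetable_puree_with_cereal = list(e = 60, na = 50, na_ch = NA, fat = 4.5, pro = NA, w = NA, fruit = "nofruit", hs = 20),
  pureed_meal_cheese = list(e = 60, na = 100, na_ch = NA, fat = 6, pro = 3, w = NA, fruit = "max5", hs = 15),
  pureed_meal_meat_fish = list(e = 60, na = 50, na_ch = 100, fat = 6, pro = 4, w = 10, fruit = "max5", hs = 15),
  pureed_meal_no_meat_fish = list(e = 60, na = 50, na_ch = 100, fat = 4.5, pro = 3, w = 8, fruit = "max5", hs = 15),
  chunky_meal_meat_fish_cheese = list(e = NA, na = 50, na_ch = 100, fat = 6, pro = 4, w = 10, fruit = "max5", hs = 15),
  chunky_meal_vegetable = list(e = NA, na = 50, na_ch = 100, fat = 4.5, pro = 3, w = NA, fruit = "max5", hs = 15)
)

# Straight-line re-computation of the six nutrient requirement statuses plus
# the high-sugar tri-state, from the label alone.
oracle_assess <- function(p, subcat) {
  th <- ORACLE_THRESHOLDS[[subcat]]
  cls <- vapply(p$ingredients$name, oracle_class, character(1))
  pct <- p$ingredients$pct_by_weight
  nm <- tolower(p$name)

  energy <- p$panel$energy
  if (!is.na(energy) && identical(p$panel$energy_unit, "kJ")) energy <- energy / 4.184

  # added sugar: sweetener vocab plus the juice rule minus lemon/lime
  low <- tolower(p$ingredients$name)
  sweet <- cls == "sugar_sweetener" |
    grepl("syrup|honey|nectar|molasses|stevia|sucralose|aspartame|saccharin|acesulfame", low) |
    (grepl("juice", low) & !grepl("lemon|lime", low))
  added_sugar <- if (any(sweet)) "fail" else "pass"

  fruit_pct <- pct[cls == "fruit"]
  fruit <- if (th$fruit == "none") "not_applicable"
    else if (length(fruit_pct) == 0) "pass"
    else if (th$fruit == "nofruit") "fail"
    else if (anyNA(fruit_pct)) "fail"
    else if (sum(fruit_pct) <= 5) "pass" else "fail"

  edens <- if (is.na(th$e)) "not_applicable"
    else if (is.na(energy)) "fail"
    else if (energy >= th$e) "pass" else "fail"

  na_lim <- th$na
  if (!is.na(th$na_ch) && grepl("chees", nm)) na_lim <- th$na_ch
  na100g <- if (!is.na(p$panel$sodium)) p$panel$sodium
    else if (!is.na(p$panel$salt)) p$panel$salt * 400 else NA
  sodium <- if (is.na(na100g) || is.na(energy)) "fail"
    else if (na100g < na_lim && na100g * 100 / energy < na_lim) "pass" else "fail"

  fat <- if (is.na(p$panel$total_fat) || is.na(energy)) "fail"
    else if (p$panel$total_fat * 100 / energy <= th$fat) "pass" else "fail"

  protein <- if (is.na(th$pro)) "not_applicable"
    else if (is.na(p$panel$protein) || is.na(energy)) "fail"
    else {
      ok <- p$panel$protein * 100 / energy >= th$pro
      named <- unique(cls[cls %in% c("meat", "fish")])
      named <- named[vapply(named, function(k) {
        any(vapply(p$ingredients$name[cls == k], function(x)
          grepl(tolower(trimws(x)), nm, fixed = TRUE), logical(1)))
      }, logical(1))]
      if (!is.na(th$w) && length(named)) {
        wp <- pct[cls %in% named]
        if (anyNA(wp)) ok <- FALSE else ok <- ok && sum(wp) >= th$w
      }
      if (ok) "pass" else "fail"
    }

  statuses <- c(added_sugar = added_sugar, fruit_content = fruit,
                energy_density = edens, sodium = sodium, total_fat = fat,
                protein = protein)
  hs <- if (is.na(p$panel$total_sugar) || is.na(energy)) "sugar_undeclared"
    else if (p$panel$total_sugar * 4 / energy * 100 >= th$hs) "warning_required"
    else "not_required"
  list(statuses = statuses,
       overall = all(statuses[statuses != "not_applicable"] == "pass"),
       high_sugar = hs)
}
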
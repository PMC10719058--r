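#' Unit conversions used by the nutrient requirements
#'
#' `salt_to_sodium()` converts a salt declaration (g/100 g) to sodium
#' (mg/100 g) by dividing by 2.5 (and scaling g to mg), the standard
#' fallback when only salt is declared. `energy_kcal_per_100g()` returns the
#' declared energy in kcal/100 g, converting a kJ declaration at
#' 4.184 kJ/kcal. `per_100kcal()` rescales a per-100 g amount to per
#' 100 kcal. `pct_energy_from_sugar()` is the percentage of energy
#' contributed by total sugar using the Atwater carbohydrate factor of
#' 4 kcal/g. Missing inputs propagate as `NA` ("undeclared").
#'
#' @param salt salt in g/100 g (non-negative).
#' @return `salt_to_sodium()`: sodium in mg/100 g.
#' @export
salt_to_sodium <- function(salt) {
  if (any(!is.na(salt) & salt < 0)) stop("salt must be non-negative")
  salt * 1000 / 2.5
}

ATWATER <- c(protein = 4, carbohydrate = 4, fat = 9)  # kcal/g
KJ_PER_KCAL <- 4.184

#' @rdname salt_to_sodium
#' @param panel a `cpcf_panel` (see [nutrient_panel()]).
#' @export
energy_kcal_per_100g <- function(panel) {
  e <- panel$energy
  if (is_missing_value(e)) return(NA_real_)
  unit <- panel$energy_unit
  if (is_missing_value(unit)) return(NA_real_)
  switch(unit, kcal = e, kJ = e / KJ_PER_KCAL,
         stop("unknown energy unit: ", unit))
}

#' @rdname salt_to_sodium
#' @param value amount per 100 g.
#' @param energy energy density in kcal/100 g.
#' @export
per_100kcal <- function(value, energy) {
  ifelse(is.na(value) | is.na(energy) | energy <= 0, NA_real_,
         value * 100 / energy)
}

#' @rdname salt_to_sodium
#' @param sugar total sugar in g/100 g.
#' @export
pct_energy_from_sugar <- function(sugar, energy) {
  ifelse(is.na(sugar) | is.na(energy) | energy <= 0, NA_real_,
         sugar * ATWATER[["carbohydrate"]] / energy * 100)
}

# Sodium in mg/100 g from the panel: a sodium declaration wins; salt/2.5 is
# the fallback.
sodium_mg_per_100g <- function(panel) {
  if (!is_missing_value(panel$sodium)) return(panel$sodium)
  if (!is_missing_value(panel$salt)) return(salt_to_sodium(panel$salt))
  NA_real_
}

# Atwater-recomputed energy from the declared macros. The label schema
# carries no total-carbohydrate field, so sugar stands in for carbohydrate
# and the result is a lower bound on true energy; offered only as a
# sensitivity option for the high-sugar computation.
atwater_energy_kcal <- function(panel) {
  if (is_missing_value(panel$protein) || is_missing_value(panel$total_fat) ||
      is_missing_value(panel$total_sugar)) return(NA_real_)
  ATWATER[["protein"]] * panel$protein + ATWATER[["fat"]] * panel$total_fat +
    ATWATER[["carbohydrate"]] * panel$total_sugar
}

req_result <- function(id, status, reason, value = NA_real_, unit = NA_character_) {
  data.frame(requirement_id = id, status = status, reason = reason,
             value = value, unit = unit, stringsAsFactors = FALSE)
}

#' Assess a product against the six nutrient-composition requirements
#'
#' Evaluates, with the per-subcategory thresholds of the loaded profile:
#' no added sugars/sweeteners (ingredient-list lexicon match), fruit content
#' (at most 5% fruit by weight, or no added fruit, per subcategory), energy
#' density (at least 60 kcal/100 g where applicable), sodium (strictly below
#' the limit both per 100 kcal and per 100 g, with a relaxed limit when
#' cheese is named front-of-pack in the subcategories that allow it), total
#' fat (at most the limit per 100 kcal) and protein (at least the minimum
#' per 100 kcal; where a meat/fish protein source is named in the product
#' name its summed ingredient weight must also reach the named-source
#' minimum). Comparison directions follow the printed rules: `>=`/`<=`
#' thresholds pass on ties, `<` thresholds fail on ties.
#'
#' A product without the declarations needed for an applicable requirement
#' fails that requirement with reason `"undeclared"`. The overall verdict is
#' the AND over applicable requirements. The high-sugar front-of-pack state
#' (percentage of energy from total sugar at or above the subcategory
#' threshold) is reported alongside but never affects the overall verdict.
#'
#' @param p a `cpcf_product`.
#' @param subcategory subcategory code; computed with [categorize()] when
#'   missing.
#' @param profile threshold profile (see [load_profile()]).
#' @param sweetener_lexicon,ingredient_lexicon lexicons.
#' @param energy_source `"declared"` (default) uses the declared energy for
#'   the high-sugar percentage; `"atwater"` recomputes energy from declared
#'   macros (a lower bound, since non-sugar carbohydrate is not declared).
#' @return a `cpcf_nutrient_assessment`: list with `results` (data frame of
#'   six requirement rows: id, status, reason, measured value),
#'   `overall_pass`, and `high_sugar` (one of `"warning_required"`,
#'   `"not_required"`, `"sugar_undeclared"`).
#' @export
assess_nutrients <- function(p, subcategory = NULL,
                             profile = load_profile(),
                             sweetener_lexicon = load_sweetener_lexicon(),
                             ingredient_lexicon = load_ingredient_lexicon(),
                             energy_source = c("declared", "atwater")) {
  energy_source <- match.arg(energy_source)
  subcategory <- as.character(subcategory %||% categorize(p, ingredient_lexicon))
  th <- profile$subcategories[[subcategory]]
  if (is.null(th)) stop("no thresholds for subcategory '", subcategory, "'")

  classes <- classify_ingredient(p$ingredients$name, ingredient_lexicon)
  energy <- energy_kcal_per_100g(p$panel)

  # (1) no added sugars/sweeteners
  hits <- find_added_sugars(p$ingredients, sweetener_lexicon)
  r_sugar <- if (nrow(hits) > 0) {
    req_result("added_sugar", "fail", "lexicon_hit", nrow(hits), "ingredients")
  } else req_result("added_sugar", "pass", "ok", 0, "ingredients")

  # (2) fruit content
  fruit_idx <- which(classes == "fruit")
  r_fruit <- if (identical(th$fruit_rule, "none") || is.null(th$fruit_rule)) {
    req_result("fruit_content", "not_applicable", "not_applicable")
  } else if (length(fruit_idx) == 0) {
    req_result("fruit_content", "pass", "ok", 0, "% weight")
  } else if (identical(th$fruit_rule, "no_added_fruit")) {
    req_result("fruit_content", "fail", "fruit_present", length(fruit_idx), "ingredients")
  } else {  # max_5pct_weight
    pcts <- p$ingredients$pct_by_weight[fruit_idx]
    if (anyNA(pcts)) {
      req_result("fruit_content", "fail", "undeclared")
    } else if (sum(pcts) <= 5) {
      req_result("fruit_content", "pass", "ok", sum(pcts), "% weight")
    } else {
      req_result("fruit_content", "fail", "threshold_exceeded", sum(pcts), "% weight")
    }
  }

  # (3) energy density
  r_energy <- if (is.null(th$energy_density_min)) {
    req_result("energy_density", "not_applicable", "not_applicable")
  } else if (is.na(energy)) {
    req_result("energy_density", "fail", "undeclared")
  } else if (energy >= th$energy_density_min) {
    req_result("energy_density", "pass", "ok", energy, "kcal/100 g")
  } else {
    req_result("energy_density", "fail", "below_threshold", energy, "kcal/100 g")
  }

  # (4) sodium: strict < limit per 100 kcal AND per 100 g
  named <- named_food_classes(p$name, ingredient_lexicon)
  na_limit <- th$sodium_max
  if (!is.null(th$sodium_max_if_cheese_named) && "cheese" %in% named) {
    na_limit <- th$sodium_max_if_cheese_named
  }
  sodium_100g <- sodium_mg_per_100g(p$panel)
  sodium_100kcal <- per_100kcal(sodium_100g, energy)
  r_sodium <- if (is.na(sodium_100g) || is.na(sodium_100kcal)) {
    req_result("sodium", "fail", "undeclared", sodium_100g, "mg/100 g")
  } else if (sodium_100g < na_limit && sodium_100kcal < na_limit) {
    req_result("sodium", "pass", "ok", sodium_100kcal, "mg/100 kcal")
  } else {
    req_result("sodium", "fail", "threshold_exceeded", sodium_100kcal, "mg/100 kcal")
  }

  # (5) total fat: <= limit per 100 kcal
  fat_100kcal <- per_100kcal(p$panel$total_fat, energy)
  r_fat <- if (is.na(fat_100kcal)) {
    req_result("total_fat", "fail", "undeclared")
  } else if (fat_100kcal <= th$fat_max) {
    req_result("total_fat", "pass", "ok", fat_100kcal, "g/100 kcal")
  } else {
    req_result("total_fat", "fail", "threshold_exceeded", fat_100kcal, "g/100 kcal")
  }

  # (6) protein: >= minimum per 100 kcal, plus the named-source weight floor
  r_protein <- if (is.null(th$protein_min)) {
    req_result("protein", "not_applicable", "not_applicable")
  } else {
    protein_100kcal <- per_100kcal(p$panel$protein, energy)
    if (is.na(protein_100kcal)) {
      req_result("protein", "fail", "undeclared")
    } else {
      value_ok <- protein_100kcal >= th$protein_min
      weight_status <- "pass"
      named_protein <- intersect(named, c("meat", "fish"))
      if (!is.null(th$named_protein_min_pct_weight) && length(named_protein)) {
        idx <- which(classes %in% named_protein)
        pcts <- p$ingredients$pct_by_weight[idx]
        weight_status <- if (length(idx) == 0 || anyNA(pcts)) "undeclared"
          else if (sum(pcts) >= th$named_protein_min_pct_weight) "pass"
          else "below_threshold"
      }
      if (weight_status == "undeclared") {
        req_result("protein", "fail", "undeclared", protein_100kcal, "g/100 kcal")
      } else if (!value_ok || weight_status == "below_threshold") {
        req_result("protein", "fail", "below_threshold", protein_100kcal, "g/100 kcal")
      } else {
        req_result("protein", "pass", "ok", protein_100kcal, "g/100 kcal")
      }
    }
  }

  results <- rbind(r_sugar, r_fruit, r_energy, r_sodium, r_fat, r_protein)

  # high-sugar front-of-pack warning (reported separately, never part of the
  # pass/fail verdict)
  hs_energy <- if (energy_source == "declared") energy else atwater_energy_kcal(p$panel)
  pes <- pct_energy_from_sugar(p$panel$total_sugar, hs_energy)
  high_sugar <- if (is.na(pes)) "sugar_undeclared"
    else if (pes >= th$high_sugar_pct_energy) "warning_required"
    else "not_required"

  applicable <- results$status != "not_applicable"
  structure(list(
    subcategory = subcategory,
    results = results,
    overall_pass = all(results$status[applicable] == "pass"),
    high_sugar = high_sugar,
    pct_energy_from_sugar = pes
  ), class = "cpcf_nutrient_assessment")
}
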
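# Shared vocabulary and small numeric helpers.

SUBCATEGORIES <- c(
  "dairy_dessert",
  "fruit_puree",
  "vegetable_only_puree",
  "vegetable_puree_with_cereal",
  "pureed_meal_cheese",
  "pureed_meal_meat_fish",
  "pureed_meal_no_meat_fish",
  "chunky_meal_meat_fish_cheese",
  "chunky_meal_vegetable"
)

CHUNKY_SUBCATEGORIES <- c("chunky_meal_meat_fish_cheese", "chunky_meal_vegetable")

MEAL_SUBCATEGORIES <- c(
  "pureed_meal_cheese", "pureed_meal_meat_fish", "pureed_meal_no_meat_fish",
  "chunky_meal_meat_fish_cheese", "chunky_meal_vegetable"
)

INGREDIENT_CLASSES <- c(
  "dairy", "fruit", "vegetable", "legume", "cereal", "pseudocereal",
  "meat", "fish", "cheese", "water", "oil_fat", "sugar_sweetener", "other"
)

NUTRIENT_REQUIREMENTS <- c(
  "added_sugar", "fruit_content", "energy_density", "sodium", "total_fat", "protein"
)

LABELLING_REQUIREMENTS <- c(
  bf_min_age_6mo               = "breastfeeding",
  bf_not_marketed_under_6mo    = "breastfeeding",
  bf_breastfeeding_message     = "breastfeeding",
  bf_no_superiority_claim      = "breastfeeding",
  bf_no_bottle_feeding         = "breastfeeding",
  cl_no_nonpermitted_compositional = "claims",
  cl_no_nutrient_content       = "claims",
  cl_no_nutrient_function      = "claims",
  cl_no_disease_risk_reduction = "claims",
  cl_no_other                  = "claims",
  nc_name_reflects_order       = "clarity",
  nc_pct_fruit_stated          = "clarity",
  nc_pct_water_stated          = "clarity",
  nc_pct_protein_stated        = "clarity",
  sp_no_suck_message           = "spout",
  sp_choke_warning             = "spout",
  ar_max_age_12mo              = "age_restriction"
)

CLAIM_CLASSES <- c(
  "nonpermitted_compositional", "nutrient_content", "nutrient_function",
  "disease_risk_reduction", "other"
)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Decimal rounding where ties go up (0.05 -> 0.1), matching the convention
#' used for the printed percentage tables; `base::round()` rounds ties to
#' even, which would print 24.45 as 24.4.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

# Normalize free text for lexicon matching: lowercase, strip punctuation,
# collapse whitespace. Keeps letters/digits/spaces only.
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9%]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

# TRUE / FALSE / NA coercion tolerant of "true"/"yes"/"1" text and blanks.
as_tristate <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA)
  if (is.logical(x)) return(x[1])
  v <- tolower(trimws(as.character(x[1])))
  if (is.na(v) || v %in% c("", "na", "unknown")) return(NA)
  if (v %in% c("true", "t", "yes", "y", "1")) return(TRUE)
  if (v %in% c("false", "f", "no", "n", "0")) return(FALSE)
  NA
}

# Numeric coercion where blank/absent becomes NA without warnings.
as_num <- function(x) {
  if (is.null(x) || length(x) == 0) return(NA_real_)
  v <- suppressWarnings(as.numeric(x[1]))
  v
}

is_missing_value <- function(x) is.null(x) || length(x) == 0 || is.na(x[1])
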
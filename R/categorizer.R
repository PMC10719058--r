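# Subcategory assignment from ingredient composition, product name and
# texture. The nine subcategory definitions are only mutually exclusive under
# an ordering, applied here from most to least specific: texture first, then
# meat/fish presence and name tests, cheese-in-name, dairy-largest,
# vegetable-only composition, vegetable+cereal, fruit-largest.

# Sum of stated percentages per ingredient class. Returns NULL when any
# percentage is missing (composition sums then fall back to list order).
class_pct_sums <- function(ing, classes) {
  if (anyNA(ing$pct_by_weight)) return(NULL)
  tapply(ing$pct_by_weight, classes, sum)
}

# Class with the largest summed weight; with missing percentages the label
# convention (ingredients in descending weight) makes the first ingredient's
# class the largest. Ties break toward the earlier-listed ingredient.
largest_ingredient_class <- function(ing, classes) {
  sums <- class_pct_sums(ing, classes)
  if (is.null(sums)) return(classes[1])
  mx <- max(sums)
  tied <- names(sums)[sums >= mx - sqrt(.Machine$double.eps)]
  if (length(tied) == 1) return(tied)
  classes[classes %in% tied][1]
}

#' Assign a product to one of the nine puree/meal subcategories
#'
#' Applies the subcategory definitions in fixed precedence. Texture splits
#' chunky meals from purees; chunky products split on whether meat or fish is
#' the first food named in the product name. Pureed products are tested in
#' order: meat/fish in the ingredients (meal classes, split on the
#' first-named food), cheese named front-of-pack (cheese meal), dairy the
#' largest ingredient class (dairy dessert), the vegetable-only composition
#' test (vegetables/legumes plus water at least 95% of stated weight, no
#' fruit, at most 5% cereals and other ingredients), vegetables/legumes/
#' cereals largest with more than 5% cereal or pseudocereal (vegetable puree
#' with cereal), and fruit largest (fruit puree).
#'
#' "Largest" compares summed stated percentages per class; when any
#' percentage is unstated it falls back to the class of the first-listed
#' ingredient, and the 95%/5% composition tests evaluate false.
#'
#' @param p a `cpcf_product`.
#' @param lexicon ingredient lexicon (see [load_ingredient_lexicon()]).
#' @return the subcategory code (character scalar) with attribute `"rule"`
#'   recording which definition fired.
#' @export
categorize <- function(p, lexicon = load_ingredient_lexicon()) {
  ing <- p$ingredients
  if (nrow(ing) == 0) stop("product ", p$product_id, " has no ingredients")
  classes <- classify_ingredient(ing$name, lexicon)
  has_meat_fish <- any(classes %in% c("meat", "fish"))
  fnf <- first_named_food(p$name, lexicon)

  done <- function(code, rule) structure(code, rule = rule)

  if (p$features$texture == "chunky") {
    if (!is.na(fnf) && fnf %in% c("meat", "fish")) {
      return(done("chunky_meal_meat_fish_cheese", "chunky_meat_fish_first_in_name"))
    }
    return(done("chunky_meal_vegetable", "chunky_residual"))
  }

  if (has_meat_fish) {
    if (!is.na(fnf) && fnf %in% c("meat", "fish")) {
      return(done("pureed_meal_meat_fish", "meat_fish_first_in_name"))
    }
    return(done("pureed_meal_no_meat_fish", "meat_fish_not_first_in_name"))
  }

  if ("cheese" %in% named_food_classes(p$name, lexicon)) {
    return(done("pureed_meal_cheese", "cheese_in_name"))
  }

  largest <- largest_ingredient_class(ing, classes)
  if (largest == "dairy") {
    return(done("dairy_dessert", "dairy_largest"))
  }

  sums <- class_pct_sums(ing, classes)
  if (!is.null(sums)) {
    pct_of <- function(cl) sum(sums[names(sums) %in% cl])
    veg_water <- pct_of(c("vegetable", "legume", "water"))
    non_veg <- pct_of(setdiff(names(sums), c("vegetable", "legume", "water")))
    if (veg_water >= 95 && pct_of("fruit") == 0 && non_veg <= 5) {
      return(done("vegetable_only_puree", "vegetable_only_composition"))
    }
    cereal_pct <- pct_of(c("cereal", "pseudocereal"))
    if (largest %in% c("vegetable", "legume", "cereal", "pseudocereal") &&
        cereal_pct > 5) {
      return(done("vegetable_puree_with_cereal", "vegetable_largest_with_cereal"))
    }
  }

  if (largest == "fruit") {
    return(done("fruit_puree", "fruit_largest"))
  }

  stop("uncategorizable pureed product ", p$product_id,
       ": no meat/fish, no cheese in name, largest class '", largest,
       "' is not dairy or fruit, and the vegetable composition tests ",
       if (is.null(sums)) "could not be evaluated (unstated percentages)"
       else "evaluated false")
}

#' Categorize a list of products
#'
#' @param products a list of `cpcf_product`.
#' @inheritParams categorize
#' @return character vector of subcategory codes, named by product_id.
#' @export
categorize_products <- function(products, lexicon = load_ingredient_lexicon()) {
  out <- vapply(products, function(p) as.character(categorize(p, lexicon)), character(1))
  names(out) <- vapply(products, `[[`, character(1), "product_id")
  out
}
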
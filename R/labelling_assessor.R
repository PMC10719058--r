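#' Classify a label claim into one of the five claim classes
#'
#' Pattern-driven classification against the claim lexicon: disease
#' risk-reduction patterns are tried first, then nutrient function, nutrient
#' content and nonpermitted compositional patterns; text matching none of
#' them is an "other" claim ("easy to carry anywhere"). Deterministic: the
#' first class (in lexicon order) with a matching pattern wins.
#'
#' @param text claim free text (scalar or vector).
#' @param lexicon claim lexicon from [load_claim_lexicon()].
#' @return character vector of claim classes.
#' @export
classify_claim <- function(text, lexicon = load_claim_lexicon()) {
  vapply(text, function(tx) {
    txt <- normalize_text(tx)
    if (!nzchar(txt)) return("other")
    for (cls in lexicon$order) {
      pats <- unlist(lexicon$patterns[[cls]])
      if (any(vapply(pats, function(p) grepl(p, txt), logical(1)))) return(cls)
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

lab_result <- function(id, ok, reason_fail = "requirement_not_met",
                       applicable = TRUE) {
  group <- unname(LABELLING_REQUIREMENTS[[id]])
  if (!applicable) {
    return(data.frame(requirement_id = id, group = group,
                      status = "not_applicable", reason = "not_applicable",
                      stringsAsFactors = FALSE))
  }
  if (is.na(ok)) {
    return(data.frame(requirement_id = id, group = group, status = "fail",
                      reason = "undeclared", stringsAsFactors = FALSE))
  }
  data.frame(requirement_id = id, group = group,
             status = if (ok) "pass" else "fail",
             reason = if (ok) "ok" else reason_fail, stringsAsFactors = FALSE)
}

#' Assess a product against the 17 labelling requirements
#'
#' The requirements fall into five groups.
#' Protection and promotion of breastfeeding (5): minimum recommended age of
#' introduction of at least 6 months; not marketed as suitable for under
#' 6 months; a message on the importance of breastfeeding to 2 years or
#' beyond; no suggestion of superiority or equivalence to breast milk; no
#' recommendation or promotion of bottle feeding.
#' Claims (5): no claims of each of the five claim classes (claims without a
#' recorded class are classified from their text).
#' Product name and ingredient-list clarity (4): name reflects ingredients in
#' descending order; percentage of fruit stated (applicable only to
#' fruit-containing products); percentage of added water stated (applicable
#' only when water is an ingredient); percentage of protein stated
#' (applicable only to meat/fish and chunky meal subcategories).
#' Spout messages (2, applicable to pureed products with a spout): states not
#' to suck from the container; warns that the cap is a choking hazard.
#' Age restriction (1, pureed subcategories only): maximum recommended age of
#' use of 12 months stated.
#'
#' Missing information for an applicable requirement fails it; requirements
#' whose applicability condition is unmet are `not_applicable` and excluded
#' from all pass logic.
#'
#' @param p a `cpcf_product`.
#' @param subcategory subcategory code; computed with [categorize()] when
#'   missing.
#' @param claim_lexicon claim lexicon.
#' @param ingredient_lexicon ingredient lexicon (for applicability of the
#'   fruit/water clarity requirements).
#' @return a `cpcf_labelling_assessment`: list with `results` (17-row data
#'   frame), `group_pass` (named logical, `NA` when a whole group is
#'   inapplicable) and `overall_pass`.
#' @export
assess_labelling <- function(p, subcategory = NULL,
                             claim_lexicon = load_claim_lexicon(),
                             ingredient_lexicon = load_ingredient_lexicon()) {
  subcategory <- as.character(subcategory %||% categorize(p, ingredient_lexicon))
  ft <- p$features
  classes <- classify_ingredient(p$ingredients$name, ingredient_lexicon)
  pureed <- !subcategory %in% CHUNKY_SUBCATEGORIES

  # breastfeeding group
  min_age_ok <- if (is_missing_value(ft$min_age_months_stated)) NA
    else ft$min_age_months_stated >= 6
  res <- list(
    lab_result("bf_min_age_6mo", min_age_ok, "age_below_6_months"),
    lab_result("bf_not_marketed_under_6mo",
               if (is.na(ft$marketed_under_6mo)) NA else !ft$marketed_under_6mo,
               "marketed_under_6_months"),
    lab_result("bf_breastfeeding_message", ft$breastfeeding_2yr_message,
               "message_absent"),
    lab_result("bf_no_superiority_claim",
               if (is.na(ft$suggests_superiority_to_breastmilk)) NA
               else !ft$suggests_superiority_to_breastmilk,
               "superiority_suggested"),
    lab_result("bf_no_bottle_feeding",
               if (is.na(ft$recommends_bottle_feeding)) NA
               else !ft$recommends_bottle_feeding,
               "bottle_feeding_promoted")
  )

  # claims group: a product with zero claims passes all five
  claim_cls <- ft$claims$claim_class
  if (nrow(ft$claims) > 0 && anyNA(claim_cls)) {
    claim_cls[is.na(claim_cls)] <- classify_claim(ft$claims$text[is.na(claim_cls)],
                                                  claim_lexicon)
  }
  for (cc in CLAIM_CLASSES) {
    id <- switch(cc,
                 nonpermitted_compositional = "cl_no_nonpermitted_compositional",
                 nutrient_content = "cl_no_nutrient_content",
                 nutrient_function = "cl_no_nutrient_function",
                 disease_risk_reduction = "cl_no_disease_risk_reduction",
                 other = "cl_no_other")
    res <- c(res, list(lab_result(id, !cc %in% claim_cls, "claim_present")))
  }

  # clarity group
  has_fruit <- any(classes == "fruit")
  has_water <- any(classes == "water")
  protein_applicable <- subcategory %in% c(
    "pureed_meal_meat_fish", "pureed_meal_no_meat_fish",
    "chunky_meal_meat_fish_cheese", "chunky_meal_vegetable"
  )
  res <- c(res, list(
    lab_result("nc_name_reflects_order", ft$name_reflects_ingredient_order,
               "name_order_mismatch"),
    lab_result("nc_pct_fruit_stated", ft$pct_fruit_stated, "pct_not_stated",
               applicable = has_fruit),
    lab_result("nc_pct_water_stated", ft$pct_water_stated, "pct_not_stated",
               applicable = has_water),
    lab_result("nc_pct_protein_stated", ft$pct_protein_stated, "pct_not_stated",
               applicable = protein_applicable)
  ))

  # spout group (pureed products with a spout)
  spout_applicable <- pureed && isTRUE(ft$has_spout)
  res <- c(res, list(
    lab_result("sp_no_suck_message", ft$spout_no_suck_message, "message_absent",
               applicable = spout_applicable),
    lab_result("sp_choke_warning", ft$spout_choke_warning, "warning_absent",
               applicable = spout_applicable)
  ))

  # age restriction on pureed products
  res <- c(res, list(
    lab_result("ar_max_age_12mo", ft$max_age_12mo_stated, "max_age_not_stated",
               applicable = pureed)
  ))

  results <- do.call(rbind, res)
  groups <- unique(unname(LABELLING_REQUIREMENTS))
  group_pass <- vapply(groups, function(g) {
    sub <- results[results$group == g & results$status != "not_applicable", ]
    if (nrow(sub) == 0) return(NA)
    all(sub$status == "pass")
  }, logical(1))
  names(group_pass) <- groups

  applicable <- results$status != "not_applicable"
  structure(list(
    subcategory = subcategory,
    results = results,
    group_pass = group_pass,
    overall_pass = all(results$status[applicable] == "pass")
  ), class = "cpcf_labelling_assessment")
}
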
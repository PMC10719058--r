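#' Run the full assessment pipeline over a product list
#'
#' Categorizes every product, runs the nutrient-composition and labelling
#' assessments, and returns one assessment record per product. This is the
#' per-product bundle the market aggregator consumes.
#'
#' @param products a list of `cpcf_product` (e.g. from [read_products()] or
#'   [generate_market()]).
#' @param profile nutrient threshold profile.
#' @param ingredient_lexicon,sweetener_lexicon,claim_lexicon lexicons.
#' @param energy_source passed to [assess_nutrients()].
#' @return a list of `cpcf_assessment` records (class `cpcf_assessments`),
#'   each with elements `product_id`, `subcategory`, `nutrients`
#'   (a `cpcf_nutrient_assessment`), `labelling`
#'   (a `cpcf_labelling_assessment`) and `panel` (the declared per-100 g
#'   values used by the nutrient summary tables).
#' @export
assess_products <- function(products,
                            profile = load_profile(),
                            ingredient_lexicon = load_ingredient_lexicon(),
                            sweetener_lexicon = load_sweetener_lexicon(),
                            claim_lexicon = load_claim_lexicon(),
                            energy_source = c("declared", "atwater")) {
  energy_source <- match.arg(energy_source)
  records <- lapply(products, function(p) {
    subcat <- as.character(categorize(p, ingredient_lexicon))
    structure(list(
      product_id = p$product_id,
      subcategory = subcat,
      nutrients = assess_nutrients(p, subcat, profile, sweetener_lexicon,
                                   ingredient_lexicon, energy_source),
      labelling = assess_labelling(p, subcat, claim_lexicon, ingredient_lexicon),
      panel = list(
        total_sugar = p$panel$total_sugar,
        sodium = sodium_mg_per_100g(p$panel),
        protein = p$panel$protein,
        total_fat = p$panel$total_fat,
        energy_kcal = energy_kcal_per_100g(p$panel)
      )
    ), class = "cpcf_assessment")
  })
  structure(records, class = "cpcf_assessments")
}

#' Flatten assessment records into a tidy per-product table
#'
#' One row per product; nutrient and labelling requirement statuses become
#' columns (`nutr_*`, `lab_*`), with overall verdicts, group passes and the
#' high-sugar tri-state. This wide table is what [summarize_market()]
#' aggregates.
#'
#' @param records a `cpcf_assessments` list from [assess_products()].
#' @return a tibble with one row per product.
#' @export
assessment_table <- function(records) {
  rows <- lapply(records, function(r) {
    nres <- stats::setNames(r$nutrients$results$status,
                            paste0("nutr_", r$nutrients$results$requirement_id))
    lres <- stats::setNames(r$labelling$results$status,
                            paste0("lab_", r$labelling$results$requirement_id))
    gp <- stats::setNames(r$labelling$group_pass,
                          paste0("group_", names(r$labelling$group_pass)))
    c(list(product_id = r$product_id, subcategory = r$subcategory),
      as.list(nres),
      list(nutrient_overall_pass = r$nutrients$overall_pass,
           high_sugar = r$nutrients$high_sugar),
      as.list(lres), as.list(gp),
      list(labelling_overall_pass = r$labelling$overall_pass,
           total_sugar = r$panel$total_sugar, sodium = r$panel$sodium,
           protein = r$panel$protein, total_fat = r$panel$total_fat))
  })
  tibble::as_tibble(do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE))))
}
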
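#' Reference market summary counts
#'
#' Loads the packaged summary counts of a published 2021 market survey of 459
#' CPCF purees/meals across seven Southeast Asian capital cities (the
#' survey's per-product raw data are not public, so only these printed counts
#' and proportions can be reproduced). Used by
#' [verify_reference_arithmetic()] and by the acceptance workflow to check
#' the aggregator's proportion arithmetic against the printed tables.
#'
#' @param path alternative counts JSON; `NULL` for the packaged fixture.
#' @return a list of per-subcategory counts, overall counts and the printed
#'   percentages.
#' @export
reference_market_counts <- function(path = NULL) {
  path <- path %||% pkg_extdata("reference_market_counts.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Recompute every reference proportion from its printed counts
#'
#' Pure aggregator arithmetic: each overall proportion of the reference
#' market is recomputed from the per-subcategory (or overall) counts with the
#' same rounding used in the report tables, and compared with the printed
#' percentage. This is the integrity check that the aggregation logic
#' reproduces the published tables exactly.
#'
#' @param counts output of [reference_market_counts()].
#' @return a tibble with one row per quantity: `quantity`, `numerator`,
#'   `denominator`, `computed_pct`, `printed_pct`, `match`.
#' @export
verify_reference_arithmetic <- function(counts = reference_market_counts()) {
  total <- sum(counts$n_products)
  rows <- list(
    list("met_all_nutrient_requirements",
         sum(counts$met_all_nutrient_requirements), total),
    list("high_sugar_warning_among_declaring",
         counts$high_sugar_warning_n, counts$sugar_declared_n),
    list("sugar_declared_share", counts$sugar_declared_n, total),
    list("breastfeeding_group_pass",
         sum(counts$breastfeeding_group_pass), total),
    list("claim_free_products", counts$claim_free_n, total),
    list("clarity_group_pass", counts$clarity_group_pass_n, total),
    list("spout_group_pass", counts$spout_group_pass_n, counts$spout_assessed_n),
    list("breastfeeding_message_missing",
         total - counts$breastfeeding_message_present_n, total),
    list("marketed_under_6mo", counts$marketed_under_6mo_n, total)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    computed <- round_half_up(100 * r[[2]] / r[[3]], 1)
    printed <- counts$printed_pct[[r[[1]]]]
    data.frame(quantity = r[[1]], numerator = r[[2]], denominator = r[[3]],
               computed_pct = computed, printed_pct = printed,
               match = isTRUE(all.equal(computed, printed)),
               stringsAsFactors = FALSE)
  }))
  tibble::as_tibble(out)
}
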
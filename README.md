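# cpcfnpm

Nutrient and promotion profiling of commercially produced complementary food
(CPCF) purées and meals — packaged baby foods marketed for children aged
6–36 months.

Public-health surveys of baby-food markets benchmark products against the
WHO-Europe style nutrient and promotion profile model (NPM): a rule set that
decides, from label information alone, whether a ready-to-eat purée or meal
is suitable for promotion for older infants and young children. `cpcfnpm`
implements an adapted NPM for the purées/meals category as a tested,
reusable pipeline for market analysts: categorize products from label data,
assess nutrient-composition and labelling requirements, flag products that
need a high-sugar front-of-pack warning, and aggregate market-level report
tables. Because survey label datasets are rarely shareable, the package also
ships a seeded synthetic label generator with known ground truth, so the
whole pipeline is verifiable end to end.

## The model

Each product, described by a structured label record (ordered ingredient
list with optional % by weight, per-100 g nutrient panel, label features,
texture), is assigned to exactly one of nine subcategories: dairy-based
desserts, fruit purées, vegetable-only purées, vegetable purées with
cereals, puréed meals with cheese / with meat-fish / without meat-fish, and
chunky meals with meat-fish-cheese / with vegetables. The subcategory
selects the thresholds for **six nutrient-composition requirements**:

| requirement | rule (per subcategory) |
|---|---|
| added sugar | no added sugars/sweeteners: mono- and disaccharides, syrups/nectars/honey, fruit juices or juice concentrates (lemon/lime juice excluded), non-sugar sweeteners |
| fruit content | ≤ 5 % fruit by weight, or no added fruit (vegetable purées) |
| energy density | ≥ 60 kcal/100 g (not applicable to chunky meals) |
| sodium | < 50 mg per 100 kcal **and** per 100 g (< 100 when cheese is named front-of-pack, for the subcategories that allow it) |
| total fat | ≤ 4.5 or ≤ 6 g/100 kcal |
| protein | ≥ 3 or ≥ 4 g/100 kcal; a meat/fish source named in the product name must also be ≥ 8 % or ≥ 10 % of product weight |

Comparisons follow the printed operators exactly (ties pass at `≥`/`≤`,
fail at `<`); salt converts to sodium as `salt / 2.5`; kJ converts at
4.184 kJ/kcal; a product missing the declarations needed for an applicable
requirement fails it ("undeclared"). A product must pass every applicable
requirement to pass overall. Separately — never part of the pass/fail
verdict — a high-sugar front-of-pack warning is required when the
percentage of energy from total sugar (Atwater factor, 4 kcal/g) reaches
the subcategory threshold: 40 % (dairy desserts), 30 % (fruit and
vegetable-only purées), 20 % (vegetable purées with cereals), 15 % (all
meals).

**Seventeen labelling requirements** in five groups are assessed with
per-category applicability: protection and promotion of breastfeeding (5),
claims (5 — one per claim class; claims are pattern-classified from their
text), product-name and ingredient-list clarity (4), spout messages (2, for
puréed products with a spout), and a 12-month maximum-age statement for
puréed products (1).

All rule inputs (ingredient-class lexicon, sweetener lexicon, claim
patterns, threshold profile) are editable YAML configuration files, so
threshold sensitivity studies need no code changes.

## Worked example

```r
library(cpcfnpm)

p <- product_label(
  product_id = "TH-0042",
  name = "Chicken and potato pie",
  ingredients = data.frame(
    name = c("chicken", "potato", "carrot", "water"),
    pct_by_weight = c(9, 55, 20, 16)
  ),
  panel = nutrient_panel(energy = 68, energy_unit = "kcal", total_sugar = 2.1,
                         salt = 0.25, total_fat = 1.4, protein = 2.9),
  features = label_features(
    min_age_months_stated = 6, marketed_under_6mo = FALSE,
    breastfeeding_2yr_message = FALSE,
    suggests_superiority_to_breastmilk = FALSE,
    recommends_bottle_feeding = FALSE,
    claims = data.frame(text = "no added salt", claim_class = NA),
    name_reflects_ingredient_order = FALSE, pct_water_stated = FALSE,
    pct_protein_stated = TRUE, has_spout = TRUE,
    spout_no_suck_message = FALSE, spout_choke_warning = TRUE,
    max_age_12mo_stated = FALSE, texture = "pureed"
  )
)

categorize(p)
#> [1] "pureed_meal_meat_fish"

a <- assess_nutrients(p)
a$results
#>   requirement_id status             reason  value        unit
#> 1    added_sugar   pass                 ok   0.00 ingredients
#> 2  fruit_content   pass                 ok   0.00    % weight
#> 3 energy_density   pass                 ok  68.00  kcal/100 g
#> 4         sodium   fail threshold_exceeded 147.06 mg/100 kcal
#> 5      total_fat   pass                 ok   2.06  g/100 kcal
#> 6        protein   fail    below_threshold   4.26  g/100 kcal
a$overall_pass   #> FALSE
a$high_sugar     #> "not_required"
```

The meal is named after its meat, so it lands in the meat/fish meal class.
The 0.25 g salt declaration converts to 100 mg sodium/100 g, which is
147 mg/100 kcal at 68 kcal/100 g — far above the 50 mg limit. Protein
density passes (4.26 ≥ 4 g/100 kcal) but chicken is only 9 % of product
weight, below the 10 % floor for a named protein source, so the protein
requirement fails. The `"no added salt"` claim is a non-permitted
compositional claim, and the missing breastfeeding message, unstated water
percentage and absent spout/no-suck message each fail their labelling
requirements (`assess_labelling(p)`).

A whole market in one go:

```r
mk  <- generate_market(market_config(n_products = 459, seed = 1))
rep <- summarize_market(assess_products(mk$products))
rep
#> <cpcf_market_report>
#>   459 products; met all nutrient requirements: 32.0% (n = 147)
#>   high-sugar warning required: 70.6% of 402 sugar-declaring products
#>   met all labelling requirements: 0.0% (n = 0)
```

`rep$nutrient_table`, `rep$labelling_table`, `rep$high_sugar_table` and
`rep$nutrient_summary` hold the per-subcategory percentages with explicit
numerators/denominators, and median [IQR] nutrient summaries over declaring
products. `generate_market()` also returns the per-product ground truth, so
`assessment_table(assess_products(mk$products))` can be compared against it
requirement by requirement.

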
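test_that("unit conversions are exact", {
  expect_equal(salt_to_sodium(1.25), 500)
  expect_equal(salt_to_sodium(0), 0)
  expect_equal(salt_to_sodium(0.10), 40)
  expect_error(salt_to_sodium(-1), "non-negative")

  expect_equal(energy_kcal_per_100g(nutrient_panel(energy = 60, energy_unit = "kcal")), 60)
  expect_equal(energy_kcal_per_100g(nutrient_panel(energy = 252, energy_unit = "kJ")),
               252 / 4.184, tolerance = 1e-10)
  expect_true(is.na(energy_kcal_per_100g(nutrient_panel())))

  expect_equal(per_100kcal(46, 80), 57.5)
  expect_equal(per_100kcal(3.0, 100), 3.0)
  expect_true(is.na(per_100kcal(46, NA)))

  expect_equal(pct_energy_from_sugar(10, 100), 40)
  expect_equal(pct_energy_from_sugar(10.6, 60), 10.6 * 4 / 60 * 100)
  expect_equal(pct_energy_from_sugar(0, 80), 0)
  expect_true(is.na(pct_energy_from_sugar(NA, 80)))
})

test_that("requirement outcomes match the printed rules on worked examples", {
  # dairy dessert with a sugar ingredient fails the no-added-sugar rule
  dairy <- make_product("D", "Yogurt dessert",
                        data.frame(name = c("yogurt", "apple", "sugar"),
                                   pct_by_weight = c(80, 4, 16)),
                        energy = 90, energy_unit = "kcal", total_sugar = 8,
                        sodium = 23, total_fat = 3.1, protein = 2.1)
  a <- assess_nutrients(dairy)
  expect_equal(a$subcategory, "dairy_dessert")
  expect_equal(status_of(a, "added_sugar"), "fail")
  expect_equal(reason_of(a, "added_sugar"), "lexicon_hit")
  expect_false(a$overall_pass)

  # chunky meal: sodium 46 mg/100 g at 80 kcal/100 g is 57.5 mg/100 kcal > 50
  chunky <- make_product("C", "Salmon and pea risotto",
                         data.frame(name = c("salmon", "peas", "rice"),
                                    pct_by_weight = c(15, 45, 40)),
                         texture = "chunky",
                         energy = 80, energy_unit = "kcal", total_sugar = 1.1,
                         sodium = 46, total_fat = 1.6, protein = 4)
  a <- assess_nutrients(chunky)
  expect_equal(status_of(a, "sodium"), "fail")
  expect_equal(a$results$value[a$results$requirement_id == "sodium"], 57.5)
  expect_equal(status_of(a, "energy_density"), "not_applicable")

  # named protein below the 10%-weight floor fails even with enough protein
  meal <- make_meal(chicken_pct = 9, protein = 4.2 * 80 / 100)
  a <- assess_nutrients(meal)
  expect_equal(a$subcategory, "pureed_meal_meat_fish")
  expect_equal(status_of(a, "protein"), "fail")

  # vegetable-only puree with any fruit fails the fruit requirement
  veg <- make_product("V", "Carrot puree",
                      data.frame(name = c("carrot", "apple", "water"),
                                 pct_by_weight = c(80, 3, 17)),
                      energy = 65, energy_unit = "kcal", total_sugar = 3,
                      sodium = 10, total_fat = 0.2, protein = 1)
  a <- assess_nutrients(veg, subcategory = "vegetable_only_puree")
  expect_equal(status_of(a, "fruit_content"), "fail")

  # cheese named front-of-pack relaxes the sodium limit to 100
  cheesy_chunky <- make_product(
    "CC", "Salmon and cheese bake",
    data.frame(name = c("salmon", "potato", "cheese"),
               pct_by_weight = c(15, 70, 15)),
    texture = "chunky", energy = 100, energy_unit = "kcal",
    sodium = 80, total_fat = 2, protein = 5, total_sugar = 1)
  a <- assess_nutrients(cheesy_chunky)
  expect_equal(status_of(a, "sodium"), "pass")
  nocheese <- make_product(
    "NC", "Salmon and potato bake",
    data.frame(name = c("salmon", "potato"), pct_by_weight = c(15, 85)),
    texture = "chunky", energy = 100, energy_unit = "kcal",
    sodium = 80, total_fat = 2, protein = 5, total_sugar = 1)
  expect_equal(status_of(assess_nutrients(nocheese), "sodium"), "fail")
})

test_that("missing declarations fail the affected requirement as undeclared", {
  p <- make_meal(energy = NA, sodium = NA, total_fat = NA, protein = NA,
                 total_sugar = NA)
  p$panel$salt <- NA_real_
  a <- assess_nutrients(p)
  for (req in c("energy_density", "sodium", "total_fat", "protein")) {
    expect_equal(status_of(a, req), "fail", info = req)
    expect_equal(reason_of(a, req), "undeclared", info = req)
  }
  expect_equal(a$high_sugar, "sugar_undeclared")
  expect_false(a$overall_pass)

  # declared sodium but undeclared energy: the per-100 kcal side cannot be
  # evaluated, so sodium still fails as undeclared
  q <- make_meal(energy = NA, sodium = 10)
  expect_equal(reason_of(assess_nutrients(q), "sodium"), "undeclared")

  # salt stands in for sodium when sodium is absent
  r <- make_meal(sodium = NA, energy = 100)
  r$panel$salt <- 0.1  # 40 mg/100 g sodium equivalent
  a <- assess_nutrients(r)
  expect_equal(status_of(a, "sodium"), "pass")
})

test_that("threshold boundaries land on the documented side", {
  # energy density >= 60 is inclusive
  f60 <- make_product("F", "Apple puree", data.frame(name = "apple", pct_by_weight = 100),
                      energy = 60, energy_unit = "kcal", total_sugar = 10,
                      sodium = 5, total_fat = 0.2, protein = 0.5)
  expect_equal(status_of(assess_nutrients(f60), "energy_density"), "pass")
  f59 <- make_product("F", "Apple puree", data.frame(name = "apple", pct_by_weight = 100),
                      energy = 59.99, energy_unit = "kcal", total_sugar = 10,
                      sodium = 5, total_fat = 0.2, protein = 0.5)
  expect_equal(status_of(assess_nutrients(f59), "energy_density"), "fail")

  # sodium < 50 is strict on both scales
  tie_100g <- make_meal(energy = 100, sodium = 50)
  expect_equal(status_of(assess_nutrients(tie_100g), "sodium"), "fail")
  tie_100kcal <- make_meal(energy = 80, sodium = 40)  # exactly 50 mg/100 kcal
  expect_equal(status_of(assess_nutrients(tie_100kcal), "sodium"), "fail")
  under <- make_meal(energy = 100, sodium = 49.99)
  expect_equal(status_of(assess_nutrients(under), "sodium"), "pass")

  # fat <= limit is inclusive (6 g/100 kcal for meat/fish meals)
  fat_tie <- make_meal(energy = 100, total_fat = 6)
  expect_equal(status_of(assess_nutrients(fat_tie), "total_fat"), "pass")
  fat_over <- make_meal(energy = 100, total_fat = 6.01)
  expect_equal(status_of(assess_nutrients(fat_over), "total_fat"), "fail")
  # and 4.5 g/100 kcal for a fruit puree
  fr <- make_product("F", "Apple puree", data.frame(name = "apple", pct_by_weight = 100),
                     energy = 100, energy_unit = "kcal", total_sugar = 10,
                     sodium = 5, total_fat = 4.5, protein = 0.5)
  expect_equal(status_of(assess_nutrients(fr), "total_fat"), "pass")
  fr$panel$total_fat <- 4.51
  expect_equal(status_of(assess_nutrients(fr), "total_fat"), "fail")

  # protein >= limit is inclusive
  pro_tie <- make_meal(energy = 100, protein = 4)
  expect_equal(status_of(assess_nutrients(pro_tie), "protein"), "pass")
  pro_under <- make_meal(energy = 100, protein = 3.99)
  expect_equal(status_of(assess_nutrients(pro_under), "protein"), "fail")

  # named-source weight >= 10% is inclusive
  w_tie <- make_meal(chicken_pct = 10, energy = 100, protein = 5)
  expect_equal(status_of(assess_nutrients(w_tie), "protein"), "pass")
  w_under <- make_meal(chicken_pct = 9.99, energy = 100, protein = 5)
  expect_equal(status_of(assess_nutrients(w_under), "protein"), "fail")

  # fruit <= 5% by weight is inclusive
  fruit_tie <- make_meal(fruit_pct = 5)
  expect_equal(status_of(assess_nutrients(fruit_tie), "fruit_content"), "pass")
  fruit_over <- make_meal(fruit_pct = 5.01)
  expect_equal(status_of(assess_nutrients(fruit_over), "fruit_content"), "fail")

  # high-sugar warning threshold is inclusive (>=)
  hs_tie <- make_product("H", "Apple puree", data.frame(name = "apple", pct_by_weight = 100),
                         energy = 100, energy_unit = "kcal", total_sugar = 7.5,
                         sodium = 5, total_fat = 0.2, protein = 0.5)
  expect_equal(assess_nutrients(hs_tie)$high_sugar, "warning_required")
  hs_tie$panel$total_sugar <- 7.49
  expect_equal(assess_nutrients(hs_tie)$high_sugar, "not_required")
})

test_that("overall pass is the AND over applicable requirements (all 2^6 patterns)", {
  grid <- expand.grid(sugar = c(FALSE, TRUE), fruit = c(FALSE, TRUE),
                      energy = c(FALSE, TRUE), sodium = c(FALSE, TRUE),
                      fat = c(FALSE, TRUE), protein = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    p <- make_meal(
      sugar_ingredient = g$sugar,
      fruit_pct = if (g$fruit) 8 else 0,
      energy = if (g$energy) 50 else 80,
      sodium = if (g$sodium) 60 else 10,
      total_fat = if (g$fat) 8 else 1,
      protein = if (g$protein) 0.5 else 4
    )
    a <- assess_nutrients(p)
    want <- c(added_sugar = g$sugar, fruit_content = g$fruit,
              energy_density = g$energy, sodium = g$sodium,
              total_fat = g$fat, protein = g$protein)
    for (req in names(want)) {
      expect_equal(status_of(a, req), if (want[[req]]) "fail" else "pass",
                   info = paste(i, req))
    }
    expect_equal(a$overall_pass, !any(unlist(g)), info = i)
  }
})

test_that("applicability and the high-sugar flag behave structurally", {
  # protein is not applicable outside meal classes
  fr <- make_product("F", "Apple puree", data.frame(name = "apple", pct_by_weight = 100),
                     energy = 65, energy_unit = "kcal", total_sugar = 11,
                     sodium = 5, total_fat = 0.2)
  a <- assess_nutrients(fr)
  expect_equal(status_of(a, "protein"), "not_applicable")
  expect_equal(status_of(a, "fruit_content"), "not_applicable")
  # a product can pass overall while protein is undeclared, because the
  # requirement does not apply
  expect_true(a$overall_pass)
  # ... and the high-sugar warning (10.6*4/65 = 65% >= 30%) does not affect it
  expect_equal(a$high_sugar, "warning_required")

  # energy density is not applicable for chunky classes
  ch <- make_meal(texture = "chunky", energy = 40)
  a2 <- assess_nutrients(ch)
  expect_equal(a2$subcategory, "chunky_meal_meat_fish_cheese")
  expect_equal(status_of(a2, "energy_density"), "not_applicable")
})

test_that("assess_nutrients matches the straight-line oracle on random products", {
  mk <- generate_market(market_config(n_products = 250, seed = 17))
  profile <- load_profile()
  ilex <- load_ingredient_lexicon()
  slex <- load_sweetener_lexicon()
  for (i in seq_along(mk$products)) {
    p <- mk$products[[i]]
    subcat <- mk$ground_truth$subcategory[i]
    got <- assess_nutrients(p, subcat, profile, slex, ilex)
    want <- oracle_assess(p, subcat)
    expect_equal(stats::setNames(got$results$status, got$results$requirement_id),
                 want$statuses, info = p$product_id)
    expect_equal(got$overall_pass, want$overall, info = p$product_id)
    expect_equal(got$high_sugar, want$high_sugar, info = p$product_id)
  }
})
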
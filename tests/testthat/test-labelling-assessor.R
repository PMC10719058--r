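test_that("claim classification follows the lexicon patterns", {
  expect_equal(classify_claim("contains naturally occurring sugars"),
               "nonpermitted_compositional")
  expect_equal(classify_claim("no added salt"), "nonpermitted_compositional")
  expect_equal(classify_claim("no artificial colours"), "nonpermitted_compositional")
  expect_equal(classify_claim("high in vitamin C"), "nutrient_content")
  expect_equal(classify_claim("source of fibre"), "nutrient_content")
  expect_equal(classify_claim("calcium supports healthy bones"), "nutrient_function")
  expect_equal(classify_claim("helps reduce the risk of anaemia"),
               "disease_risk_reduction")
  expect_equal(classify_claim("fresh and delicious as mom cooks"), "other")
  expect_equal(classify_claim("easy to carry anywhere"), "other")
  # vectorized and deterministic
  expect_equal(classify_claim(c("no added salt", "easy to carry anywhere")),
               c("nonpermitted_compositional", "other"))
})

base_features <- function(...) {
  list(min_age_months_stated = 6, marketed_under_6mo = FALSE,
       breastfeeding_2yr_message = TRUE,
       suggests_superiority_to_breastmilk = FALSE,
       recommends_bottle_feeding = FALSE,
       name_reflects_ingredient_order = TRUE,
       pct_fruit_stated = TRUE, pct_water_stated = TRUE,
       pct_protein_stated = TRUE, has_spout = TRUE,
       spout_no_suck_message = TRUE, spout_choke_warning = TRUE,
       max_age_12mo_stated = TRUE, ...)
}

full_meal <- function(...) {
  args <- utils::modifyList(base_features(), list(...))
  do.call(make_meal, c(list(id = "L1"), args))
}

lab_status <- function(a, req) a$results$status[a$results$requirement_id == req]

test_that("a fully compliant product passes every applicable requirement", {
  a <- assess_labelling(full_meal())
  expect_true(a$overall_pass)
  expect_true(all(a$group_pass, na.rm = TRUE))
  expect_true(all(a$results$status %in% c("pass", "not_applicable")))
})

test_that("breastfeeding-group requirements catch the documented failures", {
  a <- assess_labelling(full_meal(min_age_months_stated = 4))
  expect_equal(lab_status(a, "bf_min_age_6mo"), "fail")
  expect_false(a$group_pass[["breastfeeding"]])
  expect_false(a$overall_pass)

  # missing age statement fails too (missing information fails)
  a2 <- assess_labelling(full_meal(min_age_months_stated = NA))
  expect_equal(lab_status(a2, "bf_min_age_6mo"), "fail")
  expect_equal(a2$results$reason[a2$results$requirement_id == "bf_min_age_6mo"],
               "undeclared")

  a3 <- assess_labelling(full_meal(marketed_under_6mo = TRUE))
  expect_equal(lab_status(a3, "bf_not_marketed_under_6mo"), "fail")

  a4 <- assess_labelling(full_meal(breastfeeding_2yr_message = NA))
  expect_equal(lab_status(a4, "bf_breastfeeding_message"), "fail")
})

test_that("claims requirements fail exactly for the classes present", {
  p <- full_meal(claims = data.frame(
    text = c("no added salt", "easy to carry anywhere"),
    claim_class = NA_character_))
  a <- assess_labelling(p)
  expect_equal(lab_status(a, "cl_no_nonpermitted_compositional"), "fail")
  expect_equal(lab_status(a, "cl_no_other"), "fail")
  expect_equal(lab_status(a, "cl_no_nutrient_content"), "pass")
  expect_equal(lab_status(a, "cl_no_disease_risk_reduction"), "pass")
  expect_false(a$group_pass[["claims"]])

  # zero claims passes all five claims requirements
  a0 <- assess_labelling(full_meal())
  claims_rows <- a0$results[a0$results$group == "claims", ]
  expect_true(all(claims_rows$status == "pass"))
  expect_true(a0$group_pass[["claims"]])

  # a recorded claim_class is honoured without reclassification
  p2 <- full_meal(claims = data.frame(text = "mystery wording",
                                      claim_class = "nutrient_function"))
  a2 <- assess_labelling(p2)
  expect_equal(lab_status(a2, "cl_no_nutrient_function"), "fail")
  expect_equal(lab_status(a2, "cl_no_other"), "pass")
})

test_that("applicability conditions gate the clarity, spout and age requirements", {
  # chunky meal: spout and max-age requirements are not applicable
  ch <- full_meal(texture = "chunky", has_spout = FALSE,
                  spout_no_suck_message = NA, spout_choke_warning = NA,
                  max_age_12mo_stated = NA)
  a <- assess_labelling(ch)
  expect_equal(lab_status(a, "sp_no_suck_message"), "not_applicable")
  expect_equal(lab_status(a, "sp_choke_warning"), "not_applicable")
  expect_equal(lab_status(a, "ar_max_age_12mo"), "not_applicable")
  expect_true(is.na(a$group_pass[["spout"]]))
  expect_true(is.na(a$group_pass[["age_restriction"]]))
  # ...and not_applicable never blocks the overall verdict
  expect_true(a$overall_pass)

  # spout with choke warning but no no-suck message: group fails 1 of 2
  sp <- full_meal(spout_no_suck_message = FALSE)
  a2 <- assess_labelling(sp)
  expect_equal(lab_status(a2, "sp_no_suck_message"), "fail")
  expect_equal(lab_status(a2, "sp_choke_warning"), "pass")
  expect_false(a2$group_pass[["spout"]])

  # no spout: both spout requirements inapplicable even for pureed products
  nosp <- full_meal(has_spout = FALSE, spout_no_suck_message = NA,
                    spout_choke_warning = NA)
  a3 <- assess_labelling(nosp)
  expect_equal(lab_status(a3, "sp_no_suck_message"), "not_applicable")

  # percentage-of-fruit only applies to fruit-containing products
  nofruit <- assess_labelling(full_meal(pct_fruit_stated = NA))
  expect_equal(lab_status(nofruit, "nc_pct_fruit_stated"), "not_applicable")
  withfruit <- assess_labelling(full_meal(fruit_pct = 4, pct_fruit_stated = FALSE))
  expect_equal(lab_status(withfruit, "nc_pct_fruit_stated"), "fail")

  # percentage-of-protein only applies to the four meat/fish & chunky classes
  fr <- make_product("F", "Apple puree",
                     data.frame(name = "apple", pct_by_weight = 100))
  a4 <- assess_labelling(fr)
  expect_equal(lab_status(a4, "nc_pct_protein_stated"), "not_applicable")
})

test_that("overall pass implies every group pass", {
  mk <- generate_market(market_config(n_products = 200, seed = 23))
  recs <- assess_products(mk$products)
  for (r in recs) {
    gp <- r$labelling$group_pass
    if (r$labelling$overall_pass) {
      expect_true(all(gp, na.rm = TRUE), info = r$product_id)
    } else {
      expect_true(any(!gp, na.rm = TRUE), info = r$product_id)
    }
  }
})
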
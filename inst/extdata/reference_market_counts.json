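{
  "comment": "Published summary counts from a 2021 market survey of 459 CPCF purees/meals across seven Southeast Asian capital cities. Used to verify the aggregator's proportion arithmetic against the printed tables; the survey's per-product raw data are not public.",
  "schema_version": 1,
  "subcategories": [
    "dairy_dessert", "fruit_puree", "vegetable_only_puree",
    "vegetable_puree_with_cereal", "pureed_meal_cheese",
    "pureed_meal_meat_fish", "pureed_meal_no_meat_fish",
    "chunky_meal_meat_fish_cheese", "chunky_meal_vegetable"
  ],
  "n_products": [42, 245, 25, 22, 9, 51, 30, 34, 1],
  "met_all_nutrient_requirements": [0, 144, 3, 6, 4, 6, 3, 6, 1],
  "breastfeeding_group_pass": [3, 28, 0, 0, 1, 5, 1, 1, 0],
  "sugar_declared_n": 398,
  "high_sugar_warning_n": 313,
  "claim_free_n": 7,
  "clarity_group_pass_n": 112,
  "spout_group_pass_n": 18,
  "spout_assessed_n": 250,
  "breastfeeding_message_present_n": 78,
  "marketed_under_6mo_n": 132,
  "printed_pct": {
    "met_all_nutrient_requirements": 37.7,
    "high_sugar_warning_among_declaring": 78.6,
    "sugar_declared_share": 86.7,
    "breastfeeding_group_pass": 8.5,
    "claim_free_products": 1.5,
    "clarity_group_pass": 24.4,
    "spout_group_pass": 7.2,
    "breastfeeding_message_missing": 83.0,
    "marketed_under_6mo": 28.8
  }
}
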
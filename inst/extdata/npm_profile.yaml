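# Nutrient-composition threshold profile for CPCF purees/meals, one block per
# subcategory. Units: energy_density_min kcal/100 g; sodium limits apply
# jointly as mg/100 kcal AND mg/100 g (strict <); fat_max g/100 kcal
# (inclusive <=); protein_min g/100 kcal (inclusive >=);
# named_protein_min_pct_weight % of total product by weight (inclusive >=);
# fruit_rule one of max_5pct_weight | no_added_fruit | none;
# high_sugar_pct_energy % of energy from total sugar at or above which a
# front-of-pack warning is required. `~` marks a requirement that does not
# apply to the subcategory.
schema_version: 1
profile_name: adapted_npm_cpcf_purees_meals
subcategories:
  dairy_dessert:
    energy_density_min: 60
    sodium_max: 50
    sodium_max_if_cheese_named: ~
    fat_max: 4.5
    protein_min: ~
    named_protein_min_pct_weight: ~
    fruit_rule: max_5pct_weight
    high_sugar_pct_energy: 40
  fruit_puree:
    energy_density_min: 60
    sodium_max: 50
    sodium_max_if_cheese_named: ~
    fat_max: 4.5
    protein_min: ~
    named_protein_min_pct_weight: ~
    fruit_rule: none
    high_sugar_pct_energy: 30
  vegetable_only_puree:
    energy_density_min: 60
    sodium_max: 50
    sodium_max_if_cheese_named: ~
    fat_max: 4.5
    protein_min: ~
    named_protein_min_pct_weight: ~
    fruit_rule: no_added_fruit
    high_sugar_pct_energy: 30
  vegetable_puree_with_cereal:
    energy_density_min: 60
    sodium_max: 50
    sodium_max_if_cheese_named: ~
    fat_max: 4.5
    protein_min: ~
    named_protein_min_pct_weight: ~
    fruit_rule: no_added_fruit
    high_sugar_pct_energy: 20
  pureed_meal_cheese:
    energy_density_min: 60
    sodium_max: 100
    sodium_max_if_cheese_named: ~
    fat_max: 6
    protein_min: 3
    named_protein_min_pct_weight: ~
    fruit_rule: max_5pct_weight
    high_sugar_pct_energy: 15
  pureed_meal_meat_fish:
    energy_density_min: 60
    sodium_max: 50
    sodium_max_if_cheese_named: 100
    fat_max: 6
    protein_min: 4
    named_protein_min_pct_weight: 10
    fruit_rule: max_5pct_weight
    high_sugar_pct_energy: 15
  pureed_meal_no_meat_fish:
    energy_density_min: 60
    sodium_max: 50
    sodium_max_if_cheese_named: 100
    fat_max: 4.5
    protein_min: 3
    named_protein_min_pct_weight: 8
    fruit_rule: max_5pct_weight
    high_sugar_pct_energy: 15
  chunky_meal_meat_fish_cheese:
    energy_density_min: ~
    sodium_max: 50
    sodium_max_if_cheese_named: 100
    fat_max: 6
    protein_min: 4
    named_protein_min_pct_weight: 10
    fruit_rule: max_5pct_weight
    high_sugar_pct_energy: 15
  chunky_meal_vegetable:
    energy_density_min: ~
    sodium_max: 50
    sodium_max_if_cheese_named: 100
    fat_max: 4.5
    protein_min: 3
    named_protein_min_pct_weight: ~
    fruit_rule: max_5pct_weight
    high_sugar_pct_energy: 15
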
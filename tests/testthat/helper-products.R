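# Shorthand constructors for test products.

make_product <- function(id = "P1", name = "Test product",
                         ingredients = data.frame(name = "apple",
                                                  pct_by_weight = 100),
                         texture = "pureed",
                         energy = NA, energy_unit = if (is.na(energy)) NA else "kcal",
                         total_sugar = NA, sodium = NA, salt = NA,
                         total_fat = NA, protein = NA, ...) {
  product_label(
    product_id = id, name = name, ingredients = ingredients,
    panel = nutrient_panel(energy = energy, energy_unit = energy_unit,
                           total_sugar = total_sugar, sodium = sodium,
                           salt = salt, total_fat = total_fat,
                           protein = protein),
    features = label_features(texture = texture, ...)
  )
}

# A fully-declared pureed meat/fish meal where every nutrient requirement is
# applicable; arguments flip individual requirements.
make_meal <- function(id = "M1", chicken_pct = 12, fruit_pct = 0,
                      sugar_ingredient = FALSE,
                      energy = 80, sodium = 10, total_fat = 1, protein = 4,
                      total_sugar = 2, texture = "pureed", ...) {
  rows <- data.frame(
    name = c("chicken", "potato", "carrot"),
    pct_by_weight = c(chicken_pct, 100 - chicken_pct - 20 - fruit_pct -
                        if (sugar_ingredient) 2 else 0, 20),
    stringsAsFactors = FALSE
  )
  if (fruit_pct > 0) rows <- rbind(rows, data.frame(name = "apple", pct_by_weight = fruit_pct))
  if (sugar_ingredient) rows <- rbind(rows, data.frame(name = "sugar", pct_by_weight = 2))
  make_product(id, "Chicken and potato pie", rows, texture = texture,
               energy = energy, energy_unit = "kcal", total_sugar = total_sugar,
               sodium = sodium, total_fat = total_fat, protein = protein, ...)
}

status_of <- function(assessment, req) {
  assessment$results$status[assessment$results$requirement_id == req]
}

reason_of <- function(assessment, req) {
  assessment$results$reason[assessment$results$requirement_id == req]
}
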
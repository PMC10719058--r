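#' Product-label data model
#'
#' A `cpcf_product` is everything read off one product's package: identity,
#' ordered ingredient list (with optional % by weight), the nutrient
#' declaration panel (per 100 g), and the label features the labelling
#' requirements test. All assessment modules consume this type.
#'
#' Nutrient declarations are normalized to per-100 g at construction:
#' a panel declared per serving must carry `serving_size_g`, otherwise its
#' values are treated as missing. When both sodium and salt are declared,
#' sodium wins (salt/2.5 is only the fallback conversion). Booleans absent
#' from input stay `NA` ("unknown"), never silently `FALSE`: an applicable
#' requirement with unknown information fails with reason "undeclared".
#'
#' @param product_id opaque unique identifier.
#' @param name product name as printed front-of-pack.
#' @param ingredients a data frame with columns `name` and optionally
#'   `pct_by_weight` (percent, 0-100, `NA` allowed), in label order.
#' @param panel a list or `nutrient_panel()` with per-100 g declarations.
#' @param features a list or `label_features()`.
#' @param country ISO code or free text, optional.
#' @return an object of class `cpcf_product`.
#' @export
product_label <- function(product_id, name, ingredients, panel = nutrient_panel(),
                          features = label_features(), country = NA_character_) {
  ingredients <- as.data.frame(ingredients, stringsAsFactors = FALSE)
  if (is.null(ingredients$pct_by_weight)) ingredients$pct_by_weight <- NA_real_
  ingredients <- data.frame(
    rank = seq_len(nrow(ingredients)),
    name = as.character(ingredients$name),
    pct_by_weight = as.numeric(ingredients$pct_by_weight),
    stringsAsFactors = FALSE
  )
  if (!inherits(panel, "cpcf_panel")) panel <- do.call(nutrient_panel, as.list(panel))
  if (!inherits(features, "cpcf_features")) features <- do.call(label_features, as.list(features))
  structure(list(
    product_id = as.character(product_id),
    name = as.character(name),
    country = as.character(country),
    ingredients = ingredients,
    panel = panel,
    features = features
  ), class = "cpcf_product")
}

#' @rdname product_label
#' @param energy energy declaration per 100 g (or per serving, see `basis`).
#' @param energy_unit `"kcal"` or `"kJ"`; mandatory when energy is declared.
#' @param total_sugar,sodium,salt,total_fat,protein declarations: sugar/fat/
#'   protein and salt in g, sodium in mg.
#' @param basis `"per_100g"` (default) or `"per_serving"`.
#' @param serving_size_g serving size in g, required for per-serving panels.
#' @export
nutrient_panel <- function(energy = NA, energy_unit = NA_character_,
                           total_sugar = NA, sodium = NA, salt = NA,
                           total_fat = NA, protein = NA,
                           basis = "per_100g", serving_size_g = NA) {
  p <- list(energy = as_num(energy), energy_unit = as.character(energy_unit %||% NA),
            total_sugar = as_num(total_sugar), sodium = as_num(sodium),
            salt = as_num(salt), total_fat = as_num(total_fat),
            protein = as_num(protein))
  basis <- match.arg(basis, c("per_100g", "per_serving"))
  if (basis == "per_serving") {
    ss <- as_num(serving_size_g)
    fields <- c("energy", "total_sugar", "sodium", "salt", "total_fat", "protein")
    if (is_missing_value(ss) || ss <= 0) {
      p[fields] <- NA_real_   # per-serving without serving size: unusable
    } else {
      for (f in fields) p[[f]] <- p[[f]] * 100 / ss
    }
  }
  structure(p, class = "cpcf_panel")
}

#' @rdname product_label
#' @param min_age_months_stated stated minimum age of introduction, months.
#' @param marketed_under_6mo images/text implying suitability under 6 months.
#' @param breastfeeding_2yr_message message on breastfeeding to 2 years or
#'   beyond.
#' @param suggests_superiority_to_breastmilk label suggests superiority or
#'   equivalence to breast milk.
#' @param recommends_bottle_feeding label recommends or promotes bottle
#'   feeding.
#' @param claims data frame with columns `text` and optional `claim_class`
#'   (one of the five claim classes; unstated claims are classified from
#'   text by [classify_claim()]).
#' @param name_reflects_ingredient_order product name reflects ingredients in
#'   descending order per the ingredient list.
#' @param pct_fruit_stated,pct_water_stated,pct_protein_stated percentage of
#'   fruit / added water / named protein stated in the ingredient list.
#' @param has_spout packaging has a spout (pouch).
#' @param spout_no_suck_message,spout_choke_warning spout messages; only
#'   meaningful when `has_spout`.
#' @param max_age_12mo_stated maximum recommended age of use of 12 months
#'   stated.
#' @param texture `"pureed"` or `"chunky"`.
#' @export
label_features <- function(min_age_months_stated = NA,
                           marketed_under_6mo = NA,
                           breastfeeding_2yr_message = NA,
                           suggests_superiority_to_breastmilk = NA,
                           recommends_bottle_feeding = NA,
                           claims = NULL,
                           name_reflects_ingredient_order = NA,
                           pct_fruit_stated = NA,
                           pct_water_stated = NA,
                           pct_protein_stated = NA,
                           has_spout = NA,
                           spout_no_suck_message = NA,
                           spout_choke_warning = NA,
                           max_age_12mo_stated = NA,
                           texture = "pureed") {
  if (is.null(claims)) {
    claims <- data.frame(text = character(), claim_class = character(),
                         stringsAsFactors = FALSE)
  } else {
    claims <- as.data.frame(claims, stringsAsFactors = FALSE)
    if (is.null(claims$claim_class)) claims$claim_class <- NA_character_
    claims <- data.frame(text = as.character(claims$text),
                         claim_class = as.character(claims$claim_class),
                         stringsAsFactors = FALSE)
  }
  structure(list(
    min_age_months_stated = as_num(min_age_months_stated),
    marketed_under_6mo = as_tristate(marketed_under_6mo),
    breastfeeding_2yr_message = as_tristate(breastfeeding_2yr_message),
    suggests_superiority_to_breastmilk = as_tristate(suggests_superiority_to_breastmilk),
    recommends_bottle_feeding = as_tristate(recommends_bottle_feeding),
    claims = claims,
    name_reflects_ingredient_order = as_tristate(name_reflects_ingredient_order),
    pct_fruit_stated = as_tristate(pct_fruit_stated),
    pct_water_stated = as_tristate(pct_water_stated),
    pct_protein_stated = as_tristate(pct_protein_stated),
    has_spout = as_tristate(has_spout),
    spout_no_suck_message = as_tristate(spout_no_suck_message),
    spout_choke_warning = as_tristate(spout_choke_warning),
    max_age_12mo_stated = as_tristate(max_age_12mo_stated),
    texture = match.arg(texture, c("pureed", "chunky"))
  ), class = "cpcf_features")
}

#' @export
print.cpcf_product <- function(x, ...) {
  cat("<cpcf_product> ", x$product_id, ": ", x$name,
      " [", x$features$texture, ", ", nrow(x$ingredients), " ingredients]\n",
      sep = "")
  invisible(x)
}

#' Validate a product-label record
#'
#' Checks the type invariants (non-empty ingredient list, percentages in
#' [0, 100], non-negative nutrient declarations, energy unit present when
#' energy is declared, spout messages only with a spout, known claim
#' classes). Validation never throws; it returns zero or more
#' machine-readable messages of the form `"code: human text"`.
#'
#' @param p a `cpcf_product`.
#' @return character vector of violation messages; empty when valid.
#' @export
validate_product <- function(p) {
  msgs <- character()
  add <- function(code, text) msgs <<- c(msgs, paste0(code, ": ", text))
  if (!nzchar(p$product_id %||% "")) add("missing_id", "product_id is empty")
  if (nrow(p$ingredients) == 0) add("empty_ingredients", "ingredient list is empty")
  bad_pct <- which(!is.na(p$ingredients$pct_by_weight) &
                     (p$ingredients$pct_by_weight < 0 | p$ingredients$pct_by_weight > 100))
  for (i in bad_pct) {
    add("pct_out_of_range",
        sprintf("ingredient %d (%s) pct_by_weight %.6g outside [0, 100]",
                i, p$ingredients$name[i], p$ingredients$pct_by_weight[i]))
  }
  for (f in c("energy", "total_sugar", "sodium", "salt", "total_fat", "protein")) {
    v <- p$panel[[f]]
    if (!is_missing_value(v) && v < 0) add("negative_nutrient", paste0(f, " is negative"))
  }
  if (!is_missing_value(p$panel$energy) &&
      (is_missing_value(p$panel$energy_unit) ||
       !p$panel$energy_unit %in% c("kcal", "kJ"))) {
    add("missing_energy_unit", "energy declared without a kcal/kJ unit tag")
  }
  ft <- p$features
  if (!isTRUE(ft$has_spout) &&
      (isTRUE(ft$spout_no_suck_message) || isTRUE(ft$spout_choke_warning))) {
    add("spout_message_without_spout", "spout messages set on a product without has_spout")
  }
  known <- is.na(ft$claims$claim_class) | ft$claims$claim_class %in% CLAIM_CLASSES
  if (any(!known)) {
    add("unknown_claim_class",
        paste0("unknown claim_class: ",
               paste(unique(ft$claims$claim_class[!known]), collapse = ", ")))
  }
  msgs
}

# ---- serialization ---------------------------------------------------------

FEATURE_BOOL_FIELDS <- c(
  "marketed_under_6mo", "breastfeeding_2yr_message",
  "suggests_superiority_to_breastmilk", "recommends_bottle_feeding",
  "name_reflects_ingredient_order", "pct_fruit_stated", "pct_water_stated",
  "pct_protein_stated", "has_spout", "spout_no_suck_message",
  "spout_choke_warning", "max_age_12mo_stated"
)

serialize_ingredients <- function(ing) {
  paste(vapply(seq_len(nrow(ing)), function(i) {
    pct <- ing$pct_by_weight[i]
    paste0(ing$name[i], "|", if (is.na(pct)) "" else format(pct, digits = 10))
  }, character(1)), collapse = ";")
}

parse_ingredients <- function(cell, row) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    stop("row ", row, ": ingredient list is empty", call. = FALSE)
  }
  toks <- strsplit(cell, ";", fixed = TRUE)[[1]]
  toks <- toks[nzchar(trimws(toks))]
  if (length(toks) == 0) {
    stop("row ", row, ": ingredient list is empty", call. = FALSE)
  }
  parts <- strsplit(toks, "|", fixed = TRUE)
  data.frame(
    name = trimws(vapply(parts, `[`, character(1), 1)),
    pct_by_weight = vapply(parts, function(x) as_num(x[2]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

serialize_claims <- function(claims) {
  if (nrow(claims) == 0) return("")
  paste(paste0(claims$text, "|",
               ifelse(is.na(claims$claim_class), "", claims$claim_class)),
        collapse = ";")
}

parse_claims <- function(cell) {
  if (is.na(cell) || !nzchar(trimws(cell))) {
    return(data.frame(text = character(), claim_class = character(),
                      stringsAsFactors = FALSE))
  }
  toks <- strsplit(cell, ";", fixed = TRUE)[[1]]
  parts <- strsplit(toks, "|", fixed = TRUE)
  cls <- vapply(parts, function(x) {
    v <- trimws(x[2] %||% NA_character_)
    if (is.na(v) || !nzchar(v)) NA_character_ else v
  }, character(1))
  data.frame(text = trimws(vapply(parts, `[`, character(1), 1)),
             claim_class = cls, stringsAsFactors = FALSE)
}

product_to_row <- function(p) {
  ft <- p$features
  row <- list(
    product_id = p$product_id, name = p$name, country = p$country,
    texture = ft$texture,
    ingredients = serialize_ingredients(p$ingredients),
    energy = p$panel$energy, energy_unit = p$panel$energy_unit,
    total_sugar = p$panel$total_sugar, sodium = p$panel$sodium,
    salt = p$panel$salt, total_fat = p$panel$total_fat,
    protein = p$panel$protein,
    min_age_months_stated = ft$min_age_months_stated,
    claims = serialize_claims(ft$claims)
  )
  for (f in FEATURE_BOOL_FIELDS) row[[f]] <- ft[[f]]
  as.data.frame(row, stringsAsFactors = FALSE)
}

row_to_product <- function(row, i) {
  texture <- trimws(as.character(row$texture %||% "pureed"))
  if (!texture %in% c("pureed", "chunky")) {
    stop("row ", i, ": unknown texture value '", texture, "'", call. = FALSE)
  }
  feats <- list(
    min_age_months_stated = as_num(row$min_age_months_stated),
    claims = parse_claims(as.character(row$claims %||% NA)),
    texture = texture
  )
  for (f in FEATURE_BOOL_FIELDS) feats[[f]] <- as_tristate(row[[f]])
  eu <- as.character(row$energy_unit %||% NA)
  if (!is.na(eu) && nzchar(trimws(eu)) && !trimws(eu) %in% c("kcal", "kJ")) {
    stop("row ", i, ": unknown energy_unit '", eu, "'", call. = FALSE)
  }
  product_label(
    product_id = row$product_id,
    name = row$name,
    country = as.character(row$country %||% NA),
    ingredients = parse_ingredients(as.character(row$ingredients %||% ""), i),
    panel = nutrient_panel(
      energy = row$energy, energy_unit = if (is.na(eu) || !nzchar(trimws(eu))) NA else trimws(eu),
      total_sugar = row$total_sugar, sodium = row$sodium, salt = row$salt,
      total_fat = row$total_fat, protein = row$protein,
      basis = as.character(row$basis %||% "per_100g"),
      serving_size_g = row$serving_size_g %||% NA
    ),
    features = do.call(label_features, feats)
  )
}

product_to_list <- function(p) {
  ing <- p$ingredients
  list(
    product_id = p$product_id, name = p$name, country = p$country,
    ingredients = lapply(seq_len(nrow(ing)), function(i) {
      out <- list(name = ing$name[i])
      if (!is.na(ing$pct_by_weight[i])) out$pct_by_weight <- ing$pct_by_weight[i]
      out
    }),
    panel = Filter(function(v) !is_missing_value(v), unclass(p$panel)),
    features = {
      ft <- unclass(p$features)
      ft$claims <- if (nrow(ft$claims)) {
        lapply(seq_len(nrow(ft$claims)), function(i) {
          out <- list(text = ft$claims$text[i])
          if (!is.na(ft$claims$claim_class[i])) out$claim_class <- ft$claims$claim_class[i]
          out
        })
      } else list()
      ft[!vapply(ft, function(v) !is.data.frame(v) && !is.list(v) &&
                   length(v) == 1 && is.na(v), logical(1))]
    }
  )
}

list_to_product <- function(x, i) {
  if (is.null(x$ingredients) || length(x$ingredients) == 0) {
    stop("record ", i, ": ingredient list is empty", call. = FALSE)
  }
  ing <- data.frame(
    name = vapply(x$ingredients, function(e) as.character(e$name), character(1)),
    pct_by_weight = vapply(x$ingredients, function(e) as_num(e$pct_by_weight), numeric(1)),
    stringsAsFactors = FALSE
  )
  feats <- x$features %||% list()
  if (!is.null(feats$claims) && length(feats$claims)) {
    feats$claims <- data.frame(
      text = vapply(feats$claims, function(cl) as.character(cl$text), character(1)),
      claim_class = vapply(feats$claims, function(cl)
        as.character(cl$claim_class %||% NA), character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    feats$claims <- NULL
  }
  eu <- x$panel$energy_unit %||% NA
  if (!is.null(x$panel$energy) && !is_missing_value(x$panel$energy) &&
      (is_missing_value(eu) || !eu %in% c("kcal", "kJ"))) {
    stop("record ", i, ": energy declared without a valid kcal/kJ unit tag",
         call. = FALSE)
  }
  product_label(
    product_id = x$product_id %||% stop("record ", i, ": missing product_id", call. = FALSE),
    name = x$name %||% "",
    country = as.character(x$country %||% NA),
    ingredients = ing,
    panel = do.call(nutrient_panel, x$panel %||% list()),
    features = do.call(label_features, feats)
  )
}

#' Read and write product-label datasets
#'
#' `read_products()` ingests a CSV or JSON dataset into a list of validated
#' `cpcf_product` records (ingredient order preserved; schema violations are
#' hard errors naming the row). `write_products()` is its inverse; JSON is
#' the lossless canonical format, CSV serializes the ingredient list as
#' `name|pct;name|pct` tokens in one cell.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return `read_products()`: a list of `cpcf_product` (class
#'   `cpcf_products`). `write_products()`: the path, invisibly.
#' @export
read_products <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("input file not found: ", path)
  products <- if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
    required <- c("product_id", "name", "ingredients")
    miss <- setdiff(required, names(df))
    if (length(miss)) stop("CSV lacks required columns: ", paste(miss, collapse = ", "))
    lapply(seq_len(nrow(df)), function(i) row_to_product(df[i, , drop = FALSE], i))
  } else {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(recs$products)) recs <- recs$products
    lapply(seq_along(recs), function(i) list_to_product(recs[[i]], i))
  }
  ids <- vapply(products, `[[`, character(1), "product_id")
  if (anyDuplicated(ids)) {
    stop("duplicate product_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (i in seq_along(products)) {
    v <- validate_product(products[[i]])
    if (length(v)) {
      stop("row ", i, " (", ids[i], ") invalid: ", paste(v, collapse = "; "),
           call. = FALSE)
    }
  }
  structure(products, class = "cpcf_products")
}

#' @rdname read_products
#' @param products a list of `cpcf_product`.
#' @export
write_products <- function(products, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    rows <- do.call(rbind, lapply(products, product_to_row))
    utils::write.csv(rows, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(
      list(schema_version = 1, products = lapply(products, product_to_list)),
      path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
  }
  invisible(path)
}
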
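#' Lexicon and threshold-profile configuration
#'
#' The categorizer, added-sugar detector and claim classifier are all driven
#' by editable configuration files shipped under `inst/extdata/`:
#' an ingredient-class lexicon (synonym lists per class), an added-sugar /
#' sweetener lexicon (term lists plus juice patterns with a lemon/lime
#' exclusion), a claim-pattern lexicon, and the nutrient threshold profile.
#' Each loader reads the packaged default when `path` is `NULL`, so an
#' alternative file supports sensitivity analyses without code changes.
#'
#' @param path path to a YAML file, or `NULL` for the packaged default.
#' @return a list with the parsed configuration plus pre-compiled match
#'   structures.
#' @name lexicons
NULL

pkg_extdata <- function(file) {
  p <- system.file("extdata", file, package = "cpcfnpm")
  if (!nzchar(p)) stop("packaged config file not found: ", file)
  p
}

compile_terms <- function(classes) {
  term <- unlist(classes, use.names = FALSE)
  cls <- rep(names(classes), lengths(classes))
  term <- normalize_text(term)
  keep <- nzchar(term)
  data.frame(
    term = term[keep], class = cls[keep],
    nchar = nchar(term[keep]),
    stringsAsFactors = FALSE
  )
}

#' @rdname lexicons
#' @export
load_ingredient_lexicon <- function(path = NULL) {
  path <- path %||% pkg_extdata("ingredient_lexicon.yaml")
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg$classes))
  unknown <- setdiff(names(cfg$classes), INGREDIENT_CLASSES)
  if (length(unknown)) stop("unknown ingredient classes in lexicon: ",
                            paste(unknown, collapse = ", "))
  terms <- compile_terms(cfg$classes)
  structure(list(classes = cfg$classes, terms = terms,
                 schema_version = cfg$schema_version %||% 1),
            class = "cpcf_ingredient_lexicon")
}

#' @rdname lexicons
#' @export
load_sweetener_lexicon <- function(path = NULL) {
  path <- path %||% pkg_extdata("sweetener_lexicon.yaml")
  cfg <- yaml::read_yaml(path)
  terms <- compile_terms(cfg$classes)
  structure(list(
    classes = cfg$classes, terms = terms,
    juice_patterns = unlist(cfg$juice_patterns) %||% character(),
    juice_exclusions = normalize_text(unlist(cfg$juice_exclusions) %||% character()),
    schema_version = cfg$schema_version %||% 1
  ), class = "cpcf_sweetener_lexicon")
}

#' @rdname lexicons
#' @export
load_claim_lexicon <- function(path = NULL) {
  path <- path %||% pkg_extdata("claim_lexicon.yaml")
  cfg <- yaml::read_yaml(path)
  ord <- unlist(cfg$order)
  stopifnot(all(ord %in% CLAIM_CLASSES))
  structure(list(order = ord, patterns = cfg$patterns,
                 schema_version = cfg$schema_version %||% 1),
            class = "cpcf_claim_lexicon")
}

#' Load a nutrient threshold profile
#'
#' @param path path to a profile YAML, or `NULL` for the packaged adapted-NPM
#'   CPCF purees/meals profile.
#' @return a `cpcf_profile` list, one threshold block per subcategory.
#' @export
load_profile <- function(path = NULL) {
  path <- path %||% pkg_extdata("npm_profile.yaml")
  cfg <- yaml::read_yaml(path)
  missing <- setdiff(SUBCATEGORIES, names(cfg$subcategories))
  if (length(missing)) stop("profile lacks subcategories: ",
                            paste(missing, collapse = ", "))
  structure(list(profile_name = cfg$profile_name %||% basename(path),
                 subcategories = cfg$subcategories,
                 schema_version = cfg$schema_version %||% 1),
            class = "cpcf_profile")
}

# Does `term` occur in normalized text as a whole phrase?
phrase_match <- function(text, term) {
  grepl(paste0("(^| )", term, "($| )"), text, fixed = FALSE)
}

# All contiguous word n-grams (n <= maxn) of normalized text. Phrase matching
# against a lexicon is then a set lookup instead of one regex per term.
text_ngrams <- function(txt, maxn = 5L) {
  words <- strsplit(txt, " ", fixed = TRUE)[[1]]
  n <- length(words)
  if (n == 0) return(character())
  unlist(lapply(seq_len(n), function(i) {
    vapply(i:min(n, i + maxn - 1L), function(j)
      paste(words[i:j], collapse = " "), character(1))
  }), use.names = FALSE)
}

# Rows of a compiled term table whose term occurs as a phrase in `txt`.
term_hits <- function(txt, terms) {
  terms[terms$term %in% text_ngrams(txt), , drop = FALSE]
}

#' Classify an ingredient name into an ingredient class
#'
#' Longest-phrase match of the normalized ingredient text against the
#' ingredient lexicon; the longest matching synonym (by character length)
#' decides the class, so "whole milk yogurt" is dairy even though "milk"
#' alone would also match. Unmatched text is `"other"` (treated as
#' unclassified in composition sums).
#'
#' @param name ingredient free text (scalar or vector).
#' @param lexicon an ingredient lexicon from [load_ingredient_lexicon()].
#' @return character vector of ingredient classes.
#' @export
classify_ingredient <- function(name, lexicon = load_ingredient_lexicon()) {
  uniq <- unique(as.character(name))
  cls <- vapply(uniq, function(nm) {
    txt <- normalize_text(nm)
    if (!nzchar(txt)) return("other")
    hits <- term_hits(txt, lexicon$terms)
    if (nrow(hits) == 0) return("other")
    hits$class[which.max(hits$nchar)]
  }, character(1))
  unname(cls[match(as.character(name), uniq)])
}

#' First lexicon-matched food in a product name
#'
#' Scans the product name left to right and returns the ingredient class of
#' the first food token found in the lexicon ("Salmon and pea risotto" gives
#' fish). Names without any lexicon food token ("Hearty shepherd's pie")
#' give `NA`.
#'
#' @param product_name product name free text.
#' @param lexicon an ingredient lexicon.
#' @return a single ingredient class, or `NA_character_` when no food token
#'   is found.
#' @export
first_named_food <- function(product_name, lexicon = load_ingredient_lexicon()) {
  txt <- normalize_text(product_name)
  if (!nzchar(txt)) return(NA_character_)
  words <- strsplit(txt, " ", fixed = TRUE)[[1]]
  n <- length(words)
  for (i in seq_len(n)) {
    best <- NULL
    best_len <- 0L
    # longest phrase starting at word i
    for (j in i:min(n, i + 4L)) {
      cand <- paste(words[i:j], collapse = " ")
      k <- which(lexicon$terms$term == cand)
      if (length(k) && nchar(cand) > best_len) {
        best <- lexicon$terms$class[k[1]]
        best_len <- nchar(cand)
      }
    }
    if (!is.null(best)) return(best)
  }
  NA_character_
}

# All ingredient classes named anywhere in a product name (used by the
# cheese-in-name rules).
named_food_classes <- function(product_name, lexicon = load_ingredient_lexicon()) {
  txt <- normalize_text(product_name)
  if (!nzchar(txt)) return(character())
  unique(term_hits(txt, lexicon$terms)$class)
}
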
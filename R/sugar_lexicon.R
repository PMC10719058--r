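#' Detect added sugars and sweeteners in an ingredient list
#'
#' Flags every ingredient matching the added-sugar/sweetener definition: all
#' mono- and disaccharides; all syrups, nectars and honey; fruit juices or
#' concentrated/powdered fruit juice, excluding lemon or lime juice; and
#' nonsugar sweeteners. Intrinsic sugars in whole fruit or fruit puree are
#' not added sugars (fruit content is governed by a separate requirement), so
#' "banana" or "apple puree" never match. The lemon/lime exclusion overrides
#' any juice-pattern match.
#'
#' @param ingredients a data frame of ingredients (columns `name`, and
#'   optionally `rank`), e.g. the `ingredients` element of a `cpcf_product`.
#' @param lexicon sweetener lexicon from [load_sweetener_lexicon()].
#' @return a data frame with one row per matching ingredient: columns
#'   `ingredient_rank`, `matched_term`, `sweetener_class`. Zero rows means
#'   the product passes the no-added-sugar requirement.
#' @export
find_added_sugars <- function(ingredients, lexicon = load_sweetener_lexicon()) {
  ing <- as.data.frame(ingredients, stringsAsFactors = FALSE)
  if (is.null(ing$rank)) ing$rank <- seq_len(nrow(ing))
  hits <- lapply(seq_len(nrow(ing)), function(i) {
    txt <- normalize_text(ing$name[i])
    if (!nzchar(txt)) return(NULL)

    excluded <- any(vapply(lexicon$juice_exclusions, phrase_match, logical(1),
                           text = txt))
    if (!excluded) {
      jp <- vapply(lexicon$juice_patterns, function(p) grepl(p, txt), logical(1))
      if (any(jp)) {
        m <- regmatches(txt, regexpr(lexicon$juice_patterns[which(jp)[1]], txt))
        return(data.frame(ingredient_rank = ing$rank[i],
                          matched_term = m,
                          sweetener_class = "fruit_juice_or_concentrate",
                          stringsAsFactors = FALSE))
      }
    }

    tm <- term_hits(txt, lexicon$terms)
    if (nrow(tm) == 0) return(NULL)
    best <- tm[which.max(tm$nchar), ]
    data.frame(ingredient_rank = ing$rank[i],
               matched_term = best$term,
               sweetener_class = best$class,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(ingredient_rank = integer(), matched_term = character(),
                      sweetener_class = character(), stringsAsFactors = FALSE)
  }
  out
}
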
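#' Median and interquartile range
#'
#' Median and quartiles by linear interpolation between order statistics
#' (`stats::quantile()` type 7, the R default), the single convention used
#' for every nutrient summary table: `{1, 2, 3}` gives median 2 with IQR
#' [1.5, 2.5].
#'
#' @param values numeric vector; `NA`s are dropped.
#' @return named numeric vector `c(median, q1, q3)`; all `NA` for an empty
#'   input (reported as an n = 0 row, not an error).
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

# % (n) cell: proportion of passes among an explicit denominator, rounded
# half-up to one decimal for display; the raw fraction is kept alongside.
pct_cell <- function(n_pass, n_total) {
  list(pct = if (n_total > 0) round_half_up(100 * n_pass / n_total, 1) else NA_real_,
       n = n_pass, denominator = n_total,
       raw = if (n_total > 0) n_pass / n_total else NA_real_)
}

summarize_requirement <- function(tab, col, by_cat) {
  do.call(rbind, lapply(by_cat, function(idx) {
    status <- tab[[col]][idx]
    applicable <- status != "not_applicable"
    cell <- pct_cell(sum(status[applicable] == "pass"), sum(applicable))
    data.frame(pct = cell$pct, n = cell$n, denominator = cell$denominator,
               raw = cell$raw)
  }))
}

#' Aggregate assessment records into a market report
#'
#' Produces the market-level tables: per-subcategory (plus an overall "all"
#' row) pass proportions for each of the six nutrient requirements and the
#' met-all verdict; the 17 labelling requirements with the five group
#' subtotals and the met-all-labelling row; the high-sugar warning share
#' among products declaring total sugar (products with undeclared sugar or
#' energy are excluded from that denominator); and median [IQR] per-100 g
#' nutrient summaries over declaring products only. Every percentage is
#' `round_half_up(100 * n / denominator, 1)` with the denominator recorded
#' explicitly; `not_applicable` products are excluded from a requirement's
#' denominator.
#'
#' @param records a `cpcf_assessments` list from [assess_products()], or the
#'   tidy table from [assessment_table()].
#' @return a `cpcf_market_report`: list of tibbles `nutrient_table`,
#'   `labelling_table`, `high_sugar_table`, `nutrient_summary`.
#' @export
summarize_market <- function(records) {
  tab <- if (inherits(records, "cpcf_assessments")) assessment_table(records)
    else tibble::as_tibble(records)
  if (nrow(tab) == 0) {
    return(structure(list(nutrient_table = tibble::tibble(),
                          labelling_table = tibble::tibble(),
                          high_sugar_table = tibble::tibble(),
                          nutrient_summary = tibble::tibble()),
                     class = "cpcf_market_report"))
  }
  cats <- intersect(SUBCATEGORIES, unique(tab$subcategory))
  by_cat <- c(stats::setNames(lapply(cats, function(s) which(tab$subcategory == s)), cats),
              list(all = seq_len(nrow(tab))))
  cat_col <- names(by_cat)
  n_products <- unname(vapply(by_cat, length, integer(1)))

  # nutrient table
  nt <- tibble::tibble(subcategory = cat_col, n_products = n_products)
  for (req in NUTRIENT_REQUIREMENTS) {
    s <- summarize_requirement(tab, paste0("nutr_", req), by_cat)
    nt[[paste0(req, "_pct")]] <- s$pct
    nt[[paste0(req, "_n")]] <- s$n
    nt[[paste0(req, "_denominator")]] <- s$denominator
  }
  overall <- unname(vapply(by_cat, function(idx)
    sum(tab$nutrient_overall_pass[idx]), integer(1)))
  nt$met_all_n <- overall
  nt$met_all_pct <- round_half_up(100 * overall / n_products, 1)

  # labelling table
  lt <- tibble::tibble(subcategory = cat_col, n_products = n_products)
  for (req in names(LABELLING_REQUIREMENTS)) {
    s <- summarize_requirement(tab, paste0("lab_", req), by_cat)
    lt[[paste0(req, "_pct")]] <- s$pct
    lt[[paste0(req, "_n")]] <- s$n
    lt[[paste0(req, "_denominator")]] <- s$denominator
  }
  for (g in unique(unname(LABELLING_REQUIREMENTS))) {
    col <- paste0("group_", g)
    sub <- lapply(by_cat, function(idx) tab[[col]][idx])
    denom <- unname(vapply(sub, function(v) sum(!is.na(v)), integer(1)))
    npass <- unname(vapply(sub, function(v) sum(v, na.rm = TRUE), integer(1)))
    lt[[paste0("subtotal_", g, "_pct")]] <- ifelse(denom > 0,
      round_half_up(100 * npass / denom, 1), NA_real_)
    lt[[paste0("subtotal_", g, "_n")]] <- npass
    lt[[paste0("subtotal_", g, "_denominator")]] <- denom
  }
  lab_all <- unname(vapply(by_cat, function(idx)
    sum(tab$labelling_overall_pass[idx]), integer(1)))
  lt$met_all_n <- lab_all
  lt$met_all_pct <- round_half_up(100 * lab_all / n_products, 1)

  # high-sugar warning among sugar-declaring products
  hs <- do.call(rbind, lapply(by_cat, function(idx) {
    v <- tab$high_sugar[idx]
    declaring <- v != "sugar_undeclared"
    cell <- pct_cell(sum(v == "warning_required"), sum(declaring))
    data.frame(n_products = length(v), n_declaring = sum(declaring),
               declaring_pct = round_half_up(100 * mean(declaring), 1),
               warning_n = cell$n, warning_pct = cell$pct)
  }))
  hs <- tibble::as_tibble(cbind(subcategory = cat_col, hs))

  # median [IQR] nutrient summary over declaring products
  ns <- do.call(rbind, lapply(cat_col, function(cc) {
    idx <- by_cat[[cc]]
    do.call(rbind, lapply(c("total_sugar", "sodium", "protein", "total_fat"),
                          function(nut) {
      v <- tab[[nut]][idx]
      mi <- median_iqr(v)
      data.frame(subcategory = cc, nutrient = nut, n_declaring = sum(!is.na(v)),
                 median = mi[["median"]], q1 = mi[["q1"]], q3 = mi[["q3"]],
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(
    nutrient_table = nt,
    labelling_table = lt,
    high_sugar_table = hs,
    nutrient_summary = tibble::as_tibble(ns)
  ), class = "cpcf_market_report")
}

#' @export
print.cpcf_market_report <- function(x, ...) {
  nall <- x$nutrient_table[x$nutrient_table$subcategory == "all", ]
  cat("<cpcf_market_report>\n")
  if (nrow(nall)) {
    cat(sprintf("  %d products; met all nutrient requirements: %.1f%% (n = %d)\n",
                nall$n_products, nall$met_all_pct, nall$met_all_n))
    hsall <- x$high_sugar_table[x$high_sugar_table$subcategory == "all", ]
    cat(sprintf("  high-sugar warning required: %.1f%% of %d sugar-declaring products\n",
                hsall$warning_pct, hsall$n_declaring))
    lall <- x$labelling_table[x$labelling_table$subcategory == "all", ]
    cat(sprintf("  met all labelling requirements: %.1f%% (n = %d)\n",
                lall$met_all_pct, lall$met_all_n))
  }
  invisible(x)
}

#' Write a market report to disk
#'
#' Emits the full report as JSON (machine-readable, raw fractions included)
#' and each table as a CSV file.
#'
#' @param report a `cpcf_market_report`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_market_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(lapply(unclass(report), as.data.frame),
                       file.path(dir, "market_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (nm in names(report)) {
    utils::write.csv(as.data.frame(report[[nm]]),
                     file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
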
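# product_typing: assign predicted target products to broad functional
# categories (enzymes by top-level EC class, membrane transporters by
# family, other membrane proteins, other proteins, unknowns) from domain
# hits and product text via an ordered rule table.
#
# The built-in table ranks transporter rules above enzyme rules: ABC pumps
# carry nucleotide-binding domains that look enzymatic, but a pump is
# counted as a membrane transporter.

CATEGORY_MAJORS <- c("ENZYME", "MEMBRANE_TRANSPORTER", "MEMBRANE_OTHER",
                     "OTHER_PROTEIN", "UNKNOWN")

#' Load a product-category rule table
#'
#' Rules are applied in increasing `priority`; the first match decides the
#' category. Each rule matches a domain accession exactly
#' (`match_kind = "accession"`), a substring of a domain name (`"name"`), or
#' a substring of the product text (`"keyword"`); matching is
#' case-insensitive. The built-in table covers the MFS/ABC/RND transporter
#' families, common enzyme keywords per EC class, the NADB_Rossmann
#' (cl09931) and acyl-CoA dehydrogenase (cl09933) superfamilies, explicit
#' `EC n` tokens, membrane keywords, and regulator keywords.
#'
#' @param path Optional TSV with columns `pattern`, `match_kind`, `major`,
#'   `ec_class`, `family`, `priority`. `NULL` loads the built-in table.
#' @return Tibble of rules sorted by priority.
#' @export
load_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "category_rules.tsv", package = "tfrctx")
  }
  rules <- readr::read_tsv(path, show_col_types = FALSE, na = "NA",
                           col_types = readr::cols(
                             pattern = readr::col_character(),
                             match_kind = readr::col_character(),
                             major = readr::col_character(),
                             ec_class = readr::col_integer(),
                             family = readr::col_character(),
                             priority = readr::col_integer()))
  if (any(!rules$major %in% CATEGORY_MAJORS)) {
    bad <- setdiff(unique(rules$major), CATEGORY_MAJORS)
    abort(sprintf("unknown category label(s): %s", paste(bad, collapse = ", ")))
  }
  if (any(!rules$match_kind %in% c("accession", "name", "keyword"))) {
    abort("match_kind must be accession, name or keyword")
  }
  if (anyDuplicated(rules$priority)) {
    abort("rule priorities must be unique")
  }
  if (any(is.na(rules$pattern) | rules$pattern == "")) {
    abort("rule patterns must be non-empty")
  }
  dplyr::arrange(rules, .data$priority)
}

#' Categorize one gene product
#'
#' Applies the rule table to the gene's domain hits and product text; the
#' matching rule with the lowest priority number wins. No match yields
#' UNKNOWN.
#'
#' @param gene One-row gene tibble (uses `locus_tag`, `product`).
#' @param hits Domain-hit tibble restricted or restrictable to this locus.
#' @param rules Rule tibble from [load_rules()].
#' @return One-row tibble: `locus_tag`, `major`, `ec_class`, `family`,
#'   `matched_pattern`, `matched_priority`, `evidence`.
#' @export
categorize_product <- function(gene, hits = NULL, rules = load_rules()) {
  lt <- gene$locus_tag
  product <- if ("product" %in% names(gene)) gene$product else NA_character_
  if (!is.null(hits) && nrow(hits) > 0) {
    hits <- dplyr::filter(as_tibble(hits), .data$locus_tag == lt)
  } else {
    hits <- tibble(locus_tag = character(), domain_accession = character(),
                   domain_name = character())
  }
  acc <- if ("domain_accession" %in% names(hits))
    toupper(hits$domain_accession) else character()
  nm <- if ("domain_name" %in% names(hits))
    toupper(hits$domain_name) else character()
  nm <- nm[!is.na(nm)]
  ptxt <- if (is.na(product)) "" else toupper(product)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    pat <- toupper(r$pattern)
    hit <- switch(r$match_kind,
      accession = any(acc == pat),
      name = length(nm) > 0 && any(grepl(pat, nm, fixed = TRUE)),
      keyword = nzchar(ptxt) && grepl(pat, ptxt, fixed = TRUE)
    )
    if (isTRUE(hit)) {
      evidence <- switch(r$match_kind,
        accession = sprintf("domain accession %s", r$pattern),
        name = sprintf("domain name contains '%s'", r$pattern),
        keyword = sprintf("product text contains '%s'", r$pattern))
      return(tibble(locus_tag = lt, major = r$major, ec_class = r$ec_class,
                    family = r$family, matched_pattern = r$pattern,
                    matched_priority = r$priority, evidence = evidence))
    }
  }
  tibble(locus_tag = lt, major = "UNKNOWN", ec_class = NA_integer_,
         family = NA_character_, matched_pattern = NA_character_,
         matched_priority = NA_integer_,
         evidence = if (nzchar(ptxt)) sprintf("no rule matched product '%s'", product)
                    else "no domain hit, no product text")
}

#' Categorize all predicted target products
#'
#' One category call per prediction target, plus a count table by major
#' category (with EC breakdown inside ENZYME) and the per-category fraction
#' of targets whose TFR lies within the distance threshold.
#'
#' @param predictions Prediction tibble from [predict_targets()].
#' @param bundle An [annotation_bundle()].
#' @param hits Optional domain-hit tibble.
#' @param rules Rule tibble from [load_rules()].
#' @return List of class `category_result`: `calls` (per-target tibble with
#'   `predicted` carried through), `counts` (per major), `ec_counts`
#'   (ENZYME by class), `within_threshold` (per major: total, n within,
#'   fraction).
#' @export
categorize_all <- function(predictions, bundle, hits = NULL,
                           rules = load_rules()) {
  predictions <- as_tibble(predictions)
  if (nrow(predictions) == 0) {
    empty <- tibble(major = character(), n = integer())
    return(structure(list(
      calls = tibble(), counts = empty,
      ec_counts = tibble(ec_class = integer(), n = integer()),
      within_threshold = tibble(major = character(), n_total = integer(),
                                n_within = integer(), fraction = double())),
      class = "category_result"))
  }
  calls <- purrr::map_dfr(seq_len(nrow(predictions)), function(i) {
    tgt <- predictions$target_locus[i]
    gene <- bundle$genes[bundle$genes$locus_tag == tgt, ]
    if (nrow(gene) != 1) {
      abort(sprintf("prediction target not in bundle: %s", tgt))
    }
    dplyr::bind_cols(
      tibble(tfr_locus = predictions$tfr_locus[i],
             predicted = predictions$predicted[i]),
      categorize_product(gene, hits, rules)
    )
  })
  counts <- dplyr::count(calls, .data$major, name = "n")
  ec_counts <- calls |>
    dplyr::filter(.data$major == "ENZYME") |>
    dplyr::count(.data$ec_class, name = "n")
  within <- calls |>
    dplyr::group_by(.data$major) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_within = sum(.data$predicted),
                     fraction = .data$n_within / .data$n_total,
                     .groups = "drop")
  structure(list(calls = calls, counts = counts, ec_counts = ec_counts,
                 within_threshold = within),
            class = "category_result")
}

#' @export
print.category_result <- function(x, ...) {
  cat(sprintf("<category_result> %d target(s)\n", nrow(x$calls)))
  print(x$counts)
  invisible(x)
}

#' Write category calls as TSV
#'
#' @param result A `category_result` from [categorize_all()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_category_tsv <- function(result, path) {
  readr::write_tsv(result$calls, path)
  invisible(path)
}
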
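# cli_report: pipeline orchestration helpers, summary statistics and
# machine/human-readable report output.

#' Summarize a TFR genome-context analysis
#'
#' Aggregates context calls, target predictions and product categories into
#' one report: per-replicon and total TFR counts, group counts/fractions,
#' a separation histogram over divergent TFRs (default 100 bp bins with
#' edges [0,100], (100,200], ...), category counts with the EC breakdown,
#' the per-category fraction of targets within the distance threshold, and
#' optional regional TFR densities (TFRs/Mb). A consistency pass verifies
#' that group counts partition the TFR set and histogram counts sum to the
#' divergent count before the report is returned.
#'
#' @param calls Context-call tibble from [classify_context()].
#' @param predictions Optional prediction tibble from [predict_targets()].
#' @param categories Optional `category_result` from [categorize_all()].
#' @param regions Optional region tibble (`region`, `replicon_id`, `start`,
#'   `end`) for TFRs/Mb densities; TFR gene positions are looked up in
#'   `bundle`.
#' @param bundle Optional [annotation_bundle()] (needed with `regions`).
#' @param bin_width Histogram bin width in bp. Default 100.
#' @return Object of class `tfr_summary`.
#' @export
summarize_tfr_context <- function(calls, predictions = NULL, categories = NULL,
                                  regions = NULL, bundle = NULL,
                                  bin_width = 100) {
  calls <- as_tibble(calls)
  n_tfr <- nrow(calls)
  per_replicon <- dplyr::count(calls, .data$replicon_id, name = "n_tfr")
  group_levels <- c("DIVERGENT", "OPERONIC", "OTHER")
  group_counts <- calls |>
    dplyr::count(group = factor(.data$group, levels = group_levels),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(group = as.character(.data$group),
                  fraction = if (n_tfr > 0) .data$n / n_tfr else 0)
  div <- dplyr::filter(calls, .data$group == "DIVERGENT")
  histogram <- separation_histogram(div$separation_clamped, bin_width)

  # consistency pass: totals must reconcile before anything is written
  if (sum(group_counts$n) != n_tfr) {
    abort("internal inconsistency: group counts do not sum to the TFR total")
  }
  if (sum(histogram$n) != nrow(div)) {
    abort("internal inconsistency: histogram counts do not sum to divergent count")
  }

  n_predicted <- if (!is.null(predictions)) sum(as_tibble(predictions)$predicted)
                 else NA_integer_
  cat_counts <- NULL
  ec_counts <- NULL
  within <- NULL
  if (!is.null(categories)) {
    stopifnot(inherits(categories, "category_result"))
    cat_counts <- categories$counts
    ec_counts <- categories$ec_counts
    within <- categories$within_threshold
    if (!is.null(predictions) &&
        sum(cat_counts$n) != nrow(as_tibble(predictions))) {
      abort("internal inconsistency: category counts do not sum to target count")
    }
  }
  densities <- NULL
  if (!is.null(regions)) {
    if (is.null(bundle)) abort("regional densities need the annotation bundle")
    densities <- regional_density(calls, regions, bundle)
  }
  structure(list(
    n_tfr = n_tfr, per_replicon = per_replicon, group_counts = group_counts,
    histogram = histogram, n_divergent = nrow(div), n_predicted = n_predicted,
    category_counts = cat_counts, ec_counts = ec_counts,
    within_threshold = within, densities = densities,
    bin_width = bin_width
  ), class = "tfr_summary")
}

separation_histogram <- function(sep, bin_width = 100) {
  sep <- sep[!is.na(sep)]
  if (length(sep) == 0) {
    return(tibble(bin_low = integer(), bin_high = integer(), label = character(),
                  n = integer()))
  }
  top <- max(sep, bin_width)
  edges <- seq(0, ceiling(top / bin_width) * bin_width, by = bin_width)
  # first bin [0, w] inclusive of 0, later bins (kw, (k+1)w]
  idx <- pmax(ceiling(sep / bin_width), 1)
  tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    label = sprintf("%d-%d", edges[-length(edges)], edges[-1]),
    n = as.integer(tabulate(idx, nbins = length(edges) - 1))
  )
}

#' TFRs per megabase within user-supplied regions
#'
#' @param calls Context-call tibble.
#' @param regions Tibble `region`, `replicon_id`, `start`, `end`.
#' @param bundle [annotation_bundle()] used to locate TFR genes.
#' @return Tibble with `n_tfr`, `mb`, `density_raw` and the
#'   nearest-integer `density` used for display.
#' @export
regional_density <- function(calls, regions, bundle) {
  regions <- as_tibble(regions)
  tfr_pos <- dplyr::inner_join(
    as_tibble(calls)["tfr_locus"],
    dplyr::select(bundle$genes, tfr_locus = "locus_tag", "replicon_id", "start"),
    by = "tfr_locus"
  )
  purrr::map_dfr(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    n <- sum(tfr_pos$replicon_id == r$replicon_id &
             tfr_pos$start >= r$start & tfr_pos$start <= r$end)
    mb <- (r$end - r$start + 1) / 1e6
    tibble(region = r$region, replicon_id = r$replicon_id, n_tfr = n,
           mb = mb, density_raw = n / mb, density = round(n / mb))
  })
}

#' @export
print.tfr_summary <- function(x, ...) {
  cat(sprintf("<tfr_summary> %d TFR(s): %s\n", x$n_tfr,
              paste(sprintf("%s %d (%.0f%%)", x$group_counts$group,
                            x$group_counts$n, 100 * x$group_counts$fraction),
                    collapse = ", ")))
  if (!is.na(x$n_predicted)) {
    cat(sprintf("  predicted targets within threshold: %d of %d divergent\n",
                x$n_predicted, x$n_divergent))
  }
  invisible(x)
}

#' @describeIn summarize_tfr_context Per-group tidy tibble of the summary.
#' @param x A `tfr_summary`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tfr_summary <- function(x, ...) {
  x$group_counts
}

#' @describeIn summarize_tfr_context One-row overview of the summary.
#' @exportS3Method generics::glance
glance.tfr_summary <- function(x, ...) {
  g <- setNames(x$group_counts$n, tolower(x$group_counts$group))
  tibble(n_tfr = x$n_tfr, n_divergent = g[["divergent"]],
         n_operonic = g[["operonic"]], n_other = g[["other"]],
         divergent_fraction = if (x$n_tfr > 0) g[["divergent"]] / x$n_tfr else NA_real_,
         n_predicted = x$n_predicted)
}

#' @describeIn summarize_tfr_context Histogram of divergent separations.
#' @param object A `tfr_summary`.
#' @exportS3Method ggplot2::autoplot
autoplot.tfr_summary <- function(object, ...) {
  h <- object$histogram
  h$label <- factor(h$label, levels = h$label)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = sprintf("intergenic separation (bp, %d bp bins)",
                              object$bin_width),
                  y = "divergent TFRs",
                  title = "Separation of TFRs from their divergent neighbors") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar plot of context group counts
#'
#' @param calls Context-call tibble from [classify_context()].
#' @return A ggplot object.
#' @export
plot_group_counts <- function(calls) {
  d <- dplyr::count(as_tibble(calls), .data$group, name = "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "TFRs", title = "TFR genome-context groups") +
    ggplot2::theme_minimal()
}

#' Bar plot of target product categories
#'
#' @param categories A `category_result` from [categorize_all()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(categories) {
  stopifnot(inherits(categories, "category_result"))
  d <- categories$calls |>
    dplyr::mutate(label = ifelse(.data$major == "ENZYME" & !is.na(.data$ec_class),
                                 paste0("EC ", .data$ec_class), .data$major)) |>
    dplyr::count(.data$label, name = "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = NULL, y = "targets", title = "Predicted target product types") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a summary report to disk
#'
#' Writes `report.json` (machine-readable), `report.tsv` plus
#' `histogram.tsv` (flat tables), `report.md` (human-readable), and, when
#' `plot = TRUE`, `separation_histogram.png`.
#'
#' @param summary A `tfr_summary` from [summarize_tfr_context()].
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "tsv", "md")`.
#' @param plot Also write the histogram plot. Default `FALSE`.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(summary, dir, formats = c("json", "tsv", "md"),
                         plot = FALSE) {
  stopifnot(inherits(summary, "tfr_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  payload <- list(
    n_tfr = summary$n_tfr,
    per_replicon = summary$per_replicon,
    groups = summary$group_counts,
    n_divergent = summary$n_divergent,
    n_predicted = summary$n_predicted,
    separation_histogram = summary$histogram,
    category_counts = summary$category_counts,
    ec_counts = summary$ec_counts,
    within_threshold = summary$within_threshold,
    densities = summary$densities
  )
  if ("json" %in% formats) {
    p <- file.path(dir, "report.json")
    jsonlite::write_json(payload, p, dataframe = "rows", auto_unbox = TRUE,
                         na = "null", digits = NA)
    written <- c(written, p)
  }
  if ("tsv" %in% formats) {
    p <- file.path(dir, "report.tsv")
    readr::write_tsv(summary$group_counts, p)
    p2 <- file.path(dir, "histogram.tsv")
    readr::write_tsv(summary$histogram, p2)
    written <- c(written, p, p2)
  }
  if ("md" %in% formats) {
    p <- file.path(dir, "report.md")
    lines <- c(
      "# TFR genome-context report", "",
      sprintf("- TFRs analyzed: %d", summary$n_tfr),
      sprintf("- %s: %d (%.1f%%)", summary$group_counts$group,
              summary$group_counts$n, 100 * summary$group_counts$fraction),
      if (!is.na(summary$n_predicted))
        sprintf("- predicted targets within threshold: %d", summary$n_predicted),
      "", "## Separation histogram (divergent TFRs)", "",
      "| bin (bp) | n |", "|---|---|",
      sprintf("| %s | %d |", summary$histogram$label, summary$histogram$n)
    )
    writeLines(lines, p)
    written <- c(written, p)
  }
  if (isTRUE(plot)) {
    p <- file.path(dir, "separation_histogram.png")
    ggplot2::ggsave(p, autoplot(summary), width = 7, height = 4, dpi = 120)
    written <- c(written, p)
  }
  invisible(written)
}

#' Experimentally characterized TFR reference panel
#'
#' Loads the packaged panel of nine experimentally characterized
#' TFR/divergent-neighbor pairs from *S. coelicolor* and *S. griseus*
#' (locus tags, product annotations, and intergenic separations between
#' translational start sites), together with whether in vivo reporter
#' assays showed the TFR repressing the neighbor. Useful as a desk
#' benchmark for the distance rule.
#'
#' @return Tibble: `tfr_name`, `tfr_locus`, `target_locus`,
#'   `target_product`, `separation_bp`, `represses_target`.
#' @export
tfr_reference_panel <- function() {
  path <- system.file("extdata", "tfr_reference_panel.tsv", package = "tfrctx")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Experimentally footprinted operator site sequences
#'
#' Loads the packaged set of candidate operator sequences recovered from
#' DNase I footprints of seven characterized TFRs; used as regression
#' fixtures for the inverted-repeat scanner.
#'
#' @return Tibble: `tfr_name`, `site_index`, `site_seq`.
#' @export
operator_site_fixtures <- function() {
  path <- system.file("extdata", "footprint_operator_sites.tsv",
                      package = "tfrctx")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Build a minimal annotation bundle from a divergent-pair separation table
#'
#' Turns a table of TFR/neighbor separations into a synthetic linear
#' replicon in which each pair is laid out head-to-head at exactly the
#' stated separation, so the classification and prediction chain can be run
#' on published separation values directly.
#'
#' @param pairs Tibble with columns `tfr_locus`, `target_locus`,
#'   `separation_bp`.
#' @param gene_length Length given to every gene body. Default 600.
#' @param spacer Gap between successive pairs. Default 500.
#' @return List: `bundle` ([annotation_bundle()]), `tfrs` (locus tags).
#' @export
bundle_from_separations <- function(pairs, gene_length = 600, spacer = 500) {
  pairs <- as_tibble(pairs)
  stopifnot(all(c("tfr_locus", "target_locus", "separation_bp") %in% names(pairs)))
  rows <- list()
  pos <- spacer
  for (i in seq_len(nrow(pairs))) {
    tgt_start <- pos + 1
    tgt_end <- tgt_start + gene_length - 1
    tfr_start <- tgt_end + pairs$separation_bp[i] + 1
    tfr_end <- tfr_start + gene_length - 1
    rows[[2 * i - 1]] <- tibble(replicon_id = "panel", locus_tag = pairs$target_locus[i],
                                strand = "-", start = as.integer(tgt_start),
                                end = as.integer(tgt_end), feature_kind = "CDS",
                                product = NA_character_)
    rows[[2 * i]] <- tibble(replicon_id = "panel", locus_tag = pairs$tfr_locus[i],
                            strand = "+", start = as.integer(tfr_start),
                            end = as.integer(tfr_end), feature_kind = "CDS",
                            product = NA_character_)
    pos <- tfr_end + spacer
  }
  genes <- dplyr::bind_rows(rows)
  reps <- tibble(replicon_id = "panel", length = as.integer(pos + spacer),
                 topology = "linear")
  list(bundle = annotation_bundle(genes, reps), tfrs = pairs$tfr_locus)
}
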
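# context_engine: orientation classification and the intergenic distance rule.
#
# The biology behind the geometry: a TFR transcribed head-to-head with a
# neighbor shares an intergenic region containing both promoters, and in the
# TetR/tetA paradigm the TFR's operator sits in that shared DNA. Because
# transcription start sites are unknown for almost all of these genes,
# separations are measured between translational start sites (first base of
# each start codon).

#' Context-classification thresholds
#'
#' @param operon_gap_max Maximum ORF-to-ORF gap (bp) for two same-strand
#'   neighbors to be called probably co-transcribed. Default 35.
#' @param target_distance_max Maximum intergenic separation (bp) for a
#'   divergent neighbor to be predicted as a regulatory target. Default 200.
#' @param threshold_inclusive If `TRUE` (default) a separation equal to
#'   `target_distance_max` is still predicted (`<=`); if `FALSE` the rule is
#'   strict (`<`).
#' @return A list of class `context_thresholds`.
#' @export
context_thresholds <- function(operon_gap_max = 35, target_distance_max = 200,
                               threshold_inclusive = TRUE) {
  stopifnot(operon_gap_max >= 0, target_distance_max >= 0,
            is.logical(threshold_inclusive))
  structure(list(operon_gap_max = as.integer(operon_gap_max),
                 target_distance_max = as.integer(target_distance_max),
                 threshold_inclusive = threshold_inclusive),
            class = "context_thresholds")
}

#' Translational start coordinate of a gene
#'
#' The chromosomal coordinate of the first base of the start codon: `start`
#' for a `+`-strand gene, `end` for a `-`-strand gene. Vectorized.
#'
#' @param strand Character vector of `"+"`/`"-"`, or a gene tibble/row
#'   (in which case `start`/`end` are taken from it).
#' @param start,end Integer vectors of 1-based inclusive gene bounds.
#' @return Integer vector of start-codon coordinates.
#' @examples
#' translational_start("+", 100, 400) # 100
#' translational_start("-", 100, 400) # 400
#' @export
translational_start <- function(strand, start = NULL, end = NULL) {
  if (is.data.frame(strand)) {
    g <- strand
    strand <- g$strand; start <- g$start; end <- g$end
  }
  stopifnot(all(strand %in% c("+", "-")))
  ifelse(strand == "+", start, end)
}

#' Relative arrangement of two adjacent genes
#'
#' For a left gene strictly before a right gene on the same replicon:
#' divergent (head-to-head) when the left gene is on `-` and the right on
#' `+`; convergent (tail-to-tail) when left `+` / right `-`; tandem
#' otherwise. Vectorized over strand pairs.
#'
#' @param strand_left,strand_right Strands of the left and right gene.
#' @return Character vector in `{"divergent","convergent","tandem"}`.
#' @export
arrangement <- function(strand_left, strand_right) {
  stopifnot(all(strand_left %in% c("+", "-")), all(strand_right %in% c("+", "-")))
  dplyr::case_when(
    strand_left == "-" & strand_right == "+" ~ "divergent",
    strand_left == "+" & strand_right == "-" ~ "convergent",
    TRUE ~ "tandem"
  )
}

#' Immediate neighbors of a gene
#'
#' Neighbors are the immediate predecessor and successor in coordinate
#' order on the gene's replicon. On a linear replicon the outward side of a
#' terminal gene is absent (`NULL`); on a circular replicon neighbors wrap
#' around the origin. Genes duplicating the query's exact coordinates are
#' ignored; ordering ties are broken by locus tag.
#'
#' @param bundle An [annotation_bundle()].
#' @param locus_tag Locus tag of the query gene.
#' @return List with elements `left` and `right`, each a one-row gene
#'   tibble or `NULL`.
#' @export
gene_neighbors <- function(bundle, locus_tag) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  g <- bundle$genes
  at <- which(g$locus_tag == locus_tag)
  if (length(at) != 1) abort(sprintf("locus tag not in bundle: %s", locus_tag))
  me <- g[at, ]
  sib <- g[g$replicon_id == me$replicon_id, ]
  # drop exact-coordinate duplicates of the query (keep the query itself)
  dup <- sib$start == me$start & sib$end == me$end & sib$locus_tag != me$locus_tag
  sib <- sib[!dup, ]
  idx <- which(sib$locus_tag == locus_tag)
  n <- nrow(sib)
  topology <- bundle$replicons$topology[bundle$replicons$replicon_id == me$replicon_id]
  circular <- identical(topology, "circular")
  left <- if (idx > 1) sib[idx - 1, ] else if (circular && n > 1) sib[n, ] else NULL
  right <- if (idx < n) sib[idx + 1, ] else if (circular && n > 1) sib[1, ] else NULL
  list(left = left, right = right)
}

#' Intergenic separation of a divergent gene pair
#'
#' Counts the bases strictly between the first bases of the two start
#' codons: `translational_start(right) - translational_start(left) - 1`.
#' The raw value can be negative when annotated start codons overlap; the
#' clamped value floors it at 0 (the reported minimum separation for real
#' divergent pairs is 0 bp).
#'
#' @param left_gene,right_gene One-row gene tibbles; `left_gene` must lie
#'   strictly before `right_gene` and the pair must be divergent
#'   (left `-`, right `+`).
#' @return One-row tibble: `left_locus`, `right_locus`, `raw_bp`, `clamped_bp`.
#' @export
intergenic_separation <- function(left_gene, right_gene) {
  if (arrangement(left_gene$strand, right_gene$strand) != "divergent") {
    abort("intergenic_separation is defined for divergent (head-to-head) pairs only")
  }
  if (left_gene$start > right_gene$start) {
    abort("left_gene must precede right_gene in coordinate order")
  }
  raw <- as.integer(translational_start(right_gene) -
                    translational_start(left_gene) - 1L)
  tibble(left_locus = left_gene$locus_tag, right_locus = right_gene$locus_tag,
         raw_bp = raw, clamped_bp = max(raw, 0L))
}

#' ORF-to-ORF gap between adjacent same-strand genes
#'
#' `right$start - left$end - 1`: the bases strictly between the two ORF
#' extremes. Negative for overlapping ORFs. This is the quantity tested
#' against the co-transcription (operon) gap threshold.
#'
#' @param left_gene,right_gene One-row gene tibbles on the same strand,
#'   left before right.
#' @return Integer gap (possibly negative).
#' @export
boundary_gap <- function(left_gene, right_gene) {
  if (left_gene$strand != right_gene$strand) {
    abort("boundary_gap is defined for same-strand gene pairs only")
  }
  as.integer(right_gene$start - left_gene$end - 1L)
}

#' Classify the genome context of TFR genes
#'
#' Assigns each TFR to exactly one of three groups:
#' \describe{
#'   \item{DIVERGENT}{the immediate neighbor on the TFR's 5' side is
#'     head-to-head with it, at any separation;}
#'   \item{OPERONIC}{no divergent neighbor, but an immediate same-strand
#'     neighbor (either side) lies within `operon_gap_max` of the TFR's ORF
#'     (overlapping ORFs count), so the pair is probably co-transcribed;}
#'   \item{OTHER}{neither relationship holds.}
#' }
#' A TFR with a divergent neighbor on one side and a co-transcribed
#' neighbor on the other is DIVERGENT with `mixed_flag = TRUE`.
#'
#' @param bundle An [annotation_bundle()].
#' @param tfrs Character vector of TFR locus tags (see [read_tfr_list()],
#'   [select_tfrs()]).
#' @param thresholds A [context_thresholds()] object.
#' @return Tibble with one row per TFR: `tfr_locus`, `replicon_id`, `group`,
#'   `mixed_flag`, `divergent_neighbor`, `separation_raw`,
#'   `separation_clamped`, `operonic_neighbors` (comma-joined, `""` if none).
#' @export
classify_context <- function(bundle, tfrs, thresholds = context_thresholds()) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  tfrs <- unique(tfrs)
  if (length(tfrs) == 0) {
    return(tibble(tfr_locus = character(), replicon_id = character(),
                  group = character(), mixed_flag = logical(),
                  divergent_neighbor = character(),
                  separation_raw = integer(), separation_clamped = integer(),
                  operonic_neighbors = character()))
  }
  unknown <- setdiff(tfrs, bundle$genes$locus_tag)
  if (length(unknown) > 0) {
    abort(sprintf("TFR locus tag(s) not in bundle: %s",
                  paste(unknown, collapse = ", ")))
  }
  purrr::map_dfr(tfrs, function(lt) {
    me <- bundle$genes[bundle$genes$locus_tag == lt, ]
    nb <- gene_neighbors(bundle, lt)

    # head-to-head test: only the 5'-side neighbor can face the TFR
    div_nb <- NULL
    sep <- NULL
    if (me$strand == "+" && !is.null(nb$left) &&
        arrangement(nb$left$strand, me$strand) == "divergent") {
      div_nb <- nb$left
      sep <- intergenic_separation(nb$left, me)
    } else if (me$strand == "-" && !is.null(nb$right) &&
               arrangement(me$strand, nb$right$strand) == "divergent") {
      div_nb <- nb$right
      sep <- intergenic_separation(me, nb$right)
    }

    # co-transcription test: same-strand immediate neighbor within the gap
    op_nbs <- character()
    if (!is.null(nb$left) && nb$left$strand == me$strand &&
        boundary_gap(nb$left, me) <= thresholds$operon_gap_max) {
      op_nbs <- c(op_nbs, nb$left$locus_tag)
    }
    if (!is.null(nb$right) && nb$right$strand == me$strand &&
        boundary_gap(me, nb$right) <= thresholds$operon_gap_max) {
      op_nbs <- c(op_nbs, nb$right$locus_tag)
    }

    group <- if (!is.null(div_nb)) "DIVERGENT"
             else if (length(op_nbs) > 0) "OPERONIC"
             else "OTHER"
    tibble(
      tfr_locus = lt,
      replicon_id = me$replicon_id,
      group = group,
      mixed_flag = !is.null(div_nb) && length(op_nbs) > 0,
      divergent_neighbor = if (!is.null(div_nb)) div_nb$locus_tag else NA_character_,
      separation_raw = if (!is.null(sep)) sep$raw_bp else NA_integer_,
      separation_clamped = if (!is.null(sep)) sep$clamped_bp else NA_integer_,
      operonic_neighbors = if (group == "OPERONIC" || (length(op_nbs) > 0))
        paste(op_nbs, collapse = ",") else ""
    )
  })
}

#' Predict regulatory targets with the intergenic distance rule
#'
#' One prediction per DIVERGENT context call. The TFR is predicted to
#' regulate its divergent neighbor when the clamped separation is within
#' `target_distance_max` (inclusively by default); closer pairs get tier
#' `"strong"`, farther ones `"weak"`. Non-divergent TFRs yield no row.
#'
#' @param calls Context-call tibble from [classify_context()].
#' @param thresholds A [context_thresholds()] object.
#' @return Tibble: `tfr_locus`, `target_locus`, `separation_bp`,
#'   `threshold_bp`, `predicted`, `tier`.
#' @export
predict_targets <- function(calls, thresholds = context_thresholds()) {
  calls <- as_tibble(calls)
  div <- dplyr::filter(calls, .data$group == "DIVERGENT")
  if (nrow(div) == 0) {
    return(tibble(tfr_locus = character(), target_locus = character(),
                  separation_bp = integer(), threshold_bp = integer(),
                  predicted = logical(), tier = character()))
  }
  within <- if (thresholds$threshold_inclusive) {
    div$separation_clamped <= thresholds$target_distance_max
  } else {
    div$separation_clamped < thresholds$target_distance_max
  }
  tibble(
    tfr_locus = div$tfr_locus,
    target_locus = div$divergent_neighbor,
    separation_bp = div$separation_clamped,
    threshold_bp = thresholds$target_distance_max,
    predicted = within,
    tier = ifelse(within, "strong", "weak")
  )
}

#' Extract intergenic regions of divergent TFR pairs
#'
#' Returns, for each DIVERGENT context call with positive raw separation,
#' the forward-strand DNA strictly between the two start-codon first bases,
#' with coordinates both 1-based inclusive (`start`,`end`) and 0-based
#' half-open (`bed_start`,`bed_end`). Calls with separation <= 0 yield an
#' empty sequence with a warning; non-divergent calls are dropped.
#'
#' @param bundle An [annotation_bundle()] carrying sequence.
#' @param calls Context-call tibble from [classify_context()].
#' @return Tibble: `tfr_locus`, `target_locus`, `replicon_id`, `start`,
#'   `end`, `bed_start`, `bed_end`, `length`, `seq`. The sequence reads in
#'   forward-strand orientation; `tfr_first` says whether the TFR gene lies
#'   on the left (so offset 0 of `seq` is the TFR-proximal end).
#' @export
extract_igr <- function(bundle, calls) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  if (is.null(bundle$sequences)) {
    abort("bundle carries no sequence; IGR extraction needs FASTA/ORIGIN input")
  }
  div <- dplyr::filter(as_tibble(calls), .data$group == "DIVERGENT")
  rows <- purrr::map_dfr(seq_len(nrow(div)), function(i) {
    cl <- div[i, ]
    me <- bundle$genes[bundle$genes$locus_tag == cl$tfr_locus, ]
    nb <- bundle$genes[bundle$genes$locus_tag == cl$divergent_neighbor, ]
    left <- if (me$start <= nb$start) me else nb
    right <- if (me$start <= nb$start) nb else me
    ts_l <- translational_start(left)
    ts_r <- translational_start(right)
    if (cl$separation_raw <= 0) {
      warn(sprintf("divergent pair %s/%s has separation <= 0; empty IGR",
                   cl$tfr_locus, cl$divergent_neighbor))
      return(tibble(tfr_locus = cl$tfr_locus, target_locus = cl$divergent_neighbor,
                    replicon_id = me$replicon_id, start = NA_integer_,
                    end = NA_integer_, bed_start = NA_integer_,
                    bed_end = NA_integer_, length = 0L, seq = "",
                    tfr_first = me$start <= nb$start))
    }
    s <- ts_l + 1L
    e <- ts_r - 1L
    seq <- substr(bundle$sequences[[me$replicon_id]], s, e)
    tibble(tfr_locus = cl$tfr_locus, target_locus = cl$divergent_neighbor,
           replicon_id = me$replicon_id, start = s, end = e,
           bed_start = s - 1L, bed_end = e, length = e - s + 1L, seq = seq,
           tfr_first = me$start <= nb$start)
  })
  rows
}

#' Write intergenic regions as FASTA
#'
#' Headers read `tfr|target|replicon:start-end` (1-based inclusive).
#'
#' @param igrs IGR tibble from [extract_igr()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_igr_fasta <- function(igrs, path) {
  igrs <- dplyr::filter(as_tibble(igrs), .data$length > 0)
  dss <- Biostrings::DNAStringSet(igrs$seq)
  names(dss) <- sprintf("%s|%s|%s:%d-%d", igrs$tfr_locus, igrs$target_locus,
                        igrs$replicon_id, igrs$start, igrs$end)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write intergenic regions as BED (0-based half-open)
#'
#' @param igrs IGR tibble from [extract_igr()].
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_igr_bed <- function(igrs, path) {
  igrs <- dplyr::filter(as_tibble(igrs), .data$length > 0)
  bed <- tibble(chrom = igrs$replicon_id, start = igrs$bed_start,
                end = igrs$bed_end,
                name = paste(igrs$tfr_locus, igrs$target_locus, sep = "|"))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Recompute separations for named divergent locus pairs
#'
#' A spot-check helper: given locus pairs (in either order) it resolves both
#' genes in the bundle, orients them by coordinate, and recomputes the
#' translational-start separation. Pairs whose two genes are not divergent
#' or not both present get `NA` with a note.
#'
#' @param bundle An [annotation_bundle()].
#' @param pairs Tibble with columns `locus_a`, `locus_b`.
#' @return `pairs` with added `separation_bp` and `note` columns.
#' @export
spot_check_separations <- function(bundle, pairs) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  pairs <- as_tibble(pairs)
  res <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- bundle$genes[bundle$genes$locus_tag == pairs$locus_a[i], ]
    b <- bundle$genes[bundle$genes$locus_tag == pairs$locus_b[i], ]
    if (nrow(a) != 1 || nrow(b) != 1) {
      return(tibble(separation_bp = NA_integer_, note = "locus not found"))
    }
    left <- if (a$start <= b$start) a else b
    right <- if (a$start <= b$start) b else a
    if (arrangement(left$strand, right$strand) != "divergent") {
      return(tibble(separation_bp = NA_integer_, note = "pair not divergent"))
    }
    sep <- intergenic_separation(left, right)
    tibble(separation_bp = sep$clamped_bp, note = "")
  })
  dplyr::bind_cols(pairs, res)
}

#' Write per-TFR classification results as TSV
#'
#' Joins context calls with target predictions into the flat per-TFR table
#' (`tfr_locus`, `replicon`, `group`, `mixed_flag`, `divergent_neighbor`,
#' `separation_raw`, `separation_clamped`, `predicted`, `tier`).
#'
#' @param calls Context-call tibble.
#' @param predictions Prediction tibble from [predict_targets()].
#' @param path Output TSV path.
#' @return The joined tibble, invisibly.
#' @export
write_classification_tsv <- function(calls, predictions, path) {
  out <- dplyr::left_join(
    as_tibble(calls),
    dplyr::select(as_tibble(predictions), "tfr_locus", "predicted", "tier"),
    by = "tfr_locus"
  ) |>
    dplyr::rename(replicon = "replicon_id")
  readr::write_tsv(out, path)
  invisible(out)
}
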
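# annotation_io: genome annotation in, gene tables out.
#
# The internal gene model is deliberately small: a tibble of coding features
# (replicon_id, locus_tag, strand, start, end, feature_kind, product) with
# 1-based inclusive coordinates, bundled with per-replicon metadata and,
# optionally, the replicon sequences. GFF3 is read through rtracklayer and
# FASTA through Biostrings; GenBank flat files are parsed by a minimal
# feature-table reader because the analysis needs only CDS extremes, strand
# and qualifiers.

#' Construct an annotation bundle
#'
#' An annotation bundle holds one or more replicons' worth of gene
#' annotation: a gene tibble, a replicon metadata tibble, and optional
#' sequences. Locus tags must be unique across the whole bundle; genes are
#' stored sorted by start coordinate (ties by end, then locus tag) within
#' each replicon.
#'
#' @param genes Tibble with columns `replicon_id`, `locus_tag`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (1-based inclusive, `end >= start`),
#'   `feature_kind`, `product`.
#' @param replicons Tibble with columns `replicon_id`, `length`, `topology`
#'   (`"linear"` or `"circular"`).
#' @param sequences Named character vector of replicon sequences, or `NULL`.
#' @param source_path Provenance: path the bundle was read from, or `NA`.
#' @return An object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(genes, replicons, sequences = NULL,
                              source_path = NA_character_) {
  genes <- as_tibble(genes)
  replicons <- as_tibble(replicons)
  required <- c("replicon_id", "locus_tag", "strand", "start", "end",
                "feature_kind", "product")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(sprintf("gene table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) > 0) {
    if (any(is.na(genes$locus_tag)) || any(genes$locus_tag == "")) {
      abort("every gene needs a non-empty locus_tag")
    }
    if (anyDuplicated(genes$locus_tag)) {
      dup <- unique(genes$locus_tag[duplicated(genes$locus_tag)])
      abort(sprintf("duplicate locus_tag(s): %s", paste(dup, collapse = ", ")))
    }
    if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
    if (any(genes$start < 1) || any(genes$end < genes$start)) {
      abort("coordinates must satisfy 1 <= start <= end")
    }
    len <- setNames(replicons$length, replicons$replicon_id)
    if (!all(genes$replicon_id %in% replicons$replicon_id)) {
      abort("gene replicon_id absent from replicon table")
    }
    if (any(genes$end > len[genes$replicon_id])) {
      abort("gene coordinates exceed replicon length")
    }
    genes <- dplyr::arrange(genes, .data$replicon_id, .data$start, .data$end,
                            .data$locus_tag)
  }
  if (!is.null(sequences)) {
    sequences <- toupper(unlist(sequences))
    for (rid in names(sequences)) {
      want <- replicons$length[replicons$replicon_id == rid]
      if (length(want) == 1 && nchar(sequences[[rid]]) != want) {
        abort(sprintf("sequence length for %s (%d) != declared length (%d)",
                      rid, nchar(sequences[[rid]]), want))
      }
    }
  }
  checksum <- if (!is.na(source_path) && file.exists(source_path)) {
    unname(tools::md5sum(source_path))
  } else {
    NA_character_
  }
  structure(
    list(genes = genes, replicons = replicons, sequences = sequences,
         source_path = source_path, checksum = checksum),
    class = "annotation_bundle"
  )
}

#' @export
print.annotation_bundle <- function(x, ...) {
  cat(sprintf("<annotation_bundle> %d replicon(s), %d gene(s)%s\n",
              nrow(x$replicons), nrow(x$genes),
              if (is.null(x$sequences)) "" else ", with sequence"))
  print(x$replicons)
  invisible(x)
}

#' @export
format.annotation_bundle <- function(x, ...) {
  sprintf("<annotation_bundle: %d genes on %d replicon(s)>",
          nrow(x$genes), nrow(x$replicons))
}

empty_gene_table <- function() {
  tibble(replicon_id = character(), locus_tag = character(),
         strand = character(), start = integer(), end = integer(),
         feature_kind = character(), product = character())
}

# ---------------------------------------------------------------------------
# GenBank flat file

#' Read a GenBank flat file into an annotation bundle
#'
#' Parses one or more GenBank records. Every CDS feature carrying a
#' `locus_tag` qualifier becomes a gene; CDS features lacking a locus tag
#' are skipped with a warning. Compound (`join`) locations collapse to their
#' extremes; strand comes from `complement()`. Topology is taken from the
#' LOCUS line, defaulting to linear. The ORIGIN block, when present, is
#' attached as the replicon sequence.
#'
#' @param path Path to a GenBank flat file.
#' @param cds_only If `TRUE` (default) only CDS features become genes;
#'   otherwise any feature with a locus_tag is admitted (its key recorded in
#'   `feature_kind`).
#' @return An [annotation_bundle()].
#' @export
read_genbank <- function(path, cds_only = TRUE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(startsWith(lines, "LOCUS"))) {
    abort(sprintf("not a GenBank flat file (no LOCUS line): %s", path))
  }
  rec_starts <- which(startsWith(lines, "LOCUS"))
  rec_ends <- c(rec_starts[-1] - 1L, length(lines))
  genes <- list()
  reps <- list()
  seqs <- character()
  n_skipped <- 0L
  for (r in seq_along(rec_starts)) {
    rec <- lines[rec_starts[r]:rec_ends[r]]
    parsed <- parse_genbank_record(rec, cds_only = cds_only,
                                   record_index = r)
    genes[[r]] <- parsed$genes
    reps[[r]] <- parsed$replicon
    n_skipped <- n_skipped + parsed$n_skipped
    if (!is.na(parsed$sequence)) seqs[[parsed$replicon$replicon_id]] <- parsed$sequence
  }
  if (n_skipped > 0) {
    warn(sprintf("skipped %d feature(s) lacking a locus_tag qualifier", n_skipped))
  }
  annotation_bundle(
    genes = dplyr::bind_rows(genes),
    replicons = dplyr::bind_rows(reps),
    sequences = if (length(seqs)) seqs else NULL,
    source_path = path
  )
}

parse_genbank_record <- function(rec, cds_only, record_index) {
  locus_line <- rec[1]
  toks <- strsplit(trimws(locus_line), "\\s+")[[1]]
  if (length(toks) < 3 || toks[1] != "LOCUS") {
    abort(sprintf("malformed LOCUS line in record %d: '%s'",
                  record_index, locus_line))
  }
  replicon_id <- toks[2]
  bp_idx <- which(toks == "bp")
  declared_len <- if (length(bp_idx) == 1 && bp_idx > 1) {
    suppressWarnings(as.integer(toks[bp_idx - 1]))
  } else {
    NA_integer_
  }
  topology <- if (any(toks == "circular")) "circular" else "linear"

  feat_start <- which(startsWith(rec, "FEATURES"))
  origin_at <- which(startsWith(rec, "ORIGIN"))
  sequence <- NA_character_
  if (length(origin_at) == 1) {
    seq_lines <- rec[(origin_at + 1):length(rec)]
    seq_lines <- seq_lines[!startsWith(seq_lines, "//")]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) == 0) sequence <- NA_character_
  }
  genes <- empty_gene_table()
  n_skipped <- 0L
  if (length(feat_start) == 1) {
    last <- if (length(origin_at) == 1) origin_at - 1L else length(rec)
    ftab <- rec[(feat_start + 1):last]
    ftab <- ftab[!startsWith(ftab, "//") & nzchar(trimws(ftab))]
    # feature key lines are indented 5, qualifier/continuation lines 21
    is_key <- grepl("^ {5}\\S", ftab)
    if (any(is_key)) {
      key_idx <- which(is_key)
      blocks <- purrr::map2(key_idx, c(key_idx[-1] - 1L, length(ftab)),
                            function(a, b) ftab[a:b])
      rows <- list()
      for (bl in blocks) {
        key <- sub("^ {5}(\\S+).*", "\\1", bl[1])
        if (cds_only && key != "CDS") next
        if (!cds_only && key %in% c("source")) next
        loc_txt <- sub("^ {5}\\S+\\s+", "", bl[1])
        qual_at <- grep("^\\s+/", bl)
        loc_end <- if (length(qual_at)) min(qual_at) - 1L else length(bl)
        if (loc_end > 1) {
          loc_txt <- paste0(loc_txt, paste(trimws(bl[2:loc_end]), collapse = ""))
        }
        loc <- parse_genbank_location(loc_txt, record_index)
        quals <- parse_genbank_qualifiers(bl[qual_at], bl, qual_at)
        if (is.null(quals$locus_tag)) {
          n_skipped <- n_skipped + 1L
          next
        }
        rows[[length(rows) + 1L]] <- tibble(
          replicon_id = replicon_id, locus_tag = quals$locus_tag,
          strand = loc$strand, start = loc$start, end = loc$end,
          feature_kind = if (key == "CDS") "CDS" else key,
          product = quals$product %||% NA_character_
        )
      }
      if (length(rows)) genes <- dplyr::bind_rows(rows)
    }
  }
  if (is.na(declared_len)) {
    declared_len <- if (!is.na(sequence)) nchar(sequence)
                    else if (nrow(genes)) max(genes$end) else 0L
  }
  list(
    genes = genes,
    replicon = tibble(replicon_id = replicon_id,
                      length = as.integer(declared_len),
                      topology = topology),
    sequence = sequence,
    n_skipped = n_skipped
  )
}

parse_genbank_location <- function(txt, record_index) {
  txt <- gsub("\\s", "", txt)
  strand <- if (grepl("^complement\\(", txt)) "-" else "+"
  inner <- gsub("complement\\(|join\\(|order\\(|\\)", "", txt)
  inner <- gsub("[<>]", "", inner)
  parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
  bounds <- suppressWarnings(
    as.integer(unlist(strsplit(parts, "\\.\\.")))
  )
  bounds <- bounds[!is.na(bounds)]
  if (length(bounds) == 0) {
    abort(sprintf("unparseable feature location '%s' in record %d",
                  txt, record_index))
  }
  # compound locations collapse to their extremes
  list(strand = strand, start = min(bounds), end = max(bounds))
}

parse_genbank_qualifiers <- function(qual_lines, block, qual_at) {
  # re-join continuation lines (indented, not starting with '/')
  if (length(qual_at) == 0) return(list())
  out <- list()
  current_key <- NULL
  current_val <- NULL
  for (i in seq(min(qual_at), length(block))) {
    ln <- trimws(block[i])
    if (startsWith(ln, "/")) {
      if (!is.null(current_key)) out[[current_key]] <- current_val
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        current_key <- substr(ln, 2, eq - 1)
        current_val <- gsub('^"|"$', "", substr(ln, eq + 1, nchar(ln)))
      } else {
        current_key <- substring(ln, 2)
        current_val <- TRUE
      }
    } else if (!is.null(current_key) && is.character(current_val)) {
      sep <- if (current_key == "translation") "" else " "
      current_val <- paste(current_val, gsub('"$', "", ln), sep = sep)
    }
  }
  if (!is.null(current_key)) out[[current_key]] <- current_val
  out
}

#' Write an annotation bundle as a GenBank flat file
#'
#' Emits one record per replicon with CDS features and, when the bundle
#' carries sequence, an ORIGIN block. The output re-parses losslessly with
#' [read_genbank()].
#'
#' @param bundle An [annotation_bundle()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(bundle, path) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(bundle$replicons))) {
    rep <- bundle$replicons[i, ]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT 01-JAN-2000",
                       rep$replicon_id, rep$length, rep$topology), con)
    writeLines(sprintf("DEFINITION  %s synthetic annotation.", rep$replicon_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", rep$length), con)
    genes <- dplyr::filter(bundle$genes, .data$replicon_id == rep$replicon_id)
    for (j in seq_len(nrow(genes))) {
      g <- genes[j, ]
      loc <- sprintf("%d..%d", g$start, g$end)
      if (g$strand == "-") loc <- sprintf("complement(%s)", loc)
      key <- format(g$feature_kind, width = 16)
      writeLines(sprintf("     %s%s", key, loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$locus_tag), con)
      if (!is.na(g$product) && nzchar(g$product)) {
        writeLines(sprintf("                     /product=\"%s\"", g$product), con)
      }
    }
    seq <- bundle$sequences[[rep$replicon_id]] %||% NA_character_
    if (!is.na(seq)) {
      writeLines("ORIGIN", con)
      pos <- seq(1, nchar(seq), by = 60)
      for (p in pos) {
        chunk <- substr(seq, p, min(p + 59, nchar(seq)))
        tens <- strsplit(gsub("(.{10})", "\\1 ", chunk), " ")[[1]]
        writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))), con)
      }
    }
    writeLines("//", con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3 (+ FASTA)

#' Read GFF3 (and optional FASTA) into an annotation bundle
#'
#' CDS features (or `gene` features where a replicon has no CDS rows) become
#' genes; the locus tag is taken from the `locus_tag` attribute, falling
#' back to `ID`. When a FASTA file is supplied its headers must cover every
#' seqid used in the GFF3; sequences are attached to the bundle.
#'
#' @param gff_path Path to a GFF3 file.
#' @param fasta_path Optional path to the matching FASTA.
#' @param cds_only If `TRUE` (default) only CDS (with gene fallback)
#'   features are used; otherwise all annotated feature types are admitted.
#' @return An [annotation_bundle()].
#' @export
read_gff3 <- function(gff_path, fasta_path = NULL, cds_only = TRUE) {
  if (!file.exists(gff_path)) abort(sprintf("no such file: %s", gff_path))
  gr <- rtracklayer::import.gff3(gff_path)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  seqs <- NULL
  seq_len_tbl <- NULL
  if (!is.null(fasta_path)) {
    dss <- Biostrings::readDNAStringSet(fasta_path)
    names(dss) <- sub("\\s.*$", "", names(dss))
    missing_ids <- setdiff(unique(as.character(df$seqnames)), names(dss))
    if (length(missing_ids) > 0) {
      abort(sprintf("seqid(s) in GFF3 absent from FASTA: %s",
                    paste(missing_ids, collapse = ", ")))
    }
    seqs <- setNames(as.character(dss), names(dss))
    seq_len_tbl <- tibble(replicon_id = names(dss),
                          length = nchar(unname(seqs)))
  }
  keep_types <- if (cds_only) c("CDS", "gene") else unique(as.character(df$type))
  df <- df[as.character(df$type) %in% keep_types, , drop = FALSE]
  if (nrow(df) == 0) {
    warn("GFF3 contained no recognized gene/CDS features; bundle is empty")
    rep_tbl <- seq_len_tbl %||% tibble(replicon_id = character(), length = integer())
    rep_tbl$topology <- rep("linear", nrow(rep_tbl))
    return(annotation_bundle(empty_gene_table(), rep_tbl, seqs, gff_path))
  }
  lt <- df$locus_tag %||% rep(NA_character_, nrow(df))
  id <- df$ID %||% rep(NA_character_, nrow(df))
  df$.locus <- dplyr::coalesce(as.character(lt), as.character(id))
  if (cds_only) {
    # prefer CDS rows; fall back to gene rows for loci without a CDS row
    cds <- df[as.character(df$type) == "CDS", , drop = FALSE]
    gn <- df[as.character(df$type) == "gene", , drop = FALSE]
    gn <- gn[!(gn$.locus %in% cds$.locus), , drop = FALSE]
    df <- rbind(cds, gn)
  }
  df <- df[!is.na(df$.locus), , drop = FALSE]
  if (is.null(df$product)) df$product <- NA_character_
  # one row per locus: compound CDS segments collapse to extremes
  genes <- df |>
    as_tibble() |>
    dplyr::group_by(.data$.locus) |>
    dplyr::summarise(
      replicon_id = as.character(dplyr::first(.data$seqnames)),
      strand = as.character(dplyr::first(.data$strand)),
      start = min(.data$start), end = max(.data$end),
      feature_kind = if (any(.data$type == "CDS")) "CDS"
                     else as.character(dplyr::first(.data$type)),
      product = {
        p <- as.character(.data$product)
        if (all(is.na(p))) NA_character_ else p[!is.na(p)][1]
      },
      .groups = "drop"
    ) |>
    dplyr::rename(locus_tag = ".locus")
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("GFF3 feature(s) with missing strand cannot enter the gene model")
  }
  rep_ids <- unique(genes$replicon_id)
  rep_tbl <- tibble(replicon_id = rep_ids)
  if (!is.null(seq_len_tbl)) {
    rep_tbl <- dplyr::left_join(rep_tbl, seq_len_tbl, by = "replicon_id")
  } else {
    lens <- vapply(rep_ids, function(rid) {
      max(genes$end[genes$replicon_id == rid])
    }, integer(1))
    rep_tbl$length <- unname(lens)
  }
  rep_tbl$topology <- "linear"
  annotation_bundle(genes, rep_tbl, seqs, gff_path)
}

#' Write an annotation bundle as GFF3 (and optional FASTA)
#'
#' @param bundle An [annotation_bundle()].
#' @param gff_path Output GFF3 path.
#' @param fasta_path Optional FASTA output path (requires sequences).
#' @return `gff_path`, invisibly.
#' @export
write_gff3 <- function(bundle, gff_path, fasta_path = NULL) {
  stopifnot(inherits(bundle, "annotation_bundle"))
  con <- file(gff_path, "w")
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(bundle$replicons))) {
    rep <- bundle$replicons[i, ]
    writeLines(sprintf("##sequence-region %s 1 %d", rep$replicon_id, rep$length), con)
  }
  g <- bundle$genes
  if (nrow(g) > 0) {
    attrs <- sprintf("ID=%s;locus_tag=%s%s", g$locus_tag, g$locus_tag,
                     ifelse(is.na(g$product) | g$product == "", "",
                            paste0(";product=", gsub("[;=]", " ", g$product))))
    writeLines(sprintf("%s\ttfrctx\t%s\t%d\t%d\t.\t%s\t0\t%s",
                       g$replicon_id, g$feature_kind, g$start, g$end,
                       g$strand, attrs), con)
  }
  close(con)
  if (!is.null(fasta_path)) {
    if (is.null(bundle$sequences)) abort("bundle carries no sequence to write")
    dss <- Biostrings::DNAStringSet(unlist(bundle$sequences))
    Biostrings::writeXStringSet(dss, fasta_path)
  }
  invisible(gff_path)
}

# ---------------------------------------------------------------------------
# Plain tables

#' Write the gene table as TSV
#'
#' Columns: replicon, locus_tag, strand, start, end, product.
#'
#' @param bundle An [annotation_bundle()] (or a gene tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(bundle, path) {
  genes <- if (inherits(bundle, "annotation_bundle")) bundle$genes else as_tibble(bundle)
  out <- dplyr::select(genes, replicon = "replicon_id", "locus_tag",
                       "strand", "start", "end", "product")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read a gene table TSV back into a gene tibble
#'
#' Inverse of [write_gene_table()]; feature_kind is assumed CDS.
#'
#' @param path TSV path.
#' @return Gene tibble in the internal model.
#' @export
read_gene_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    replicon = readr::col_character(),
                    locus_tag = readr::col_character(),
                    strand = readr::col_character(),
                    start = readr::col_integer(),
                    end = readr::col_integer(),
                    product = readr::col_character())) |>
    dplyr::rename(replicon_id = "replicon") |>
    dplyr::mutate(feature_kind = "CDS", .before = "product") |>
    dplyr::arrange(.data$replicon_id, .data$start, .data$end, .data$locus_tag)
}

#' Read a TFR locus list
#'
#' One locus tag per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to the list file.
#' @return Character vector of locus tags.
#' @export
read_tfr_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Read a domain-hit table
#'
#' TSV with header columns `locus_tag`, `domain_accession`, `domain_name`,
#' `score`, `evalue` (the last three optional).
#'
#' @param path TSV path.
#' @return Tibble of domain hits.
#' @export
read_domain_hits <- function(path) {
  hits <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("locus_tag", "domain_accession") %in% names(hits))) {
    abort("domain-hit table needs locus_tag and domain_accession columns")
  }
  for (col in c("domain_name")) if (is.null(hits[[col]])) hits[[col]] <- NA_character_
  for (col in c("score", "evalue")) if (is.null(hits[[col]])) hits[[col]] <- NA_real_
  as_tibble(hits)
}

#' Select TFR loci from a domain-hit table
#'
#' Returns the locus tags with at least one hit to the given domain
#' accession scoring at or above `min_score`. The canonical use filters
#' Pfam PF00440 (TetR_N DNA-binding domain) hits, the signature that defines
#' TFR family membership.
#'
#' @param hits Domain-hit tibble (see [read_domain_hits()]).
#' @param accession Domain accession to keep (default `"PF00440"`).
#' @param min_score Minimum bit score; hits with `NA` score pass only when
#'   `min_score` is `-Inf`.
#' @return Sorted character vector of unique locus tags.
#' @export
select_tfrs <- function(hits, accession = "PF00440", min_score = 25) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    warn("empty domain-hit table; no TFRs selected")
    return(character())
  }
  score <- if ("score" %in% names(hits)) hits$score else rep(NA_real_, nrow(hits))
  ok <- hits$domain_accession == accession &
    (if (is.infinite(min_score) && min_score < 0) TRUE
     else !is.na(score) & score >= min_score)
  sort(unique(hits$locus_tag[ok]))
}
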
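# synthetic_genomes: annotated replicons with planted TFR contexts.
#
# The generator lays gene blocks left-to-right on a single replicon (a
# chromosome + small plasmid pair behind a flag). Each TFR block encodes
# one planted context:
#   DIVERGENT  [neighbor '-'] <--sep--> [TFR '+'] ... [filler '+', gap > operon max]
#   OPERONIC   [upstream '+', gap <= operon max] [TFR '+'] [filler '-']
#   OTHER      [filler '+', large gap] [TFR '+'] [filler '-', large gap]
# Background sequence is i.i.d. with configurable GC (streptomycete-like
# 0.72 by default); start codons are rendered ATG. Planted operators are
# perfect inverted repeats written into divergent IGRs with a recorded
# offset; the bases immediately flanking a planted site are forced
# non-complementary so the planted arm length is exactly recoverable.

#' Specification for a synthetic fixture
#'
#' Defaults emulate the observed survey conditions in the three
#' streptomycete genomes: two thirds of TFRs divergent, about 15%
#' operonic, the rest in other contexts; divergent separations uniform on
#' 0..1123 bp (the observed range); operon gaps uniform on 0..35 bp; GC
#' content 0.72; linear topology.
#'
#' @param n_tfr Number of TFRs to plant. Default 20.
#' @param group_mix Named proportions over DIVERGENT/OPERONIC/OTHER summing
#'   to 1. Counts are assigned by largest remainder.
#' @param separation_sampler List `(dist = "uniform", min, max)` for
#'   divergent separations in bp.
#' @param operon_gap_sampler List `(dist = "uniform", min, max)` for
#'   operonic ORF gaps in bp.
#' @param plant_operators Plant a perfect inverted repeat in each divergent
#'   IGR large enough to hold it. Default `TRUE`.
#' @param operator_arm Planted arm length. Default 7.
#' @param operator_mismatches Mismatches written into the planted right
#'   arm. Default 0 (perfect palindrome).
#' @param gc_content Background GC fraction in (0,1). Default 0.72.
#' @param topology `"linear"` (default) or `"circular"`.
#' @param multi_replicon Also emit a small plasmid replicon carrying one
#'   extra divergent TFR. Default `FALSE`.
#' @param seed Integer seed making generation deterministic.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_tfr = 20,
                         group_mix = c(DIVERGENT = 0.672, OPERONIC = 0.148,
                                       OTHER = 0.180),
                         separation_sampler = list(dist = "uniform", min = 0,
                                                   max = 1123),
                         operon_gap_sampler = list(dist = "uniform", min = 0,
                                                   max = 35),
                         plant_operators = TRUE,
                         operator_arm = 7,
                         operator_mismatches = 0,
                         gc_content = 0.72,
                         topology = c("linear", "circular"),
                         multi_replicon = FALSE,
                         seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_tfr >= 1, gc_content > 0, gc_content < 1,
            abs(sum(group_mix) - 1) < 1e-8, operator_arm >= 2,
            operator_mismatches >= 0)
  structure(list(n_tfr = as.integer(n_tfr), group_mix = group_mix,
                 separation_sampler = separation_sampler,
                 operon_gap_sampler = operon_gap_sampler,
                 plant_operators = plant_operators,
                 operator_arm = as.integer(operator_arm),
                 operator_mismatches = as.integer(operator_mismatches),
                 gc_content = gc_content, topology = topology,
                 multi_replicon = multi_replicon, seed = as.integer(seed)),
            class = "fixture_spec")
}

sample_from <- function(sampler, n) {
  if (identical(sampler$dist, "uniform")) {
    vals <- seq(sampler$min, sampler$max)
    as.integer(vals[sample.int(length(vals), n, replace = TRUE)])
  } else {
    abort(sprintf("unknown sampler distribution: %s", sampler$dist))
  }
}

# largest-remainder apportionment of n_tfr into group counts
apportion_groups <- function(n, mix) {
  raw <- n * mix / sum(mix)
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    order_by_frac <- order(raw - counts, decreasing = TRUE)
    counts[order_by_frac[seq_len(rem)]] <- counts[order_by_frac[seq_len(rem)]] + 1
  }
  setNames(as.integer(counts), names(mix))
}

#' Generate a synthetic annotated replicon with planted ground truth
#'
#' Deterministic for a fixed seed. Returns the annotation bundle (with
#' sequence) together with the planted truth table that the classification
#' and scanning pipeline should recover exactly.
#'
#' @param spec A [fixture_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List of class `tfr_fixture`: `bundle` ([annotation_bundle()]),
#'   `truth` (per-TFR tibble: `locus_tag`, `true_group`, `true_neighbor`,
#'   `true_separation`, `true_category`, `op_offset`, `op_arm`, `op_loop`),
#'   `hits` (planted domain-hit tibble for target typing), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  seed <- seed %||% spec$seed
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  counts <- apportion_groups(spec$n_tfr, spec$group_mix)
  groups <- sample(rep(names(counts), counts))  # shuffle block order
  main <- build_replicon("synrep1", groups, spec)
  bundles <- list(main)
  if (isTRUE(spec$multi_replicon)) {
    bundles[[2]] <- build_replicon("synplasmid1", "DIVERGENT", spec,
                                   tfr_offset = length(groups))
  }
  genes <- dplyr::bind_rows(purrr::map(bundles, "genes"))
  reps <- dplyr::bind_rows(purrr::map(bundles, "replicon"))
  seqs <- unlist(purrr::map(bundles, "sequence"))
  truth <- dplyr::bind_rows(purrr::map(bundles, "truth"))
  hits <- dplyr::bind_rows(purrr::map(bundles, "hits"))
  bundle <- annotation_bundle(genes, reps, seqs)
  structure(list(bundle = bundle, truth = truth, hits = hits, spec = spec),
            class = "tfr_fixture")
}

# planted product palette: category label -> product text + optional domain hit
PLANT_PALETTE <- list(
  list(category = "ENZYME_EC1", product = "putative oxidoreductase",
       accession = "cl09931", name = "NADB_Rossmann"),
  list(category = "ENZYME_EC2", product = "acyltransferase (EC 2)",
       accession = NA, name = NA),
  list(category = "ENZYME_EC3", product = "secreted glycosyl hydrolase",
       accession = NA, name = NA),
  list(category = "MFS", product = "MFS transporter",
       accession = NA, name = NA),
  list(category = "ABC", product = "ABC transporter ATP-binding protein",
       accession = NA, name = NA),
  list(category = "UNKNOWN", product = "hypothetical protein",
       accession = NA, name = NA)
)

build_replicon <- function(replicon_id, groups, spec, tfr_offset = 0L) {
  n <- length(groups)
  seps <- sample_from(spec$separation_sampler, n)
  op_gaps <- sample_from(spec$operon_gap_sampler, n)
  gene_len <- function() as.integer(sample(seq(300, 900, by = 3), 1))
  big_gap <- function() as.integer(sample(150:400, 1))

  rows <- list()
  truth <- list()
  hits <- list()
  pos <- big_gap()  # left margin
  gid <- 0L
  add_gene <- function(lt, strand, len, kind, product) {
    start <- pos + 1L
    end <- pos + len
    rows[[length(rows) + 1L]] <<- tibble(
      replicon_id = replicon_id, locus_tag = lt, strand = strand,
      start = start, end = as.integer(end), feature_kind = kind,
      product = product)
    pos <<- end
    c(start = start, end = as.integer(end))
  }
  operators <- list()  # deferred sequence edits

  for (i in seq_along(groups)) {
    g <- groups[i]
    ti <- i + tfr_offset
    tfr_lt <- sprintf("SYN_TFR%03d", ti)
    if (g == "DIVERGENT") {
      pal <- PLANT_PALETTE[[sample(length(PLANT_PALETTE), 1)]]
      nb_lt <- sprintf("SYN_TGT%03d", ti)
      nb <- add_gene(nb_lt, "-", gene_len(), "CDS", pal$product)
      sep <- seps[i]
      pos <- nb[["end"]] + sep  # TFR start codon at ts(nb) + sep + 1
      tfr <- add_gene(tfr_lt, "+", gene_len(), "CDS",
                      "TetR family transcriptional regulator")
      op <- c(NA_integer_, NA_integer_, NA_integer_)
      if (isTRUE(spec$plant_operators)) {
        loop <- as.integer(sample(0:4, 1))
        site_len <- 2L * spec$operator_arm + loop
        if (site_len + 2L <= sep) {
          offs <- 0:(sep - site_len - 2L)
          off <- as.integer(offs[sample.int(length(offs), 1)]) + 1L
          # off is 0-based within IGR after reserving one left blocking base;
          # IGR runs (nb$end + 1) .. (tfr$start - 1) on the forward strand
          operators[[length(operators) + 1L]] <- list(
            igr_start = nb[["end"]] + 1L, offset = off,
            arm = spec$operator_arm, loop = loop,
            mismatches = spec$operator_mismatches)
          op <- c(off, spec$operator_arm, loop)
        }
      }
      truth[[length(truth) + 1L]] <- tibble(
        locus_tag = tfr_lt, true_group = "DIVERGENT", true_neighbor = nb_lt,
        true_separation = sep, true_category = pal$category,
        op_offset = op[1], op_arm = op[2], op_loop = op[3])
      if (!is.na(pal$accession)) {
        hits[[length(hits) + 1L]] <- tibble(
          locus_tag = nb_lt, domain_accession = pal$accession,
          domain_name = pal$name, score = 100, evalue = 1e-20)
      }
      pos <- pos + big_gap()
      add_gene(sprintf("SYN_FIL%03da", ti), "+", gene_len(), "CDS",
               "hypothetical protein")
    } else if (g == "OPERONIC") {
      up <- add_gene(sprintf("SYN_UP%03d", ti), "+", gene_len(), "CDS",
                     "hypothetical protein")
      pos <- up[["end"]] + op_gaps[i]  # gap bases strictly between ORFs
      tfr <- add_gene(tfr_lt, "+", gene_len(), "CDS",
                      "TetR family transcriptional regulator")
      pos <- pos + big_gap()
      add_gene(sprintf("SYN_FIL%03db", ti), "-", gene_len(), "CDS",
               "hypothetical protein")
      truth[[length(truth) + 1L]] <- tibble(
        locus_tag = tfr_lt, true_group = "OPERONIC",
        true_neighbor = NA_character_, true_separation = NA_integer_,
        true_category = NA_character_, op_offset = NA_integer_,
        op_arm = NA_integer_, op_loop = NA_integer_)
    } else {
      add_gene(sprintf("SYN_FIL%03dc", ti), "+", gene_len(), "CDS",
               "hypothetical protein")
      pos <- pos + big_gap()
      tfr <- add_gene(tfr_lt, "+", gene_len(), "CDS",
                      "TetR family transcriptional regulator")
      pos <- pos + big_gap()
      add_gene(sprintf("SYN_FIL%03dd", ti), "-", gene_len(), "CDS",
               "hypothetical protein")
      truth[[length(truth) + 1L]] <- tibble(
        locus_tag = tfr_lt, true_group = "OTHER",
        true_neighbor = NA_character_, true_separation = NA_integer_,
        true_category = NA_character_, op_offset = NA_integer_,
        op_arm = NA_integer_, op_loop = NA_integer_)
    }
    pos <- pos + big_gap()
  }
  total_len <- pos + big_gap()
  genes <- dplyr::bind_rows(rows)
  if (max(genes$end) > total_len) {
    abort("fixture packing error: genes exceed replicon length")
  }

  seq <- random_dna(total_len, spec$gc_content)
  # render start codons: ATG at the translational start of every gene
  for (j in seq_len(nrow(genes))) {
    gj <- genes[j, ]
    if (gj$strand == "+") {
      seq <- splice_seq(seq, gj$start, "ATG")
    } else {
      seq <- splice_seq(seq, gj$end - 2L, "CAT")
    }
  }
  # write planted operators with non-complementary blocking flanks
  for (opr in operators) {
    arm_l <- random_dna(opr$arm, 0.5)
    arm_r <- revcomp(arm_l)
    if (opr$mismatches > 0) {
      idx <- sample(opr$arm, min(opr$mismatches, opr$arm))
      chars <- strsplit(arm_r, "", fixed = TRUE)[[1]]
      for (k in idx) {
        chars[k] <- sample(setdiff(c("A", "C", "G", "T"), chars[k]), 1)
      }
      arm_r <- paste(chars, collapse = "")
    }
    loop_seq <- if (opr$loop > 0) random_dna(opr$loop, 0.5) else ""
    if (opr$loop >= 2) {
      # forbid complementary symmetric loop positions: otherwise the site
      # re-reads as a longer-armed palindrome with a shorter loop and the
      # planted geometry stops being the unique maximal rendering
      lc <- strsplit(loop_seq, "", fixed = TRUE)[[1]]
      for (k in seq_len(floor(opr$loop / 2))) {
        if (COMPLEMENT[[lc[k]]] == lc[opr$loop + 1 - k]) {
          lc[k] <- lc[opr$loop + 1 - k]
        }
      }
      loop_seq <- paste(lc, collapse = "")
    }
    site <- paste0(arm_l, loop_seq, arm_r)
    at <- opr$igr_start + opr$offset  # 1-based genome position of site start
    seq <- splice_seq(seq, at, site)
    # blocking flanks: same base on both sides of the site never pairs
    block <- substr(arm_l, 1, 1)
    seq <- splice_seq(seq, at - 1L, block)
    seq <- splice_seq(seq, at + nchar(site), block)
  }

  list(genes = genes,
       replicon = tibble(replicon_id = replicon_id,
                         length = as.integer(total_len),
                         topology = spec$topology),
       sequence = setNames(seq, replicon_id),
       truth = dplyr::bind_rows(truth),
       hits = if (length(hits)) dplyr::bind_rows(hits) else
         tibble(locus_tag = character(), domain_accession = character(),
                domain_name = character(), score = double(), evalue = double()))
}

#' Write a fixture to disk in standard formats
#'
#' Emits GenBank, GFF3, FASTA, a truth TSV and a truth JSON.
#'
#' @param fixture A `tfr_fixture` from [generate_fixture()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "tfr_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genbank = file.path(dir, "fixture.gbk"),
    gff3 = file.path(dir, "fixture.gff3"),
    fasta = file.path(dir, "fixture.fasta"),
    truth_tsv = file.path(dir, "truth.tsv"),
    truth_json = file.path(dir, "truth.json")
  )
  write_genbank(fixture$bundle, paths[["genbank"]])
  write_gff3(fixture$bundle, paths[["gff3"]], paths[["fasta"]])
  readr::write_tsv(fixture$truth, paths[["truth_tsv"]])
  jsonlite::write_json(fixture$truth, paths[["truth_json"]], dataframe = "rows",
                       na = "null")
  invisible(paths)
}

#' Compare pipeline output against planted truth
#'
#' Measures how faithfully the classification chain recovers what the
#' generator planted: per-group confusion counts, exact separation match
#' rate over divergent TFRs, and the fraction of planted operators
#' recovered. An operator counts as exactly recovered when a reported site
#' in its TFR's IGR has the planted offset and arm; it counts as covered
#' when a reported site with at least the planted arm spans the planted
#' site.
#'
#' @param truth Truth tibble from [generate_fixture()].
#' @param calls Context-call tibble from [classify_context()].
#' @param sites Optional site tibble from [scan_igrs()].
#' @return List of class `recovery_report`: `confusion` (true_group x
#'   group counts), `group_recovery`, `separation_match`,
#'   `operator_exact`, `operator_covered` (rates in `[0,1]`, `NA` when not
#'   applicable).
#' @export
evaluate_recovery <- function(truth, calls, sites = NULL) {
  truth <- as_tibble(truth)
  calls <- as_tibble(calls)
  if (!setequal(truth$locus_tag, calls$tfr_locus)) {
    abort("truth and calls cover different locus sets")
  }
  joined <- dplyr::inner_join(truth, calls,
                              by = c(locus_tag = "tfr_locus"))
  confusion <- dplyr::count(joined, .data$true_group, .data$group, name = "n")
  group_recovery <- mean(joined$true_group == joined$group)
  div <- dplyr::filter(joined, .data$true_group == "DIVERGENT")
  separation_match <- if (nrow(div) > 0) {
    mean(div$true_separation == div$separation_clamped)
  } else {
    NA_real_
  }
  operator_exact <- NA_real_
  operator_covered <- NA_real_
  planted <- dplyr::filter(truth, !is.na(.data$op_offset))
  if (!is.null(sites) && nrow(planted) > 0) {
    sites <- as_tibble(sites)
    hit <- purrr::map_lgl(seq_len(nrow(planted)), function(i) {
      s <- dplyr::filter(sites, .data$tfr_locus == planted$locus_tag[i])
      any(s$offset == planted$op_offset[i] & s$arm_len == planted$op_arm[i])
    })
    cover <- purrr::map_lgl(seq_len(nrow(planted)), function(i) {
      s <- dplyr::filter(sites, .data$tfr_locus == planted$locus_tag[i])
      p_start <- planted$op_offset[i]
      p_end <- p_start + 2 * planted$op_arm[i] + planted$op_loop[i]
      any(s$arm_len >= planted$op_arm[i] & s$offset <= p_start &
          (s$offset + 2 * s$arm_len + s$loop_len) >= p_end)
    })
    operator_exact <- mean(hit)
    operator_covered <- mean(cover)
  }
  structure(list(confusion = confusion, group_recovery = group_recovery,
                 separation_match = separation_match,
                 operator_exact = operator_exact,
                 operator_covered = operator_covered),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> groups %.1f%%, separations %s, operators %s\n",
              100 * x$group_recovery,
              if (is.na(x$separation_match)) "n/a"
              else sprintf("%.1f%%", 100 * x$separation_match),
              if (is.na(x$operator_exact)) "n/a"
              else sprintf("%.1f%% exact", 100 * x$operator_exact)))
  print(x$confusion)
  invisible(x)
}
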
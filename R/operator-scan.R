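# operator_scan: palindromic operator discovery in intergenic DNA.
#
# TFRs bind DNA as homodimers, so their operators are characteristically
# inverted repeats: a left arm whose reverse complement reappears as the
# right arm, with an optional unconstrained loop between them. The scanner
# enumerates candidate centers and grows arms outward under a mismatch
# budget; known operators can also be matched directly as degenerate IUPAC
# consensus patterns.

#' Find inverted repeats (candidate operators) in a DNA sequence
#'
#' For every candidate center (each position between bases, widened by a
#' loop of 0..`max_loop` bases) the arms are extended outward while the
#' number of non-complementary arm pairs stays within `max_mismatch`; `N`
#' never counts as matching. Only the longest arm at each center is kept,
#' and a site is suppressed when another reported site with a strictly
#' longer arm and no more mismatches spans it. Results are sorted by offset,
#' then by decreasing arm length.
#'
#' @param seq DNA character scalar over `A,C,G,T,N` (case-insensitive).
#' @param min_arm Minimum arm length (>= 2). Default 5.
#' @param max_loop Maximum loop (spacer) length. Default 6.
#' @param max_mismatch Maximum non-complementary arm pairs. Default 2.
#' @return Tibble with one row per site: `offset` (0-based start of the
#'   site within `seq`), `arm_len`, `loop_len`, `mismatches`, `site_seq`.
#' @examples
#' find_inverted_repeats("TGGAACGTCGTTCCA", min_arm = 5, max_loop = 3,
#'                       max_mismatch = 0)
#' @export
find_inverted_repeats <- function(seq, min_arm = 5, max_loop = 6,
                                  max_mismatch = 2) {
  stopifnot(min_arm >= 2, max_loop >= 0, max_mismatch >= 0)
  x <- check_dna(seq)
  n <- nchar(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  comp <- unname(COMPLEMENT[ch])
  comp[ch == "N"] <- ""   # N complements nothing: never a match
  sites <- list()
  # center: left arm ends at i (1-based), loop occupies i+1 .. i+L
  for (i in seq_len(max(n - 1, 0))) {
    for (L in 0:max_loop) {
      if (i + L + 1 > n) break
      mm <- 0L
      arm <- 0L
      arm_mm <- 0L
      k <- 1L
      while (i - k + 1 >= 1 && i + L + k <= n) {
        if (comp[i - k + 1] != ch[i + L + k] || ch[i - k + 1] == "N") {
          mm <- mm + 1L
          if (mm > max_mismatch) break
        }
        arm <- k
        arm_mm <- mm
        k <- k + 1L
      }
      if (arm >= min_arm) {
        off0 <- i - arm              # 0-based start of the site
        sites[[length(sites) + 1L]] <- c(off0, arm, L, arm_mm)
      }
    }
  }
  if (length(sites) == 0) {
    return(tibble(offset = integer(), arm_len = integer(), loop_len = integer(),
                  mismatches = integer(), site_seq = character()))
  }
  m <- do.call(rbind, sites)
  res <- tibble(offset = as.integer(m[, 1]), arm_len = as.integer(m[, 2]),
                loop_len = as.integer(m[, 3]), mismatches = as.integer(m[, 4]))
  res$span_end <- res$offset + 2L * res$arm_len + res$loop_len  # 0-based excl.
  # containment suppression: spanned by a longer-armed site with <= mismatches
  keep <- vapply(seq_len(nrow(res)), function(j) {
    !any(res$arm_len > res$arm_len[j] &
         res$mismatches <= res$mismatches[j] &
         res$offset <= res$offset[j] &
         res$span_end >= res$span_end[j])
  }, logical(1))
  res <- res[keep, ]
  res$site_seq <- substr(rep(x, nrow(res)), res$offset + 1L, res$span_end)
  res$span_end <- NULL
  dplyr::arrange(res, .data$offset, dplyr::desc(.data$arm_len), .data$loop_len)
}

#' Match a degenerate IUPAC consensus against a sequence
#'
#' Reports every offset where each pattern symbol's IUPAC base set contains
#' the corresponding sequence base. Matching is case-insensitive; `U` is
#' rejected. An `N` in the subject sequence matches nothing.
#'
#' @param seq DNA character scalar.
#' @param pattern IUPAC pattern (e.g. `"TGGAACGNCGTTCCA"`).
#' @param both_strands Also scan the reverse complement and report matches
#'   with `strand = "-"` at forward-strand offsets. Default `FALSE`.
#' @return Tibble: `offset` (0-based), `strand`, `matched_text`.
#' @export
match_consensus <- function(seq, pattern, both_strands = FALSE) {
  x <- check_dna(seq)
  p <- toupper(pattern)
  psym <- strsplit(p, "", fixed = TRUE)[[1]]
  if (!all(psym %in% names(IUPAC_SETS))) {
    bad <- setdiff(unique(psym), names(IUPAC_SETS))
    abort(sprintf("invalid IUPAC symbol(s) in pattern: %s",
                  paste(bad, collapse = ", ")))
  }
  scan_one <- function(subject, strand) {
    n <- nchar(subject)
    L <- length(psym)
    if (L == 0 || n < L) {
      return(tibble(offset = integer(), strand = character(),
                    matched_text = character()))
    }
    ch <- strsplit(subject, "", fixed = TRUE)[[1]]
    hit <- rep(TRUE, n - L + 1L)
    for (k in seq_len(L)) {
      hit <- hit & ch[seq_len(n - L + 1L) + k - 1L] %in% IUPAC_SETS[[psym[k]]]
    }
    offs <- which(hit) - 1L
    if (length(offs) == 0) {
      return(tibble(offset = integer(), strand = character(),
                    matched_text = character()))
    }
    tibble(offset = offs, strand = strand,
           matched_text = substring(subject, offs + 1L, offs + L))
  }
  fwd <- scan_one(x, "+")
  if (!both_strands) return(fwd)
  rev <- scan_one(revcomp(x), "-")
  if (nrow(rev) > 0) {
    # report at forward-strand coordinates of the matched window
    rev$offset <- nchar(x) - rev$offset - length(psym)
  }
  dplyr::arrange(dplyr::bind_rows(fwd, rev), .data$offset, .data$strand)
}

#' Build a degenerate consensus from aligned equal-length sequences
#'
#' In the default mode a column emits its base when all sequences agree and
#' `N` otherwise. In strict-IUPAC mode a column emits the minimal IUPAC
#' code covering the observed bases.
#'
#' @param seqs Character vector of >= 2 equal-length DNA sequences.
#' @param mode `"n"` (default) or `"iupac"`.
#' @return Consensus pattern string.
#' @examples
#' build_consensus(c("TGGAACGTCGTTCCA", "TGGAACGACGTTCCA", "TGGAACGCCGTTCCA"))
#' @export
build_consensus <- function(seqs, mode = c("n", "iupac")) {
  mode <- match.arg(mode)
  stopifnot(length(seqs) >= 2)
  seqs <- vapply(seqs, check_dna, character(1), USE.NAMES = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    abort("consensus requires equal-length sequences")
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cols <- apply(mat, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1) return(u)
    if (mode == "n") "N" else iupac_code_for(u)
  })
  paste(cols, collapse = "")
}

#' Classify where a site sits within an intergenic region
#'
#' The site midpoint is expressed as a fraction of the IGR length measured
#' from the TFR's translational start toward the target's, then bucketed
#' into TFR_PROXIMAL / CENTRAL / TARGET_PROXIMAL zones.
#'
#' @param offset 0-based site start within the IGR (integer vector).
#' @param arm_len,loop_len Site geometry (vectors recycled as usual).
#' @param igr_length IGR length in bp (> 0).
#' @param toward_target `TRUE` (default) when the scanned sequence runs
#'   from the TFR side toward the target; `FALSE` flips the fraction.
#' @param cut_low,cut_high Zone cut points in (0,1), defaults 1/3 and 2/3.
#' @return Tibble: `fraction`, `zone`.
#' @export
classify_placement <- function(offset, arm_len, loop_len, igr_length,
                               toward_target = TRUE,
                               cut_low = 1 / 3, cut_high = 2 / 3) {
  if (any(igr_length <= 0)) abort("igr_length must be positive")
  stopifnot(cut_low > 0, cut_low < cut_high, cut_high < 1)
  mid <- offset + (2 * arm_len + loop_len) / 2
  fraction <- mid / igr_length
  if (!isTRUE(toward_target)) fraction <- 1 - fraction
  zone <- dplyr::case_when(
    fraction <= cut_low ~ "TFR_PROXIMAL",
    fraction > cut_high ~ "TARGET_PROXIMAL",
    TRUE ~ "CENTRAL"
  )
  tibble(fraction = fraction, zone = zone)
}

#' Scan extracted intergenic regions for operator candidates
#'
#' Runs [find_inverted_repeats()] on each IGR and annotates each site with
#' its placement zone relative to the TFR gene.
#'
#' @param igrs IGR tibble from [extract_igr()] (columns `tfr_locus`,
#'   `target_locus`, `seq`, `length`, `tfr_first`).
#' @param min_arm,max_loop,max_mismatch Scan parameters
#'   (see [find_inverted_repeats()]).
#' @param cut_low,cut_high Placement cut points (see [classify_placement()]).
#' @return Tibble of sites with `tfr_locus`, `target_locus`, site columns,
#'   `fraction`, `zone`.
#' @export
scan_igrs <- function(igrs, min_arm = 5, max_loop = 6, max_mismatch = 2,
                      cut_low = 1 / 3, cut_high = 2 / 3) {
  igrs <- dplyr::filter(as_tibble(igrs), .data$length > 0)
  purrr::map_dfr(seq_len(nrow(igrs)), function(i) {
    row <- igrs[i, ]
    sites <- find_inverted_repeats(row$seq, min_arm, max_loop, max_mismatch)
    if (nrow(sites) == 0) return(NULL)
    pl <- classify_placement(sites$offset, sites$arm_len, sites$loop_len,
                             igr_length = row$length,
                             toward_target = isTRUE(row$tfr_first),
                             cut_low = cut_low, cut_high = cut_high)
    dplyr::bind_cols(
      tibble(tfr_locus = row$tfr_locus, target_locus = row$target_locus),
      sites, pl
    )
  })
}

#' Write operator sites as TSV
#'
#' @param sites Site tibble from [scan_igrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  readr::write_tsv(as_tibble(sites), path)
  invisible(path)
}

#' Write operator sites as BED intervals on the genome
#'
#' Needs genome-anchored IGRs: joins sites back to the IGR table to convert
#' IGR-relative offsets to replicon coordinates (0-based half-open).
#'
#' @param sites Site tibble from [scan_igrs()].
#' @param igrs The IGR tibble the sites came from.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, igrs, path) {
  joined <- dplyr::inner_join(
    as_tibble(sites),
    dplyr::select(as_tibble(igrs), "tfr_locus", "replicon_id", "bed_start"),
    by = "tfr_locus"
  )
  span <- 2L * joined$arm_len + joined$loop_len
  bed <- tibble(chrom = joined$replicon_id,
                start = joined$bed_start + joined$offset,
                end = joined$bed_start + joined$offset + span,
                name = sprintf("%s_site%d", joined$tfr_locus,
                               seq_len(nrow(joined))))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
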
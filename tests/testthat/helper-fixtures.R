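# Shared helpers: hand-built gene bundles, an independent brute-force
# inverted-repeat oracle, an independent brute-force context classifier,
# and a strand-mirroring transform. The oracles are deliberately written
# against the definitions, not against the package implementation.

make_bundle <- function(genes, length = NULL, topology = "linear",
                        sequence = NULL, replicon_id = "chr") {
  genes <- tibble::as_tibble(genes)
  if (!"replicon_id" %in% names(genes)) genes$replicon_id <- replicon_id
  if (!"feature_kind" %in% names(genes)) genes$feature_kind <- "CDS"
  if (!"product" %in% names(genes)) genes$product <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (is.null(length)) length <- max(genes$end) + 100L
  reps <- tibble::tibble(replicon_id = unique(genes$replicon_id),
                         length = as.integer(length), topology = topology)
  seqs <- if (!is.null(sequence)) stats::setNames(sequence, replicon_id) else NULL
  annotation_bundle(genes, reps, seqs)
}

# independent reverse complement (vector of single characters)
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Brute-force inverted-repeat finder: enumerate every (start, arm, loop)
# triple, count mismatches directly by comparing the left arm with the
# reverse complement of the right arm, then apply per-center maximality and
# containment suppression.
oracle_sites <- function(seq, min_arm = 5, max_loop = 6, max_mismatch = 2) {
  seq <- toupper(seq)
  n <- nchar(seq)
  cand <- list()
  for (s in 0:(n - 1)) {                       # 0-based site start
    for (arm in min_arm:floor((n - s) / 2)) {
      if (arm < min_arm) next
      for (loop in 0:max_loop) {
        e <- s + 2 * arm + loop                # 0-based exclusive end
        if (e > n) break
        left <- substr(seq, s + 1, s + arm)
        right <- substr(seq, s + arm + loop + 1, e)
        rc <- oracle_revcomp(right)
        lv <- strsplit(left, "")[[1]]
        rv <- strsplit(rc, "")[[1]]
        mm <- sum(lv != rv | lv == "N" | rv == "N")
        if (mm <= max_mismatch) {
          cand[[length(cand) + 1]] <-
            data.frame(offset = s, arm_len = arm, loop_len = loop,
                       mismatches = mm)
        }
      }
    }
  }
  if (length(cand) == 0) {
    return(data.frame(offset = integer(), arm_len = integer(),
                      loop_len = integer(), mismatches = integer()))
  }
  d <- do.call(rbind, cand)
  # per-center maximality: same (left-arm end, loop) keeps the longest arm
  d$center <- paste(d$offset + d$arm_len, d$loop_len)
  d <- do.call(rbind, lapply(split(d, d$center), function(g) {
    g[which.max(g$arm_len), ]
  }))
  d$span_end <- d$offset + 2 * d$arm_len + d$loop_len
  keep <- vapply(seq_len(nrow(d)), function(j) {
    !any(d$arm_len > d$arm_len[j] & d$mismatches <= d$mismatches[j] &
         d$offset <= d$offset[j] & d$span_end >= d$span_end[j])
  }, logical(1))
  d <- d[keep, c("offset", "arm_len", "loop_len", "mismatches")]
  d <- d[order(d$offset, -d$arm_len, d$loop_len), ]
  rownames(d) <- NULL
  d
}

# Brute-force three-group classifier over a sorted linear gene table.
oracle_classify <- function(genes, tfrs, operon_gap_max = 35) {
  genes <- genes[order(genes$start, genes$end, genes$locus_tag), ]
  out <- lapply(tfrs, function(lt) {
    i <- which(genes$locus_tag == lt)
    me <- genes[i, ]
    left <- if (i > 1) genes[i - 1, ] else NULL
    right <- if (i < nrow(genes)) genes[i + 1, ] else NULL
    div <- (me$strand == "+" && !is.null(left) && left$strand == "-") ||
           (me$strand == "-" && !is.null(right) && right$strand == "+")
    oper <- (!is.null(left) && left$strand == me$strand &&
             (me$start - left$end - 1) <= operon_gap_max) ||
            (!is.null(right) && right$strand == me$strand &&
             (right$start - me$end - 1) <= operon_gap_max)
    sep <- NA_integer_
    if (div && me$strand == "+") sep <- me$start - left$end - 1L
    if (div && me$strand == "-") sep <- right$start - me$end - 1L
    group <- if (div) "DIVERGENT" else if (oper) "OPERONIC" else "OTHER"
    data.frame(tfr_locus = lt, group = group,
               separation_raw = as.integer(sep))
  })
  do.call(rbind, out)
}

# random non-overlapping linear gene arrangement for oracle comparison
random_gene_table <- function(n_genes = 20) {
  starts <- integer(n_genes); ends <- integer(n_genes)
  pos <- 0L
  for (i in seq_len(n_genes)) {
    gap <- sample(c(0:60, 150:300), 1)           # mix of tight and loose gaps
    len <- sample(90:600, 1)
    starts[i] <- pos + gap + 1L
    ends[i] <- starts[i] + len - 1L
    pos <- ends[i]
  }
  tibble::tibble(
    replicon_id = "chr",
    locus_tag = sprintf("g%02d", seq_len(n_genes)),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    start = starts, end = ends, feature_kind = "CDS",
    product = NA_character_
  )
}

# mirror a bundle: reverse complement coordinates and strands
mirror_bundle <- function(bundle) {
  L <- bundle$replicons$length
  stopifnot(nrow(bundle$replicons) == 1)
  g <- bundle$genes
  new <- tibble::tibble(
    replicon_id = g$replicon_id, locus_tag = g$locus_tag,
    strand = ifelse(g$strand == "+", "-", "+"),
    start = as.integer(L - g$end + 1L), end = as.integer(L - g$start + 1L),
    feature_kind = g$feature_kind, product = g$product
  )
  seqs <- if (!is.null(bundle$sequences)) {
    stats::setNames(oracle_revcomp(bundle$sequences[[1]]),
                    names(bundle$sequences)[1])
  } else NULL
  annotation_bundle(new, bundle$replicons, seqs)
}

# plain random DNA for oracle comparisons (balanced base usage)
random_test_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
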
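test_that("translational starts follow strand and mirror under reversal", {
  expect_equal(translational_start("+", 100, 400), 100)
  expect_equal(translational_start("-", 100, 400), 400)
  # mirroring a gene on a replicon of length L maps its start codon to L - ts + 1
  L <- 1000
  expect_equal(translational_start("-", L - 400 + 1, L - 100 + 1),
               L - translational_start("+", 100, 400) + 1)
})

test_that("arrangement distinguishes divergent, convergent and tandem pairs", {
  expect_equal(arrangement("-", "+"), "divergent")
  expect_equal(arrangement("+", "-"), "convergent")
  expect_equal(arrangement("+", "+"), "tandem")
  expect_equal(arrangement("-", "-"), "tandem")
})

test_that("neighbors honor coordinate order, linear ends and circular wrap", {
  g <- tibble::tibble(locus_tag = c("A", "B", "C"), strand = "+",
                      start = c(10L, 200L, 400L), end = c(100L, 300L, 500L))
  lin <- make_bundle(g)
  nb <- gene_neighbors(lin, "B")
  expect_equal(nb$left$locus_tag, "A")
  expect_equal(nb$right$locus_tag, "C")
  first <- gene_neighbors(lin, "A")
  expect_null(first$left)
  expect_equal(first$right$locus_tag, "B")

  circ <- make_bundle(g, topology = "circular")
  wrapped <- gene_neighbors(circ, "A")
  expect_equal(wrapped$left$locus_tag, "C")
  expect_error(gene_neighbors(lin, "nope"), "locus tag")
})

test_that("divergent separation counts bases strictly between start codons", {
  left <- tibble::tibble(locus_tag = "L", strand = "-", start = 200L, end = 500L)
  right <- tibble::tibble(locus_tag = "R", strand = "+", start = 611L, end = 900L)
  sep <- intergenic_separation(left, right)
  # positions 501..610 enumerate to 110 intervening bases
  expect_equal(sep$raw_bp, length(501:610))
  expect_equal(sep$clamped_bp, 110L)

  abut <- intergenic_separation(
    dplyr::mutate(left, end = 500L),
    dplyr::mutate(right, start = 501L))
  expect_equal(abut$raw_bp, 0L)

  overlap <- intergenic_separation(
    left, dplyr::mutate(right, start = 495L, end = 800L))
  expect_equal(overlap$raw_bp, -6L)
  expect_equal(overlap$clamped_bp, 0L)

  expect_error(
    intergenic_separation(dplyr::mutate(left, strand = "+"), right),
    "divergent")
})

test_that("boundary gaps are signed ORF-to-ORF distances for same-strand pairs", {
  a <- tibble::tibble(locus_tag = "a", strand = "+", start = 1L, end = 100L)
  b <- tibble::tibble(locus_tag = "b", strand = "+", start = 121L, end = 300L)
  expect_equal(boundary_gap(a, b), 20L)
  expect_equal(boundary_gap(a, dplyr::mutate(b, start = 101L)), 0L)
  expect_equal(boundary_gap(a, dplyr::mutate(b, start = 97L)), -4L)
  expect_error(boundary_gap(a, dplyr::mutate(b, strand = "-")), "same-strand")
})

test_that("context groups follow the divergent > operonic > other precedence", {
  # TFR '+' with '-' left neighbor: divergent regardless of distance
  g1 <- tibble::tibble(locus_tag = c("n", "tfr"), strand = c("-", "+"),
                       start = c(10L, 2000L), end = c(900L, 2600L))
  c1 <- classify_context(make_bundle(g1), "tfr")
  expect_equal(c1$group, "DIVERGENT")
  expect_equal(c1$divergent_neighbor, "n")
  expect_false(c1$mixed_flag)

  # same-strand upstream within 35 bp, convergent on the right: operonic
  g2 <- tibble::tibble(locus_tag = c("up", "tfr", "conv"),
                       strand = c("+", "+", "-"),
                       start = c(10L, 121L, 1000L), end = c(100L, 700L, 1400L))
  c2 <- classify_context(make_bundle(g2), "tfr")
  expect_equal(c2$group, "OPERONIC")
  expect_equal(c2$operonic_neighbors, "up")

  # divergent left + co-transcribed right: divergent with mixed flag
  g3 <- tibble::tibble(locus_tag = c("n", "tfr", "down"),
                       strand = c("-", "+", "+"),
                       start = c(10L, 500L, 1211L), end = c(400L, 1200L, 1700L))
  c3 <- classify_context(make_bundle(g3), "tfr")
  expect_equal(c3$group, "DIVERGENT")
  expect_true(c3$mixed_flag)

  # neither relation: other
  g4 <- tibble::tibble(locus_tag = c("far", "tfr"), strand = c("+", "+"),
                       start = c(10L, 500L), end = c(100L, 900L))
  c4 <- classify_context(make_bundle(g4), "tfr")
  expect_equal(c4$group, "OTHER")

  expect_error(classify_context(make_bundle(g4), c("tfr", "ghost")), "ghost")
})

test_that("overlapping same-strand neighbors count as co-transcribed", {
  g <- tibble::tibble(locus_tag = c("up", "tfr"), strand = c("+", "+"),
                      start = c(10L, 396L), end = c(400L, 900L))
  cc <- classify_context(make_bundle(g), "tfr")
  expect_equal(cc$group, "OPERONIC")   # gap of -5 is <= 35
})

test_that("classification matches a brute-force oracle on random replicons", {
  set.seed(404)
  for (rep in 1:25) {
    genes <- random_gene_table(20)
    b <- make_bundle(genes)
    tfrs <- sample(genes$locus_tag, 8)
    got <- classify_context(b, tfrs)
    want <- oracle_classify(genes, tfrs)
    expect_equal(got$group, want$group, info = sprintf("replicon %d", rep))
    div <- !is.na(want$separation_raw)
    expect_equal(got$separation_raw[div], want$separation_raw[div],
                 info = sprintf("replicon %d separations", rep))
  }
})

test_that("group assignments and separations are strand-flip invariant", {
  set.seed(77)
  for (rep in 1:10) {
    genes <- random_gene_table(20)
    b <- make_bundle(genes)
    tfrs <- sample(genes$locus_tag, 6)
    fwd <- classify_context(b, tfrs)
    rev <- classify_context(mirror_bundle(b), tfrs)
    ord <- order(fwd$tfr_locus)
    ord2 <- order(rev$tfr_locus)
    expect_equal(fwd$group[ord], rev$group[ord2])
    expect_equal(fwd$separation_raw[ord], rev$separation_raw[ord2])
  }
})

test_that("every TFR gets exactly one group and counts partition the set", {
  set.seed(11)
  genes <- random_gene_table(30)
  b <- make_bundle(genes)
  tfrs <- genes$locus_tag
  calls <- classify_context(b, tfrs)
  expect_equal(nrow(calls), length(tfrs))
  expect_true(all(calls$group %in% c("DIVERGENT", "OPERONIC", "OTHER")))
  expect_equal(sum(table(calls$group)), length(tfrs))
  # a TFR can have at most one divergent neighbor
  expect_true(all(is.na(calls$divergent_neighbor) |
                  !duplicated(paste(calls$tfr_locus, calls$divergent_neighbor))))
})

test_that("target predictions apply the distance rule with configurable strictness", {
  panel <- tfr_reference_panel()
  bp <- bundle_from_separations(panel)
  calls <- classify_context(bp$bundle, bp$tfrs)
  expect_true(all(calls$group == "DIVERGENT"))
  expect_equal(
    stats::setNames(calls$separation_clamped, calls$tfr_locus)[panel$tfr_locus],
    stats::setNames(panel$separation_bp, panel$tfr_locus))

  preds <- predict_targets(calls)
  expect_equal(sum(preds$predicted), 5)
  expect_setequal(preds$tfr_locus[preds$predicted],
                  c("SCO5082", "SCO4099", "SGR3979", "SCO7222", "SCO3367"))
  expect_true(all(preds$tier[preds$predicted] == "strong"))

  # threshold 0 predicts nothing here; strict-less at an exact boundary differs
  none <- predict_targets(calls, context_thresholds(target_distance_max = 0))
  expect_equal(sum(none$predicted), 0)
  at212 <- predict_targets(calls, context_thresholds(target_distance_max = 212))
  at212s <- predict_targets(calls, context_thresholds(target_distance_max = 212,
                                                      threshold_inclusive = FALSE))
  expect_equal(sum(at212$predicted) - sum(at212s$predicted), 1)
})

test_that("predicted count is monotone in the distance threshold", {
  panel <- tfr_reference_panel()
  bp <- bundle_from_separations(panel)
  calls <- classify_context(bp$bundle, bp$tfrs)
  counts <- vapply(seq(0, 1200, by = 25), function(th) {
    sum(predict_targets(calls, context_thresholds(target_distance_max = th))$predicted)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_equal(counts[length(counts)], nrow(panel))
})

test_that("IGR extraction returns the DNA strictly between start codons", {
  fx <- generate_fixture(fixture_spec(n_tfr = 10, seed = 5))
  calls <- classify_context(fx$bundle, fx$truth$locus_tag)
  igrs <- extract_igr(fx$bundle, calls)
  div <- fx$truth[fx$truth$true_group == "DIVERGENT", ]
  expect_setequal(igrs$tfr_locus, div$locus_tag)
  expect_equal(
    stats::setNames(igrs$length, igrs$tfr_locus)[div$locus_tag],
    stats::setNames(div$true_separation, div$locus_tag))
  expect_true(all(nchar(igrs$seq) == igrs$length))
  expect_true(all(igrs$bed_end - igrs$bed_start == igrs$length))

  # strand flip: re-extracted IGR is the reverse complement of the original
  flipped <- mirror_bundle(fx$bundle)
  igrs2 <- extract_igr(flipped, classify_context(flipped, fx$truth$locus_tag))
  m <- match(igrs$tfr_locus, igrs2$tfr_locus)
  expect_equal(vapply(igrs$seq, oracle_revcomp, character(1), USE.NAMES = FALSE),
               igrs2$seq[m])
})

test_that("IGR extraction without sequence errors; abutting starts give empty IGR", {
  g <- tibble::tibble(locus_tag = c("n", "tfr"), strand = c("-", "+"),
                      start = c(10L, 501L), end = c(500L, 900L))
  b <- make_bundle(g)
  calls <- classify_context(b, "tfr")
  expect_error(extract_igr(b, calls), "no sequence")
  seq <- strrep("ACGT", 250)
  b2 <- make_bundle(g, length = 1000L, sequence = seq)
  expect_warning(igr <- extract_igr(b2, calls), "separation")
  expect_equal(igr$seq, "")
  expect_equal(igr$length, 0L)
})

test_that("spot-check separations resolve published pair lists against a bundle", {
  fx <- generate_fixture(fixture_spec(n_tfr = 8, seed = 9))
  div <- fx$truth[fx$truth$true_group == "DIVERGENT", ]
  pairs <- tibble::tibble(locus_a = div$locus_tag, locus_b = div$true_neighbor)
  out <- spot_check_separations(fx$bundle, pairs)
  expect_equal(out$separation_bp, div$true_separation)
  bad <- spot_check_separations(
    fx$bundle, tibble::tibble(locus_a = "missing", locus_b = div$locus_tag[1]))
  expect_true(is.na(bad$separation_bp))
})
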
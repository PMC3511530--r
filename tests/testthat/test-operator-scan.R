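test_that("known operator geometries are found exactly", {
  # 15-mer with arm 7 / loop 1: left arm is the reverse complement of the
  # right arm (checked by hand: revcomp(CGTTCCA) = TGGAACG)
  s1 <- find_inverted_repeats("TGGAACGTCGTTCCA", min_arm = 5, max_loop = 3,
                              max_mismatch = 0)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$offset, 0L)
  expect_equal(s1$arm_len, 7L)
  expect_equal(s1$loop_len, 1L)
  expect_equal(s1$mismatches, 0L)
  expect_equal(s1$site_seq, "TGGAACGTCGTTCCA")

  # arm 5 / loop 4 site (ACTAA ... TTAGT; revcomp(TTAGT) = ACTAA)
  s2 <- find_inverted_repeats("ACTAACCACTTAGT", min_arm = 4, max_loop = 4,
                              max_mismatch = 0)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$arm_len, 5L)
  expect_equal(s2$loop_len, 4L)

  # homopolymer arms cannot mirror to themselves
  expect_equal(nrow(find_inverted_repeats("AAAAAAAA", min_arm = 3,
                                          max_loop = 3, max_mismatch = 0)), 0)
  # minimal self-reverse-complement
  s3 <- find_inverted_repeats("ACGT", min_arm = 2, max_loop = 0,
                              max_mismatch = 0)
  expect_equal(nrow(s3), 1)
  expect_equal(s3$arm_len, 2L)
  expect_equal(s3$loop_len, 0L)
})

test_that("scanner rejects invalid characters and treats N as never matching", {
  expect_error(find_inverted_repeats("ACGU"), "invalid DNA")
  # perfect arm broken by N: with zero budget nothing is reported
  expect_equal(nrow(find_inverted_repeats("TGGAANGTCGTTCCA", min_arm = 7,
                                          max_loop = 1, max_mismatch = 0)), 0)
})

test_that("scanner agrees with the brute-force oracle on random sequences", {
  set.seed(1234)
  n_seq <- 120
  for (i in seq_len(n_seq)) {
    seq <- random_test_dna(60)
    got <- as.data.frame(find_inverted_repeats(seq))[,
      c("offset", "arm_len", "loop_len", "mismatches")]
    want <- oracle_sites(seq)
    rownames(got) <- NULL
    expect_equal(got, want, info = sprintf("sequence %d: %s", i, seq))
  }
})

test_that("reported mismatch counts equal arm Hamming distances, and scanning is
           reverse-complement symmetric", {
  set.seed(99)
  for (i in 1:30) {
    seq <- random_test_dna(80)
    sites <- find_inverted_repeats(seq)
    if (nrow(sites) > 0) {
      hd <- vapply(seq_len(nrow(sites)), function(j) {
        s <- sites[j, ]
        left <- substr(s$site_seq, 1, s$arm_len)
        right <- substr(s$site_seq, s$arm_len + s$loop_len + 1,
                        2 * s$arm_len + s$loop_len)
        sum(strsplit(left, "")[[1]] != strsplit(oracle_revcomp(right), "")[[1]])
      }, numeric(1))
      expect_equal(sites$mismatches, as.integer(hd))
    }
    rc_sites <- find_inverted_repeats(oracle_revcomp(seq))
    mirrored <- tibble::tibble(
      offset = nchar(seq) - (sites$offset + 2L * sites$arm_len + sites$loop_len),
      arm_len = sites$arm_len, loop_len = sites$loop_len,
      mismatches = sites$mismatches)
    mirrored <- dplyr::arrange(mirrored, offset, dplyr::desc(arm_len), loop_len)
    expect_equal(as.data.frame(mirrored),
                 as.data.frame(rc_sites[, names(mirrored)]))
  }
})

test_that("IUPAC consensus matching respects degeneracy on both strands", {
  sites <- c("TGGAACGTCGTTCCA", "TGGAACGACGTTCCA", "TGGAACGCCGTTCCA")
  hits <- vapply(sites, function(s) {
    nrow(match_consensus(s, "TGGAACGNCGTTCCA"))
  }, numeric(1))
  expect_equal(unname(hits), c(1, 1, 1))

  expect_equal(nrow(match_consensus("ACGTA", "NNN")), 3)
  expect_equal(nrow(match_consensus("AAAA", "TTT")), 0)
  # an all-N pattern of length L over length M gives M - L + 1 matches
  expect_equal(nrow(match_consensus(random_test_dna(40), strrep("N", 8))), 33)

  # R = A/G at the degenerate position; reverse strand picks up the
  # revcomp rendering of the site
  both <- match_consensus("TTTGGAACGTCGTTCCATT", "TGGAACGNCGTTCCA",
                          both_strands = TRUE)
  expect_equal(nrow(both), 2)
  expect_setequal(both$strand, c("+", "-"))
  expect_equal(unique(both$offset), 2L)

  expect_error(match_consensus("ACGT", "AXG"), "IUPAC")
  expect_error(match_consensus("ACGT", "AUG"), "IUPAC")
})

test_that("consensus building emits N (default) or minimal IUPAC codes", {
  seqs <- c("TGGAACGTCGTTCCA", "TGGAACGACGTTCCA", "TGGAACGCCGTTCCA")
  expect_equal(build_consensus(seqs), "TGGAACGNCGTTCCA")
  expect_equal(build_consensus(c("ACGT", "ACGT")), "ACGT")  # idempotence
  expect_equal(build_consensus(c("AC", "GT")), "NN")
  expect_equal(build_consensus(c("AC", "GT"), mode = "iupac"), "RY")
  expect_equal(build_consensus(c("ACG", "TCG", "CCG"), mode = "iupac"), "HCG")
  expect_error(build_consensus(c("AC", "ACG")), "equal-length")
})

test_that("placement fractions bucket into the three IGR zones", {
  # site of span 10 centred at 15 bp of a 150 bp IGR
  p1 <- classify_placement(10, 4, 2, igr_length = 150)
  expect_equal(p1$zone, "TFR_PROXIMAL")
  p2 <- classify_placement(70, 4, 2, igr_length = 150)
  expect_equal(p2$zone, "CENTRAL")
  p3 <- classify_placement(130, 4, 2, igr_length = 150)
  expect_equal(p3$zone, "TARGET_PROXIMAL")
  # measuring from the other end flips the fraction
  p4 <- classify_placement(10, 4, 2, igr_length = 150, toward_target = FALSE)
  expect_equal(p4$zone, "TARGET_PROXIMAL")
  expect_equal(p1$fraction + p4$fraction, 1)
  expect_error(classify_placement(0, 4, 2, igr_length = 0), "positive")
})

test_that("experimentally footprinted operator sequences are recovered with
           default scan parameters", {
  fx <- operator_site_fixtures()
  for (i in seq_len(nrow(fx))) {
    sites <- find_inverted_repeats(fx$site_seq[i])
    expect_gt(nrow(sites), 0,
              label = sprintf("%s site %d (%s): sites found",
                              fx$tfr_name[i], fx$site_index[i], fx$site_seq[i]))
    expect_gte(max(sites$arm_len), 5)
  }
})

test_that("zero-mismatch loopless sites agree with an independent palindrome finder", {
  set.seed(4321)
  for (i in 1:20) {
    seq <- random_test_dna(100)
    ours <- find_inverted_repeats(seq, min_arm = 4, max_loop = 0,
                                  max_mismatch = 0)
    ref <- Biostrings::findPalindromes(
      Biostrings::DNAString(seq), min.armlength = 4, max.looplength = 0,
      max.mismatch = 0)
    # the reference reports maximal full spans; every site we report must
    # appear there with the same span
    if (nrow(ours) > 0) {
      spans <- paste(ours$offset + 1, ours$offset + 2 * ours$arm_len)
      ref_spans <- paste(Biostrings::start(ref), Biostrings::end(ref))
      expect_true(all(spans %in% ref_spans), label = seq)
    } else {
      expect_equal(length(ref), 0, label = seq)
    }
  }
})
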
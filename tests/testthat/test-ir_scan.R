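test_that("constructed repeats are recovered with exact geometry", {
  set.seed(21)
  x <- random_dna_str(11)
  spacer <- random_dna_str(5)
  s <- paste0(x, spacer, reverse_complement(x))
  r <- find_inverted_repeats(s, ir_params(min_arm = 11, max_gap = 7,
                                          max_mismatch = 0))
  expect_equal(nrow(r), 1L)
  expect_equal(r$arm_len, 11L)
  expect_equal(r$spacer_len, 5L)
  expect_equal(r$mismatches, 0L)
  expect_equal(r$arm1_seq, x)

  # R-BOX1 geometry: one substitution at position 2 of arm 2
  arm2 <- strsplit(reverse_complement(x), "")[[1]]
  arm2[2] <- setdiff(c("A", "C", "G", "T"), arm2[2])[1]
  s1 <- paste0(x, spacer, paste(arm2, collapse = ""))
  # at the exact budget the planted geometry is the only repeat ...
  r1 <- find_inverted_repeats(s1, ir_params(min_arm = 11, max_gap = 7,
                                            max_mismatch = 1))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$mismatches, 1L)
  expect_equal(r1$arm_len, 11L)
  expect_equal(r1$spacer_len, 5L)
  # ... and with headroom in the budget it is still reported exactly
  # (maximal spacer-eating variants may legitimately join it)
  r2 <- find_inverted_repeats(s1, ir_params(min_arm = 11, max_gap = 7,
                                            max_mismatch = 2))
  planted <- r2[r2$arm_len == 11 & r2$spacer_len == 5, ]
  expect_equal(planted$mismatches, 1L)
  expect_equal(planted$arm1_seq, x)

  # a homopolymer has no inverted repeats within a 2-mismatch budget
  expect_equal(nrow(find_inverted_repeats(strrep("A", 60),
                                          ir_params(min_arm = 10))), 0L)
})

test_that("scanner output equals the brute-force oracle on random inputs", {
  set.seed(22)
  for (i in 1:150) {
    L <- sample(20:120, 1)
    s <- random_dna_str(L, alphabet = c("A", "C", "G", "T",
                                        if (i %% 5 == 0) "N"))
    min_arm <- sample(4:15, 1)
    max_gap <- sample(0:7, 1)
    max_mm <- sample(0:3, 1)
    semantics <- if (i %% 7 == 0) "total" else "per_arm"
    got <- find_inverted_repeats(s, ir_params(min_arm, max_gap, max_mm,
                                              semantics))
    want <- ir_oracle(s, min_arm, max_gap, max_mm, semantics)
    expect_equal(got[, names(want)], want,
                 info = sprintf("seq %s arm %d gap %d mm %d %s",
                                s, min_arm, max_gap, max_mm, semantics))
  }
})

test_that("IR scan invariants: strand symmetry, re-validation, case", {
  set.seed(23)
  params <- ir_params(min_arm = 5, max_gap = 5, max_mismatch = 2)
  for (i in 1:40) {
    s <- random_dna_str(sample(30:150, 1))
    r <- find_inverted_repeats(s, params)
    # strand symmetry: results on revcomp mirror the coordinates
    rc <- find_inverted_repeats(reverse_complement(s), params)
    L <- nchar(s)
    mirrored <- data.frame(arm1_start = L - r$arm2_end,
                           arm1_end = L - r$arm2_start,
                           arm2_start = L - r$arm1_end,
                           arm2_end = L - r$arm1_start,
                           arm_len = r$arm_len, spacer_len = r$spacer_len,
                           mismatches = r$mismatches)
    mirrored <- mirrored[order(mirrored$arm1_start, -mirrored$arm_len,
                               mirrored$spacer_len), ]
    rownames(mirrored) <- NULL
    expect_equal(rc[, names(mirrored)], mirrored)
    # every reported repeat re-validates its mismatch count
    for (j in seq_len(nrow(r))) {
      a1 <- strsplit(r$arm1_seq[j], "")[[1]]
      a2r <- strsplit(reverse_complement(r$arm2_seq[j]), "")[[1]]
      expect_equal(sum(a1 != a2r), r$mismatches[j])
      expect_equal(r$arm2_start[j] - r$arm1_end[j], r$spacer_len[j])
    }
    # case invariance
    expect_equal(find_inverted_repeats(tolower(s), params)[, 2:8], r[, 2:8])
  }
})

test_that("upstream scanning counts IR-bearing loci and is monotone", {
  corp <- shared_corpus()
  fx <- write_corpus_inputs(corp, withr::local_tempdir())
  genomes <- corp$genomes
  reg_hits <- search(corp$query, genomes, thresholds = search_thresholds(1e-5))
  loci <- anchor_regulators(reg_hits, genomes)
  res <- scan_upstream_all(loci, ir_params())
  planted <- corp$expected_irs
  expect_equal(res$summary$n_loci_with_ir, length(unique(planted$locus_id)))
  # every planted repeat is recovered with its exact geometry
  for (j in seq_len(nrow(planted))) {
    hit <- res$repeats[res$repeats$seq_id == planted$locus_id[j] &
                         res$repeats$arm_len == planted$arm_len[j] &
                         res$repeats$spacer_len == planted$spacer_len[j], ]
    expect_equal(nrow(hit), 1L, info = planted$locus_id[j])
    expect_equal(hit$mismatches, planted$mismatches[j])
    expect_equal(hit$arm1_seq, planted$arm1_seq[j])
    expect_equal(hit$arm2_seq, planted$arm2_seq[j])
    # position within the upstream window: offset bases before gene start
    expect_equal(hit$arm2_end, 200L - planted$offset[j])
  }
  # stricter mismatch budget: every strict repeat has a full-budget
  # counterpart with the same inner boundary and spacer, at least as long
  strict <- scan_upstream_all(loci, ir_params(max_mismatch = 0L))
  for (j in seq_len(nrow(strict$repeats))) {
    sr <- strict$repeats[j, ]
    match_full <- res$repeats[res$repeats$seq_id == sr$seq_id &
                                res$repeats$arm1_end == sr$arm1_end &
                                res$repeats$spacer_len == sr$spacer_len, ]
    expect_equal(nrow(match_full), 1L)
    expect_gte(match_full$arm_len, sr$arm_len)
  }
  # too-short upstream sequence: no hits, message logged
  short <- loci[1, , drop = FALSE]
  short$upstream_seq <- substr(short$upstream_seq, 1, 30)
  expect_message(r2 <- scan_upstream_all(short, ir_params()), "shorter")
  expect_equal(r2$summary$n_ir, 0L)
})

test_that("operator-box comparison counts per-component differences", {
  a <- list(arm1_seq = "ACGTACGTACG", spacer_seq = "TTTTT",
            arm2_seq = "CGTACGTACGT")
  expect_equal(score_rbox_pair(a, a)[c("ir1_diff", "spacer_diff", "ir2_diff")],
               list(ir1_diff = 0L, spacer_diff = 0L, ir2_diff = 0L))
  b <- a; substr(b$arm2_seq, 3, 3) <- "A"
  expect_equal(score_rbox_pair(a, b)$ir2_diff, 1L)
  # random pairs against direct positional comparison
  set.seed(24)
  for (i in 1:20) {
    x <- list(arm1_seq = random_dna_str(11), spacer_seq = random_dna_str(5),
              arm2_seq = random_dna_str(11))
    y <- list(arm1_seq = random_dna_str(11), spacer_seq = random_dna_str(5),
              arm2_seq = random_dna_str(11))
    got <- score_rbox_pair(x, y)
    expect_equal(got$ir1_diff, sum(strsplit(x$arm1_seq, "")[[1]] !=
                                     strsplit(y$arm1_seq, "")[[1]]))
    expect_equal(got$spacer_diff, sum(strsplit(x$spacer_seq, "")[[1]] !=
                                        strsplit(y$spacer_seq, "")[[1]]))
  }
  expect_error(score_rbox_pair(a, list(arm1_seq = "ACGT", spacer_seq = "TTTTT",
                                       arm2_seq = "ACGT")), "unequal")
})
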
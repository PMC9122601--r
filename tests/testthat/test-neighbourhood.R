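# window-geometry fixture: regulator at [5000,6000) plus markers at
# controlled edge gaps on both sides
window_fixture <- function(anchor_strand = "+") {
  feats <- rbind(
    mk_feat("reg", "g1_rep1", 5000, 6000, anchor_strand),
    mk_feat("m_right_10k", "g1_rep1", 16000, 16900),
    mk_feat("m_right_just_out", "g1_rep1", 56001, 56900),
    mk_feat("m_right_at_50k", "g1_rep1", 56000, 56900),
    mk_feat("m_left_10k", "g1_rep1", 3000, 4000, "-"))
  g <- toy_genome(feats, len = 70000L)
  hits <- do.call(rbind, lapply(
    c("m_right_10k", "m_right_just_out", "m_right_at_50k", "m_left_10k"),
    function(f) mk_hit(g, f, query_id = "brxA")))
  loci <- data.frame(locus_id = "g1:reg", genome_id = "g1",
                     feature_id = "reg", replicon_id = "g1_rep1",
                     start = 5000L, end = 6000L, strand = anchor_strand,
                     replicon_type = "chromosome", evalue = 1e-20,
                     identity_frac = 0.9, upstream_seq = strrep("A", 200),
                     stringsAsFactors = FALSE)
  list(g = g, hits = hits, locus = loci)
}

test_that("scan_window applies the strand-aware <= W edge-gap filter", {
  fx <- window_fixture("+")
  down <- scan_window(fx$locus, fx$hits, fx$g, W = 50000L, "downstream")
  expect_setequal(down$subject_feature_id, c("m_right_10k", "m_right_at_50k"))
  expect_equal(down$distance[down$subject_feature_id == "m_right_10k"], 10000L)
  expect_equal(down$distance[down$subject_feature_id == "m_right_at_50k"], 50000L)
  up <- scan_window(fx$locus, fx$hits, fx$g, W = 50000L, "upstream")
  expect_equal(up$subject_feature_id, "m_left_10k")
  expect_equal(up$distance, 1000L)

  # minus-strand anchor: downstream and upstream swap sides
  fm <- window_fixture("-")
  downm <- scan_window(fm$locus, fm$hits, fm$g, W = 50000L, "downstream")
  expect_equal(downm$subject_feature_id, "m_left_10k")
  upm <- scan_window(fm$locus, fm$hits, fm$g, W = 50000L, "upstream")
  expect_setequal(upm$subject_feature_id, c("m_right_10k", "m_right_at_50k"))

  # coordinate mode ignores the anchor strand
  downc <- scan_window(fm$locus, fm$hits, fm$g, W = 50000L, "downstream",
                       direction_mode = "coordinate")
  expect_setequal(downc$subject_feature_id, c("m_right_10k", "m_right_at_50k"))

  # the regulator's own feature is never returned
  own <- rbind(fx$hits, mk_hit(fx$g, "reg", query_id = "brxA"))
  d2 <- scan_window(fx$locus, own, fx$g, W = 50000L, "downstream")
  expect_false("reg" %in% d2$subject_feature_id)
})

test_that("group_systems collapses by system name within the cluster gap", {
  feats <- rbind(
    mk_feat("reg", "g1_rep1", 1000, 2000),
    mk_feat("b1", "g1_rep1", 10000, 10900),
    mk_feat("b2", "g1_rep1", 14000, 14900),
    mk_feat("b3", "g1_rep1", 18000, 18900),
    mk_feat("mrr1", "g1_rep1", 20000, 20900),
    mk_feat("b4", "g1_rep1", 49000, 49900))
  g <- toy_genome(feats, len = 70000L)
  panel <- toy_panel()
  hits <- rbind(mk_hit(g, "b1", "brxA", evalue = 1e-30),
                mk_hit(g, "b2", "brxB", evalue = 1e-10),
                mk_hit(g, "b3", "brxC", evalue = 1e-20),
                mk_hit(g, "mrr1", "mrr", evalue = 1e-15),
                mk_hit(g, "b4", "brxA", evalue = 1e-8))
  locus <- data.frame(locus_id = "g1:reg", genome_id = "g1",
                      feature_id = "reg", replicon_id = "g1_rep1",
                      start = 1000L, end = 2000L, strand = "+",
                      stringsAsFactors = FALSE)
  wh <- scan_window(locus, hits, g, 50000L, "downstream")
  ins <- group_systems(wh, panel, g, "g1:reg", "downstream",
                       cluster_gap = 20000L)
  # b1..b3 (8.9 kb span) collapse; b4 is 30.1 kb past b3 -> second instance
  brex <- ins[ins$system_class == "BREX", ]
  expect_equal(nrow(brex), 2L)
  expect_equal(brex$n_markers, c(3L, 1L))
  expect_equal(brex$subtype[1], "I")   # subtype of the best-E hit
  expect_equal(nrow(ins[ins$system_class == "Type IV restriction", ]), 1L)
  # distance is the nearest marker's edge gap
  expect_equal(brex$distance[1], 8000L)
  # a hit without a panel mapping is an error
  bad <- wh; bad$query_id[1] <- "not_in_panel"
  expect_error(group_systems(bad, panel, g, "x", "downstream"),
               "lack a panel mapping")
})

test_that("classify yields the four-way verdict", {
  locus <- data.frame(locus_id = "L1", stringsAsFactors = FALSE)
  some <- data.frame(instance_id = "i1")
  none <- data.frame()
  expect_equal(classify(locus, some, none)$verdict, "downstream_only")
  expect_equal(classify(locus, none, some)$verdict, "upstream_only")
  expect_equal(classify(locus, some, some)$verdict, "both")
  expect_equal(classify(locus, none, none)$verdict, "none")
})

mk_instances <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(instance_id = paste0(r[[1]], r[[3]]), locus_id = r[[1]],
               direction = r[[2]], system_class = r[[3]],
               system_name = paste0(r[[3]], "_1"), subtype = NA_character_,
               n_markers = 1L, marker_feature_ids = "x", span_start = 0L,
               span_end = 1L, distance = 100L, stringsAsFactors = FALSE)
  }))
}

test_that("cooccurrence maps class sets to locus counts", {
  ins <- mk_instances(
    list("L1", "downstream", "BREX"),
    list("L2", "downstream", "BREX"),
    list("L2", "downstream", "Type IV restriction"),
    list("L3", "upstream", "CBASS"))
  co <- cooccurrence(ins)
  expect_setequal(co$classes, c("BREX", "BREX+Type IV restriction"))
  expect_equal(sum(co$n_loci), 2L)  # L3 is upstream-only: not counted
  expect_equal(nrow(cooccurrence(ins[0, ])), 0L)
  # singleton counts equal a brute-force set decomposition
  set.seed(31)
  classes <- c("BREX", "CBASS", "Wadjet")
  rows <- list()
  for (l in 1:30) {
    for (cl in sample(classes, sample(0:3, 1))) {
      rows[[length(rows) + 1L]] <- list(paste0("L", l), "downstream", cl)
    }
  }
  ins2 <- do.call(mk_instances, rows)
  co2 <- cooccurrence(ins2)
  sets <- lapply(split(ins2$system_class, ins2$locus_id),
                 function(x) sort(unique(x)))
  for (cl in classes) {
    alone <- sum(vapply(sets, function(s) identical(s, cl), TRUE))
    got <- co2$n_loci[co2$classes == cl]
    expect_equal(if (length(got)) got else 0L, alone, info = cl)
  }
  expect_equal(sum(co2$n_loci), length(sets))
})

test_that("class distribution reproduces two-decimal percentages", {
  rows <- c(rep("BREX", 70), rep("Type IV restriction", 37),
            rep("Type I RM", 34), rep("CRISPR-Cas", 21),
            rep("other", 48))  # 210 instances in total
  ins <- do.call(mk_instances, lapply(seq_along(rows), function(i) {
    list(paste0("L", i), "downstream", rows[i])
  }))
  cd <- class_distribution(ins)
  expect_equal(cd$percent[cd$system_class == "BREX"], 33.33)
  expect_equal(cd$percent[cd$system_class == "CRISPR-Cas"], 10.00)
  expect_equal(cd$percent[cd$system_class == "Type I RM"], 16.19)
  expect_equal(sum(cd$percent), 100, tolerance = 0.0006)
  one <- class_distribution(mk_instances(list("L1", "downstream", "BREX")))
  expect_equal(one$percent, 100.00)
})

test_that("taxonomy summary computes per-rank percentages with unclassified bin", {
  loci <- data.frame(locus_id = sprintf("L%d", 1:347),
                     genome_id = sprintf("G%d", 1:347),
                     replicon_type = "chromosome", stringsAsFactors = FALSE)
  lineage <- data.frame(assembly_id = sprintf("G%d", 1:347),
                        genus = c(rep("Pseudomonas", 24),
                                  rep("Shewanella", 18),
                                  rep("other", 305)),
                        phylum = c(rep("Proteobacteria", 338),
                                   rep("Firmicutes", 9)),
                        stringsAsFactors = FALSE)
  tx <- taxonomy_summary(loci, lineage)
  expect_equal(tx$percent[tx$rank == "genus" & tx$name == "Pseudomonas"], 6.92)
  expect_equal(tx$percent[tx$rank == "genus" & tx$name == "Shewanella"], 5.19)
  expect_equal(tx$percent[tx$rank == "phylum" & tx$name == "Proteobacteria"],
               97.41)
  # empty lineage: everything unclassified, percents still total 100
  tx0 <- taxonomy_summary(loci, NULL)
  expect_equal(tx0$name, "unclassified")
  expect_equal(tx0$percent, 100)
})

test_that("replicon summary covers all three types with zeros", {
  loci <- data.frame(genome_id = c("a", "b", "c"),
                     replicon_type = c("plasmid", "plasmid", "chromosome"),
                     stringsAsFactors = FALSE)
  rs <- replicon_summary(loci)
  expect_equal(rs$count[rs$replicon_type == "plasmid"], 2L)
  expect_equal(rs$count[rs$replicon_type == "unknown"], 0L)
  expect_equal(sum(replicon_summary(loci[0, ])$count), 0L)
})

test_that("anchoring attaches upstream sequence and replicon type", {
  corp <- shared_corpus()
  reg_hits <- search(corp$query, corp$genomes,
                     thresholds = search_thresholds(1e-5))
  loci <- anchor_regulators(reg_hits, corp$genomes)
  expect_equal(nrow(loci), nrow(corp$expected$records))
  expect_equal(sum(table(loci$genome_id) > 1), 1L)  # one two-locus genome
  expect_true(all(nchar(loci$upstream_seq) == 200L))
  expect_equal(sort(unique(loci$replicon_type[loci$genome_id == "synthg005"])),
               "plasmid")
  # truncated upstream when the gene sits near the replicon edge
  g <- toy_genome(mk_feat("near", "g1_rep1", 120, 900,
                          prot = "MKLV"), len = 5000L)
  h <- mk_hit(g, "near")
  l2 <- anchor_regulators(h, g)
  expect_equal(nchar(l2$upstream_seq), 120L)
  expect_equal(nrow(anchor_regulators(h[0, ], g)), 0L)
})

test_that("association invariants hold on the synthetic corpus", {
  corp <- shared_corpus()
  reg_hits <- search(corp$query, corp$genomes,
                     thresholds = search_thresholds(1e-5))
  marker_queries <- setNames(corp$panel$protein_seq, corp$panel$marker_id)
  marker_hits <- search(marker_queries, corp$genomes,
                        thresholds = search_thresholds(1e-5))
  loci <- anchor_regulators(reg_hits, corp$genomes)
  assoc <- associate_loci(loci, marker_hits, corp$genomes, corp$panel)
  # verdict partition
  expect_equal(sum(table(assoc$records$verdict)), nrow(loci))
  # window monotonicity: associated loci grow with W
  a_small <- associate_loci(loci, marker_hits, corp$genomes, corp$panel,
                            W = 20000L)
  assoc_ids <- function(a) a$records$locus_id[a$records$verdict != "none"]
  expect_true(all(assoc_ids(a_small) %in% assoc_ids(assoc)))
  # co-occurrence totals equal downstream-associated loci
  co <- cooccurrence(assoc$instances)
  expect_equal(sum(co$n_loci),
               sum(assoc$records$verdict %in% c("downstream_only", "both")))
  # shrinking evalue_max never adds loci or instances
  tight_hits <- marker_hits[marker_hits$evalue < 1e-30, , drop = FALSE]
  a_tight <- associate_loci(loci, tight_hits, corp$genomes, corp$panel)
  expect_lte(nrow(a_tight$instances), nrow(assoc$instances))
  expect_true(all(assoc_ids(a_tight) %in% assoc_ids(assoc)))
})
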
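test_that("GFF3 CDS coordinates convert to 0-based half-open and round-trip", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fna"); gf <- file.path(td, "g.gff3")
  set.seed(7)
  writeLines(c(">rep1 chromosome linear", random_dna_str(3000)), fa)
  writeLines(c("##gff-version 3",
               "rep1\tsrc\tCDS\t1001\t2000\t.\t+\t0\tID=geneA;product=thing",
               "rep1\tsrc\tgene\t1001\t2000\t.\t+\t0\tID=geneA_g",
               "rep1\tsrc\tCDS\t2101\t2400\t.\t-\t0\tID=geneB"), gf)
  g <- suppressWarnings(read_genome(fa, gf))
  expect_equal(g$features$start, c(1000L, 2100L))
  expect_equal(g$features$end, c(2000L, 2400L))
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$feature_id, c("geneA", "geneB"))
  expect_equal(g$replicons$replicon_type, "chromosome")

  # agreement with an established GFF3 reader on the same file
  gr <- rtracklayer::import(gf)
  cds <- gr[gr$type == "CDS"]
  expect_equal(g$features$start, GenomicRanges::start(cds) - 1L)
  expect_equal(g$features$end, GenomicRanges::end(cds))

  # round-trip through write_genome is bit-exact on features
  paths <- write_genome(g, file.path(td, "out"))
  g2 <- suppressWarnings(read_genome(
    paths[["fasta"]], paths[["gff3"]],
    protein_fasta_path = if ("protein" %in% names(paths)) paths[["protein"]],
    assembly_id = g$assembly_id))
  expect_identical(
    g2$features[c("feature_id", "replicon_id", "start", "end", "strand")],
    g$features[order(g$features$replicon_id, g$features$start),
               c("feature_id", "replicon_id", "start", "end", "strand")])
  expect_identical(g2$replicons$sequence, g$replicons$sequence)

  # JSON fixture serialization round-trips
  jp <- file.path(td, "g.json")
  write_genome_json(g, jp)
  g3 <- read_genome_json(jp)
  expect_identical(g3$features, g$features)
  expect_identical(g3$replicons, g$replicons)
})

test_that("malformed GFF3 and out-of-bounds features are reported", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fna"); gf <- file.path(td, "g.gff3")
  writeLines(c(">rep1", strrep("ACGT", 100)), fa)
  writeLines(c("##gff-version 3", "rep1\tsrc\tCDS\t10\t50\t.\t+\t0"), gf)
  expect_error(read_genome(fa, gf), "line 2.*9 tab-separated",
               class = "brxrscan_parse_error")
  writeLines(c("##gff-version 3",
               "rep1\tsrc\tCDS\t10\t5000\t.\t+\t0\tID=x"), gf)
  expect_error(suppressWarnings(read_genome(fa, gf)), "outside replicon bounds",
               class = "brxrscan_validation_error")
})

test_that("CDS not divisible by 3 is kept without protein, with a warning", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fna"); gf <- file.path(td, "g.gff3")
  writeLines(c(">rep1", strrep("ACGT", 100)), fa)
  writeLines(c("##gff-version 3",
               "rep1\tsrc\tCDS\t11\t20\t.\t+\t0\tID=broken"), gf)
  expect_warning(g <- read_genome(fa, gf), "not divisible by 3")
  expect_true(is.na(g$features$protein_seq[1]))
})

test_that("GenBank records parse: plasmid keyword, strand, translation", {
  td <- withr::local_tempdir()
  gb <- file.path(td, "g.gbk")
  seq <- paste0(strrep("acgt", 30))
  writeLines(c(
    "LOCUS       pTEST                 120 bp    DNA     circular BCT 01-JAN-2020",
    "DEFINITION  Escherichia sp. plasmid pTEST, complete sequence.",
    "FEATURES             Location/Qualifiers",
    "     CDS             7..15",
    "                     /locus_tag=\"ptest_001\"",
    "                     /product=\"demo protein\"",
    "                     /translation=\"MK\"",
    "     CDS             complement(31..39)",
    "                     /locus_tag=\"ptest_002\"",
    "ORIGIN",
    paste0("        1 ", seq),
    "//"), gb)
  g <- suppressWarnings(read_genome(genbank_path = gb))
  expect_equal(g$replicons$replicon_type, "plasmid")
  expect_equal(g$replicons$topology, "circular")
  expect_equal(g$features$start, c(6L, 30L))
  expect_equal(g$features$end, c(15L, 39L))
  expect_equal(g$features$strand, c("+", "-"))
  expect_equal(g$features$protein_seq[1], "MK")
  # second CDS has no supplied translation: translated from sequence
  expect_false(is.na(g$features$protein_seq[2]))
})

test_that("reverse_complement is a correct involution and rejects junk", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAT"), "ATTT")
  expect_identical(reverse_complement("acgtn"), "NACGT")
  expect_error(reverse_complement("ACGU"), "invalid character")
  set.seed(11)
  for (i in 1:20) {
    s <- random_dna_str(sample(1:200, 1), alphabet = c("A","C","G","T","N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("extract_upstream respects strand, truncation and wrap flag", {
  set.seed(3)
  s <- random_dna_str(3000)
  g <- toy_genome(rbind(mk_feat("plus", "g1_rep1", 1000, 2000, "+"),
                        mk_feat("minus", "g1_rep1", 1000, 2000, "-"),
                        mk_feat("edge", "g1_rep1", 120, 900, "+")),
                  seq = s)
  expect_identical(extract_upstream(g, "plus", 200), substr(s, 801, 1000))
  expect_identical(extract_upstream(g, "minus", 200),
                   reverse_complement(substr(s, 2001, 2200)))
  expect_identical(extract_upstream(g, "edge", 200), substr(s, 1, 120))
  expect_equal(nchar(extract_upstream(g, "edge", 200)), 120)
  # property: length <= requested, == requested when available
  for (len in c(1, 50, 999)) {
    expect_lte(nchar(extract_upstream(g, "plus", len)), len)
    expect_equal(nchar(extract_upstream(g, "plus", min(len, 1000))),
                 min(len, 1000))
  }
  # circular wrap only when enabled
  gc <- g; gc$replicons$topology <- "circular"
  expect_equal(nchar(extract_upstream(gc, "edge", 200)), 120)
  expect_identical(extract_upstream(gc, "edge", 200, circular_wrap = TRUE),
                   paste0(substr(s, 3000 - 79, 3000), substr(s, 1, 120)))
})

test_that("distance_between is strand-aware with edge-gap semantics", {
  g <- toy_genome(rbind(mk_feat("a", "g1_rep1", 1000, 2000, "+"),
                        mk_feat("b", "g1_rep1", 12000, 13000, "+"),
                        mk_feat("c", "g1_rep1", 10000, 11000, "-"),
                        mk_feat("d", "g1_rep1", 2000, 3000, "+"),
                        mk_feat("e", "g1_rep1", 1500, 2500, "+")))
  f <- function(id) g$features[g$features$feature_id == id, ]
  expect_equal(distance_between(f("a"), f("b")),
               list(distance = 10000L, direction = "downstream"))
  expect_equal(distance_between(f("c"), f("d")),
               list(distance = 7000L, direction = "downstream"))
  expect_equal(distance_between(f("a"), f("e")),
               list(distance = 0L, direction = "overlapping"))
  # symmetric magnitude, antisymmetric direction for equal strands
  d1 <- distance_between(f("a"), f("b")); d2 <- distance_between(f("b"), f("a"))
  expect_equal(d1$distance, d2$distance)
  expect_setequal(c(d1$direction, d2$direction), c("downstream", "upstream"))
  g2 <- toy_genome(mk_feat("x", "other", 0, 10), rep_id = "other")
  expect_error(distance_between(f("a"), g2$features[1, ]),
               "different replicons")
})

test_that("genome validation enforces the model invariants", {
  expect_error(toy_genome(mk_feat("x", "nope", 0, 10)), "unknown replicons",
               class = "brxrscan_validation_error")
  expect_error(genome("g", data.frame(replicon_id = "r", sequence = "ACGU")),
               "outside \\{A,C,G,T,N\\}")
  expect_error(genome("g", data.frame(replicon_id = c("r", "r"),
                                      sequence = c("ACG", "ACG"))),
               "unique")
})
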
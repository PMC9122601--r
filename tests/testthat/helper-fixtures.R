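# In-code fixtures shared across test files.

mk_feat <- function(fid, rep_id, start, end, strand = "+", prot = NA_character_) {
  data.frame(feature_id = fid, replicon_id = rep_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand, product = NA_character_, protein_seq = prot,
             stringsAsFactors = FALSE)
}

toy_genome <- function(feats = NULL, len = 70000L, id = "g1",
                       rep_id = "g1_rep1", type = "chromosome",
                       seq = NULL) {
  reps <- data.frame(replicon_id = rep_id,
                     sequence = seq %||% strrep("A", len),
                     replicon_type = type, topology = "linear",
                     stringsAsFactors = FALSE)
  genome(id, reps, feats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a fully-populated hit row referencing a feature of a genome
mk_hit <- function(g, fid, query_id = "q", evalue = 1e-10, identity = 0.8) {
  f <- g$features[match(fid, g$features$feature_id), ]
  data.frame(query_id = query_id, subject_feature_id = fid,
             genome_id = g$assembly_id, replicon_id = f$replicon_id,
             subject_start = f$start, subject_strand = f$strand,
             score = 100L, bitscore = 50, evalue = evalue,
             identity_frac = identity, aln_len = 100L,
             q_start = 1L, q_end = 100L, s_start = 1L, s_end = 100L,
             stringsAsFactors = FALSE)
}

# small panel mapping marker ids onto two classes, without sequences being
# used (for grouping tests the protein_seq content is irrelevant)
toy_panel <- function() {
  marker_panel(data.frame(
    marker_id = c("brxA", "brxB", "brxC", "mrr", "cas3"),
    protein_seq = strrep("M", 5),
    system_name = c("BREX_1", "BREX_1", "BREX_1", "TypeIV_1", "CRISPR_1"),
    system_class = c("BREX", "BREX", "BREX", "Type IV restriction",
                     "CRISPR-Cas"),
    subtype = c("I", "I", "I", NA, "I-F"), stringsAsFactors = FALSE))
}

# deterministic small corpus shared by neighbourhood/interface tests
shared_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_corpus(n_genomes = 6, seed = 402L)
    cache
  }
})

write_corpus_inputs <- function(corp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qf <- file.path(dir, "query.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(corp$query), qf)
  write_panel(corp$panel, file.path(dir, "panel.faa"),
              file.path(dir, "panel.tsv"))
  write.table(corp$lineage, file.path(dir, "lineage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gdir <- file.path(dir, "genomes")
  for (g in corp$genomes) write_genome(g, gdir)
  list(query = qf, panel_fasta = file.path(dir, "panel.faa"),
       panel_tsv = file.path(dir, "panel.tsv"),
       lineage = file.path(dir, "lineage.tsv"), genomes_dir = gdir)
}
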
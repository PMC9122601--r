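#' Simulate a multi-genome corpus with a shared regulator query
#'
#' Builds a deterministic corpus of annotated genomes emulating the
#' structure the association analysis assumes: one shared regulator
#' source protein planted across genomes at a controlled identity,
#' defence systems planted at edge gaps straddling the 50-kb window in
#' both strand-aware directions, plasmid replicons, multi-regulator
#' genomes, non-homologous decoy genes, and flank-guarded upstream
#' inverted repeats.  Six genome archetypes are cycled:
#'
#' 1. no systems (verdict `none`);
#' 2. one downstream system at 10 kb, regulator on `+`;
#' 3. regulator on `-` with a downstream system at 49.5 kb and an
#'    upstream system at exactly 50 kb (both within the window,
#'    verdict `both`);
#' 4. one system just beyond the window (50,001 bp; verdict `none`);
#' 5. regulator and an upstream system on a plasmid;
#' 6. two regulator loci, one associated downstream at 30 kb, the other
#'    on a second replicon with nothing (multi-homologue genome).
#'
#' @param n_genomes number of genomes (default 20).
#' @param seed integer root seed.
#' @param panel optional [marker_panel()]; defaults to
#'   `generate_panel(5, 2, seed)`.
#' @param identity regulator identity target (default 0.6).
#' @param out_dir if non-`NULL`, write FASTA/GFF3/protein files, the
#'   query FASTA, panel files, lineage TSV and truth JSON there.
#' @return list with `genomes`, `truths`, `panel`, `query` (named
#'   protein vector), `lineage`, `expected`
#'   (from [truth_associations()]), `expected_irs` (per-locus planted IR
#'   geometry) and `paths` (when written).
#' @export
simulate_corpus <- function(n_genomes = 20L, seed = 1L, panel = NULL,
                            identity = 0.6, out_dir = NULL) {
  if (is.null(panel)) panel <- generate_panel(5L, 2L, child_seed(seed, "panel"))
  query_seq <- random_protein(300L, child_seed(seed, "query"))
  query <- c(regulator_query = query_seq)
  sysnames <- unique(panel$system_name)
  marker_of <- function(sn) panel$marker_id[panel$system_name == sn]

  genomes <- list(); truths <- list(); expected_irs <- list()
  for (i in seq_len(n_genomes)) {
    gid <- sprintf("synthg%03d", i)
    gseed <- child_seed(seed, paste0("genome", i))
    arche <- (i - 1L) %% 6L
    sn1 <- sysnames[((i - 1L) %% length(sysnames)) + 1L]
    sn2 <- sysnames[(i %% length(sysnames)) + 1L]
    spec <- switch(
      as.character(arche),
      "0" = genome_spec(gid, gseed,
        replicons = data.frame(length = 30000L, replicon_type = "chromosome"),
        regulator = list(protein = query_seq, identity = identity,
                         placements = data.frame(replicon = 1L, pos = 5000L,
                                                 strand = "+")),
        decoys = list(count = 2L)),
      "1" = genome_spec(gid, gseed,
        replicons = data.frame(length = 80000L, replicon_type = "chromosome"),
        regulator = list(protein = query_seq, identity = identity,
                         placements = data.frame(replicon = 1L, pos = 5000L,
                                                 strand = "+")),
        planted_systems = list(list(system_name = sn1,
                                    markers = marker_of(sn1),
                                    anchor = 1L, direction = "downstream",
                                    edge_gap = 10000L, strand = "-")),
        decoys = list(count = 2L),
        planted_irs = list(list(anchor = 1L, arm_len = 20L, spacer_len = 5L,
                                mismatches = 2L, offset = 30L))),
      "2" = genome_spec(gid, gseed,
        replicons = data.frame(length = 125000L, replicon_type = "chromosome"),
        regulator = list(protein = query_seq, identity = identity,
                         placements = data.frame(replicon = 1L, pos = 60000L,
                                                 strand = "-")),
        planted_systems = list(
          list(system_name = sn1, markers = marker_of(sn1), anchor = 1L,
               direction = "downstream", edge_gap = 49500L, strand = "+"),
          list(system_name = sn2, markers = marker_of(sn2), anchor = 1L,
               direction = "upstream", edge_gap = 50000L, strand = "+")),
        decoys = list(count = 2L),
        planted_irs = list(list(anchor = 1L, arm_len = 22L, spacer_len = 4L,
                                mismatches = 2L, offset = 40L))),
      "3" = genome_spec(gid, gseed,
        replicons = data.frame(length = 90000L, replicon_type = "chromosome"),
        regulator = list(protein = query_seq, identity = identity,
                         placements = data.frame(replicon = 1L, pos = 5000L,
                                                 strand = "+")),
        planted_systems = list(list(system_name = sn1,
                                    markers = marker_of(sn1)[1],
                                    anchor = 1L, direction = "downstream",
                                    edge_gap = 50001L, strand = "+")),
        decoys = list(count = 2L)),
      "4" = genome_spec(gid, gseed,
        replicons = data.frame(length = c(40000L, 90000L),
                               replicon_type = c("chromosome", "plasmid")),
        regulator = list(protein = query_seq, identity = identity,
                         placements = data.frame(replicon = 2L, pos = 30000L,
                                                 strand = "-")),
        planted_systems = list(list(system_name = sn1,
                                    markers = marker_of(sn1),
                                    anchor = 1L, direction = "upstream",
                                    edge_gap = 15000L, strand = "-")),
        decoys = list(count = 2L),
        planted_irs = list(list(anchor = 1L, arm_len = 20L, spacer_len = 6L,
                                mismatches = 2L, offset = 25L))),
      "5" = genome_spec(gid, gseed,
        replicons = data.frame(length = c(70000L, 40000L),
                               replicon_type = c("chromosome", "chromosome")),
        regulator = list(protein = query_seq, identity = identity,
                         placements = data.frame(replicon = c(1L, 2L),
                                                 pos = c(5000L, 10000L),
                                                 strand = c("+", "+"))),
        planted_systems = list(list(system_name = sn1,
                                    markers = marker_of(sn1),
                                    anchor = 1L, direction = "downstream",
                                    edge_gap = 30000L, strand = "+")),
        decoys = list(count = 2L)))
    res <- generate_genome(spec, panel)
    genomes[[i]] <- res$genome
    truths[[i]] <- res$truth
    if (!is.null(res$truth$irs)) {
      e <- res$truth$irs
      e$locus_id <- sprintf("%s:%s", gid, e$anchor_feature)
      expected_irs[[length(expected_irs) + 1L]] <- e
    }
  }
  names(genomes) <- vapply(genomes, `[[`, "", "assembly_id")

  n_ps <- max(1L, round(0.4 * n_genomes))
  n_vib <- max(1L, round(0.2 * n_genomes))
  lineage <- generate_lineage(
    names(genomes),
    allocation = data.frame(
      genus = c("Pseudomonas", "Vibrio"),
      class = c("Gammaproteobacteria", "Gammaproteobacteria"),
      phylum = c("Proteobacteria", "Proteobacteria"),
      n = c(n_ps, n_vib), stringsAsFactors = FALSE),
    seed = child_seed(seed, "lineage"))

  out <- list(genomes = genomes, truths = truths, panel = panel,
              query = query, lineage = lineage,
              expected = truth_associations(truths),
              expected_irs = if (length(expected_irs))
                do.call(rbind, expected_irs) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gdir <- file.path(out_dir, "genomes")
    for (g in genomes) write_genome(g, gdir)
    qf <- file.path(out_dir, "query.faa")
    aa <- Biostrings::AAStringSet(query)
    Biostrings::writeXStringSet(aa, qf, width = 80L)
    write_panel(panel, file.path(out_dir, "panel.faa"),
                file.path(out_dir, "panel.tsv"))
    write.table(lineage, file.path(out_dir, "lineage.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_truth_json(truths, file.path(out_dir, "truth.json"))
    out$paths <- list(genomes = gdir, query = qf,
                      panel_fasta = file.path(out_dir, "panel.faa"),
                      panel_tsv = file.path(out_dir, "panel.tsv"),
                      lineage = file.path(out_dir, "lineage.tsv"),
                      truth = file.path(out_dir, "truth.json"))
  }
  out
}
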
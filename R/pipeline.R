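#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end scan with its default: 50-kb
#' association window, 200-bp upstream extract, E-value thresholds 1e-5
#' (primary) and 1e-3 (sensitivity re-check), inverted-repeat scan at
#' minimum arm 20 / gap < 8 / at most 2 mismatches, 20-kb marker
#' clustering gap, and strand-aware direction.
#'
#' @param window association window W in bp.
#' @param upstream upstream extract length U in bp.
#' @param evalue_primary,evalue_sensitive search thresholds.
#' @param ir an [ir_params()].
#' @param cluster_gap marker clustering gap in bp.
#' @param direction_mode `"strand"` or `"coordinate"`.
#' @param genomes_dir directory of genome files (`*.fna` + `*.gff3`,
#'   optional `*.faa`, or `*.gbk`).
#' @param query regulator protein FASTA path.
#' @param panel_fasta,panel_tsv marker panel paths.
#' @param lineage optional lineage TSV path.
#' @param out_dir output directory.
#' @param seed integer seed recorded in the manifest (the analysis
#'   stages themselves are deterministic and seed-free).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 50000L, upstream = 200L,
                            evalue_primary = 1e-5, evalue_sensitive = 1e-3,
                            ir = ir_params(), cluster_gap = 20000L,
                            direction_mode = "strand",
                            genomes_dir = NULL, query = NULL,
                            panel_fasta = NULL, panel_tsv = NULL,
                            lineage = NULL, out_dir = NULL, seed = 1L) {
  structure(list(window = as.integer(window), upstream = as.integer(upstream),
                 evalue_primary = evalue_primary,
                 evalue_sensitive = evalue_sensitive, ir = ir,
                 cluster_gap = as.integer(cluster_gap),
                 direction_mode = direction_mode, genomes_dir = genomes_dir,
                 query = query, panel_fasta = panel_fasta,
                 panel_tsv = panel_tsv, lineage = lineage,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_flat <- function(config) {
  c(window = config$window, upstream = config$upstream,
    evalue_primary = format(config$evalue_primary, scientific = TRUE),
    evalue_sensitive = format(config$evalue_sensitive, scientific = TRUE),
    ir_min_arm = config$ir$min_arm, ir_max_gap = config$ir$max_gap,
    ir_max_mismatch = config$ir$max_mismatch,
    ir_length_semantics = config$ir$length_semantics,
    cluster_gap = config$cluster_gap, direction_mode = config$direction_mode,
    genomes_dir = config$genomes_dir %||% "", query = config$query %||% "",
    panel_fasta = config$panel_fasta %||% "",
    panel_tsv = config$panel_tsv %||% "", lineage = config$lineage %||% "",
    out_dir = config$out_dir %||% "", seed = config$seed)
}

#' Write / read a pipeline configuration as a flat key=value file
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `write_config`: `path` invisibly; `read_config`: a
#'   `pipeline_config` (round-trips [write_config()]).
#' @export
write_config <- function(config, path) {
  fl <- config_flat(config)
  writeLines(paste0(names(fl), "=", fl), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(#|\\s*$)", lines)]
  eq <- regexpr("=", lines, fixed = TRUE)
  assert_that(all(eq > 0), "config: every line must be key=value")
  kv <- setNames(substring(lines, eq + 1L), substring(lines, 1L, eq - 1L))
  blank_null <- function(x) {
    x <- unname(x)
    if (is.na(x) || !nzchar(x)) NULL else x
  }
  pipeline_config(
    window = as.integer(kv[["window"]]),
    upstream = as.integer(kv[["upstream"]]),
    evalue_primary = as.numeric(kv[["evalue_primary"]]),
    evalue_sensitive = as.numeric(kv[["evalue_sensitive"]]),
    ir = ir_params(as.integer(kv[["ir_min_arm"]]),
                   as.integer(kv[["ir_max_gap"]]),
                   as.integer(kv[["ir_max_mismatch"]]),
                   kv[["ir_length_semantics"]]),
    cluster_gap = as.integer(kv[["cluster_gap"]]),
    direction_mode = kv[["direction_mode"]],
    genomes_dir = blank_null(kv["genomes_dir"]),
    query = blank_null(kv["query"]),
    panel_fasta = blank_null(kv["panel_fasta"]),
    panel_tsv = blank_null(kv["panel_tsv"]),
    lineage = blank_null(kv["lineage"]),
    out_dir = blank_null(kv["out_dir"]),
    seed = as.integer(kv[["seed"]]))
}

load_genome_dir <- function(dir) {
  assert_that(dir.exists(dir), paste0("no such genome directory: ", dir))
  fna <- sort(list.files(dir, pattern = "\\.(fna|fa|fasta)$", full.names = TRUE))
  gbk <- sort(list.files(dir, pattern = "\\.(gb|gbk|gbff)$", full.names = TRUE))
  genomes <- list()
  for (f in fna) {
    stem <- sub("\\.(fna|fa|fasta)$", "", f)
    gff <- paste0(stem, ".gff3")
    if (!file.exists(gff)) gff <- paste0(stem, ".gff")
    assert_that(file.exists(gff), paste0("no GFF3 companion for ", f))
    faa <- paste0(stem, ".faa")
    genomes[[length(genomes) + 1L]] <- read_genome(
      fasta_path = f, gff3_path = gff,
      protein_fasta_path = if (file.exists(faa)) faa else NULL)
  }
  for (f in gbk) {
    genomes[[length(genomes) + 1L]] <- read_genome(genbank_path = f)
  }
  if (!length(genomes)) message("no genomes found in ", dir, "; reports will be empty")
  as_genome_list(genomes)
}

#' Run the full neighbourhood scan
#'
#' Executes homology search (regulator and marker panel), locus
#' anchoring, strand-aware window scans in both directions, system
#' grouping, association classification, inverted-repeat scanning of
#' upstream regions, and all summary tables; writes every table as TSV
#' plus a run manifest (JSON with the effective configuration, its hash,
#' package version, and headline counts).  Each filter stage is logged
#' with before/after counts.  Reruns with the same inputs and
#' configuration are byte-identical.
#'
#' @param config a [pipeline_config()] with input paths set; inputs are
#'   checked before any computation.
#' @param genomes optionally, pre-loaded genomes (bypasses
#'   `genomes_dir`).
#' @return invisibly, a list with all tables (`loci`, `records`,
#'   `instances`, `cooccurrence`, `class_distribution`, `taxonomy`,
#'   `replicon`, `ir`, `summary`, `manifest`, ...).
#' @export
run_scan <- function(config, genomes = NULL) {
  for (p in c("query", "panel_fasta", "panel_tsv")) {
    assert_that(!is.null(config[[p]]) && file.exists(config[[p]]),
                paste0("missing input: ", p, " (", config[[p]] %||% "unset", ")"),
                class = "brxrscan_input_error")
  }
  if (is.null(genomes)) {
    assert_that(!is.null(config$genomes_dir),
                "missing input: genomes_dir", class = "brxrscan_input_error")
    genomes <- load_genome_dir(config$genomes_dir)
  } else {
    genomes <- as_genome_list(genomes)
  }
  panel <- read_panel(config$panel_fasta, config$panel_tsv)
  lineage <- if (!is.null(config$lineage) && file.exists(config$lineage)) {
    read.delim(config$lineage, stringsAsFactors = FALSE)
  } else NULL
  scheme <- scoring_scheme()
  thr <- search_thresholds(config$evalue_primary)

  message(sprintf("searching regulator query against %d genome(s)", length(genomes)))
  reg_hits <- search(config$query, genomes, scheme, thr)
  message(sprintf("regulator hits passing E < %g: %d", config$evalue_primary,
                  nrow(reg_hits)))
  marker_queries <- setNames(panel$protein_seq, panel$marker_id)
  marker_hits <- search(marker_queries, genomes, scheme, thr)
  message(sprintf("marker hits passing E < %g: %d", config$evalue_primary,
                  nrow(marker_hits)))

  loci <- anchor_regulators(reg_hits, genomes, upstream_len = config$upstream)
  message(sprintf("anchored loci: %d (from %d hits)", nrow(loci), nrow(reg_hits)))
  assoc <- associate_loci(loci, marker_hits, genomes, panel,
                          W = config$window, cluster_gap = config$cluster_gap,
                          direction_mode = config$direction_mode)
  message(sprintf("associated loci (any direction): %d of %d",
                  sum(assoc$records$verdict != "none"), nrow(loci)))
  co <- cooccurrence(assoc$instances)
  cd <- class_distribution(assoc$instances)
  tax <- taxonomy_summary(loci, lineage)
  repl <- replicon_summary(loci)
  irs <- scan_upstream_all(loci, config$ir)
  message(sprintf("inverted repeats: %d in %d of %d loci",
                  irs$summary$n_ir, irs$summary$n_loci_with_ir, nrow(loci)))
  headline <- summarize(loci, assoc$records, assoc$instances)
  headline$n_ir <- irs$summary$n_ir
  headline$n_loci_with_ir <- irs$summary$n_loci_with_ir

  manifest <- list(
    package = "brxrscan",
    version = as.character(utils::packageVersion("brxrscan")),
    config = as.list(config_flat(config)),
    # the hash identifies the analysis, not where it is written
    config_hash = hash_string(paste(
      config_flat(config)[setdiff(names(config_flat(config)), "out_dir")],
      collapse = "\n")),
    n_genomes = length(genomes),
    counts = headline)

  out <- list(loci = loci, records = assoc$records,
              instances = assoc$instances, cooccurrence = co,
              class_distribution = cd, taxonomy = tax, replicon = repl,
              ir = irs$repeats, summary = headline, manifest = manifest,
              regulator_hits = reg_hits, marker_hits = marker_hits)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) write.table(d, file.path(config$out_dir, f),
                                     sep = "\t", quote = FALSE, row.names = FALSE)
    wt(loci, "loci.tsv")
    wt(assoc$records, "association.tsv")
    wt(assoc$instances, "instances.tsv")
    wt(co, "cooccurrence.tsv")
    wt(cd, "class_distribution.tsv")
    wt(tax, "taxonomy.tsv")
    wt(repl, "replicon.tsv")
    write_ir_tsv(irs$repeats, file.path(config$out_dir, "inverted_repeats.tsv"))
    write_hits(reg_hits, file.path(config$out_dir, "regulator_hits.tsv"))
    write_hits(marker_hits, file.path(config$out_dir, "marker_hits.tsv"))
    wt(data.frame(key = names(unlist(headline)), value = unlist(headline)),
       "summary.tsv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

hash_string <- function(s) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(s, tf)
  unname(tools::md5sum(tf))
}

#' Headline summary of a scan
#'
#' Every number reported here is recomputable from the detailed tables
#' (loci, association records, instances); nothing exists only in the
#' summary.
#'
#' @param loci loci table.
#' @param records association records.
#' @param instances instance table.
#' @return named list of counts and 2-dp percentages.
#' @export
summarize <- function(loci, records, instances) {
  n <- nrow(records)
  nd <- sum(records$verdict %in% c("downstream_only", "both"))
  nu <- sum(records$verdict %in% c("upstream_only", "both"))
  nb <- sum(records$verdict == "both")
  na_ <- sum(records$verdict != "none")
  ins_d <- instances[instances$direction == "downstream", , drop = FALSE]
  list(
    n_homologues = nrow(loci),
    n_genomes = length(unique(loci$genome_id)),
    n_multi_homologue_genomes = sum(table(loci$genome_id) > 1),
    n_assoc_downstream = nd, n_assoc_upstream = nu, n_assoc_both = nb,
    n_assoc_any = na_,
    pct_assoc_downstream = percent2(nd, n),
    pct_assoc_any = percent2(na_, n),
    n_instances_downstream = nrow(ins_d),
    n_instances_total = nrow(instances),
    n_marker_hits_downstream = sum(ins_d$n_markers),
    n_marker_hits_total = sum(instances$n_markers))
}

#' Batch dissociation-constant estimation from an intensity table
#'
#' @param input_tsv TSV with columns `probe_id`, `conc_nM`, `replicate`,
#'   `I_T`, `I_C`.
#' @param output_tsv optional path for the estimates table.
#' @param model,fix_ymax,average_replicates passed to [fit_kd()].
#' @return data frame with one row per probe: `probe_id`, `kd_nM`,
#'   `kd_stderr_nM`, `ymax`, `hill_n`, `model`, `n_points`, `converged`,
#'   `status`.
#' @export
emsa_fit_cmd <- function(input_tsv, output_tsv = NULL,
                         model = "hyperbolic", fix_ymax = NULL,
                         average_replicates = FALSE) {
  curves <- read_emsa_tsv(input_tsv)
  rows <- lapply(names(curves), function(pid) {
    est <- fit_kd(curves[[pid]], model = model, fix_ymax = fix_ymax,
                  average_replicates = average_replicates)
    data.frame(probe_id = pid, kd_nM = est$kd, kd_stderr_nM = est$kd_stderr,
               ymax = est$ymax, hill_n = est$hill_n, model = est$model,
               n_points = est$n_points, converged = est$converged,
               status = est$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(output_tsv)) {
    write.table(out, output_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
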
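#' Specification for one synthetic annotated genome
#'
#' Describes a genome to be generated: replicon backbones, regulator
#' placements at a controlled protein identity to a source sequence,
#' defence-system markers planted at controlled edge gaps / directions /
#' strands, non-homologous decoy genes, and upstream inverted repeats of
#' controlled geometry.  The same spec and seed always produce
#' byte-identical output; a single root seed fans out to per-element
#' child seeds so that editing one element does not perturb the others.
#'
#' @param assembly_id assembly identifier.
#' @param seed integer root seed.
#' @param replicons data frame with columns `length`, `replicon_type`
#'   (and optionally `replicon_id`, `topology`).
#' @param regulator list: `protein` (source amino-acid string starting
#'   with M, or `NULL` to draw a random 300-mer), `identity` (target
#'   alignment identity of each planted copy, in (0, 1]), `placements`
#'   (data frame `replicon` (index), `pos` (0-based start), `strand`).
#' @param planted_systems list of lists: `system_name`, `markers`
#'   (panel marker ids), `anchor` (regulator placement index),
#'   `direction` (`downstream`/`upstream` relative to the anchor's
#'   strand), `edge_gap` (bp from anchor edge to the nearest marker
#'   edge), `strand`, `identity` (marker identity target, default 0.7),
#'   `spacing` (bp between consecutive markers, default 200).
#' @param decoys list: `count`, proteins drawn by shuffling the
#'   composition of random panel entries (no homology).
#' @param planted_irs list of lists: `anchor` (placement index),
#'   `arm_len`, `spacer_len`, `mismatches`, `offset` (bp from the second
#'   arm's end to the gene start, within the upstream window).
#' @param gc background GC fraction (default 0.5).
#' @return object of class `genome_spec`.
#' @export
genome_spec <- function(assembly_id, seed,
                        replicons = data.frame(length = 100000L,
                                               replicon_type = "chromosome"),
                        regulator = list(protein = NULL, identity = 0.6,
                                         placements = data.frame(
                                           replicon = 1L, pos = 5000L,
                                           strand = "+")),
                        planted_systems = list(),
                        decoys = list(count = 0L),
                        planted_irs = list(),
                        gc = 0.5) {
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  if (is.null(replicons$replicon_id)) {
    replicons$replicon_id <- sprintf("%s_rep%d", assembly_id,
                                     seq_len(nrow(replicons)))
  }
  if (is.null(replicons$topology)) replicons$topology <- "linear"
  regulator$identity <- regulator$identity %||% 0.6
  assert_that(regulator$identity > 0 && regulator$identity <= 1,
              "regulator identity target must be in (0, 1]")
  structure(list(assembly_id = assembly_id, seed = as.integer(seed),
                 replicons = replicons, regulator = regulator,
                 planted_systems = planted_systems, decoys = decoys,
                 planted_irs = planted_irs, gc = gc),
            class = "genome_spec")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
          "P","S","T","W","Y","V")

#' Random protein sequence (first residue M)
#' @param len length in residues.
#' @param seed integer seed.
#' @return amino-acid string.
#' @export
random_protein <- function(len, seed) {
  with_seed(seed, paste0("M", paste(sample(AA20, len - 1L, replace = TRUE),
                                    collapse = "")))
}

# substitute residues uniformly (positions 2..L) until the target identity
# is reached; position 1 (M) is preserved so the ORF keeps its start codon
mutate_protein <- function(prot, identity, seed) {
  v <- strsplit(prot, "")[[1]]
  n_sub <- round((1 - identity) * length(v))
  if (n_sub == 0) return(prot)
  assert_that(n_sub <= length(v) - 1L, "identity target too low for length")
  with_seed(seed, {
    pos <- sample(2:length(v), n_sub)
    for (p in pos) v[p] <- sample(setdiff(AA20, v[p]), 1L)
  })
  paste(v, collapse = "")
}

.codon_cache <- new.env(parent = emptyenv())

codon_choices <- function() {
  if (is.null(.codon_cache$tab)) {
    gc <- Biostrings::getGeneticCode("11")
    .codon_cache$tab <- split(names(gc), unname(gc))
  }
  .codon_cache$tab
}

# uniform synonymous codon choice under the bacterial code; TAA stop
back_translate <- function(prot, seed) {
  choices <- codon_choices()
  v <- strsplit(prot, "")[[1]]
  with_seed(seed, {
    codons <- vapply(v, function(a) {
      cs <- choices[[a]]
      assert_that(!is.null(cs), paste0("cannot back-translate residue: ", a))
      if (length(cs) == 1L) cs else sample(cs, 1L)
    }, "")
    paste0(paste(codons, collapse = ""), "TAA")
  })
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

NON_COMP <- c(A = "A", C = "C", G = "G", T = "T")  # a base never pairs with itself

#' Generate a synthetic annotated genome with a truth table
#'
#' Background DNA is i.i.d. at the spec's GC; planted genes are written
#' as ORFs (ATG start, no internal stop, TAA stop) back-translated with
#' uniform synonymous codon choice from proteins mutated to the target
#' identity.  Planted inverted repeats are flank-guarded (the outward
#' base pairs are forced non-complementary) so that a scan whose mismatch
#' budget equals the planted mismatch count recovers exactly the planted
#' geometry.  Identical seeds give byte-identical output.
#'
#' @param spec a [genome_spec()].
#' @param panel a [marker_panel()] supplying marker and decoy source
#'   proteins (required when systems or decoys are planted).
#' @return list with `genome` (a [genome()]) and `truth` (plan-level
#'   coordinates of every planted element; see [truth_associations()]).
#' @export
generate_genome <- function(spec, panel = NULL) {
  reps <- spec$replicons
  seqs <- lapply(seq_len(nrow(reps)), function(i) {
    strsplit(with_seed(child_seed(spec$seed, paste0("bg", i)),
                       random_dna(reps$length[i], spec$gc)), "")[[1]]
  })
  claimed <- lapply(seq_len(nrow(reps)), function(i) {
    empty_df(start = "integer", end = "integer", what = "character")
  })
  claim <- function(ri, start, end, what) {
    assert_that(start >= 0 && end <= reps$length[ri],
                sprintf("infeasible placement for %s: [%d,%d) outside replicon %s",
                        what, start, end, reps$replicon_id[ri]))
    cl <- claimed[[ri]]
    overlap <- cl$start < end & start < cl$end
    assert_that(!any(overlap),
                sprintf("infeasible placement for %s: overlaps %s",
                        what, paste(cl$what[overlap], collapse = ", ")))
    claimed[[ri]] <<- rbind(cl, data.frame(start = start, end = end, what = what,
                                           stringsAsFactors = FALSE))
  }
  put <- function(ri, start, nt) {
    v <- strsplit(nt, "")[[1]]
    seqs[[ri]][(start + 1L):(start + length(v))] <<- v
  }
  feats <- list()
  add_feature <- function(fid, ri, start, end, strand, product, prot) {
    feats[[length(feats) + 1L]] <<- data.frame(
      feature_id = fid, replicon_id = reps$replicon_id[ri],
      start = start, end = end, strand = strand, product = product,
      protein_seq = prot, stringsAsFactors = FALSE)
  }

  # --- regulator placements ---
  src <- spec$regulator$protein %||%
    random_protein(300L, child_seed(spec$seed, "regsrc"))
  pl <- spec$regulator$placements
  reg_truth <- list()
  for (i in seq_len(nrow(pl))) {
    prot <- mutate_protein(src, spec$regulator$identity,
                           child_seed(spec$seed, paste0("regmut", i)))
    orf <- back_translate(prot, child_seed(spec$seed, paste0("regbt", i)))
    ri <- pl$replicon[i]
    start <- pl$pos[i]; end <- start + nchar(orf)
    fid <- sprintf("reg%d", i)
    claim(ri, start, end, fid)
    put(ri, start, if (pl$strand[i] == "-") reverse_complement(orf) else orf)
    add_feature(fid, ri, start, end, pl$strand[i], "planted regulator homologue", prot)
    reg_truth[[i]] <- data.frame(
      feature_id = fid, replicon_id = reps$replicon_id[ri],
      start = start, end = end, strand = pl$strand[i],
      replicon_type = reps$replicon_type[ri],
      target_identity = spec$regulator$identity, stringsAsFactors = FALSE)
  }
  reg_truth <- do.call(rbind, reg_truth)

  # --- planted defence systems ---
  sys_truth <- list(); marker_truth <- list()
  for (s in seq_along(spec$planted_systems)) {
    ps <- spec$planted_systems[[s]]
    assert_that(!is.null(panel), "generate_genome: panel required to plant systems")
    anchor <- reg_truth[ps$anchor, , drop = FALSE]
    ri <- match(anchor$replicon_id, reps$replicon_id)
    identity <- ps$identity %||% 0.7
    spacing <- ps$spacing %||% 200L
    # rightward on the replicon iff (anchor +, downstream) or (anchor -, upstream)
    rightward <- xor(anchor$strand == "-", ps$direction == "downstream")
    orfs <- lapply(seq_along(ps$markers), function(m) {
      j <- match(ps$markers[m], panel$marker_id)
      assert_that(!is.na(j), paste0("unknown panel marker: ", ps$markers[m]))
      prot <- mutate_protein(panel$protein_seq[j], identity,
                             child_seed(spec$seed, sprintf("sys%d_m%d_mut", s, m)))
      list(prot = prot,
           orf = back_translate(prot, child_seed(spec$seed, sprintf("sys%d_m%d_bt", s, m))),
           marker_id = ps$markers[m],
           system_class = panel$system_class[j])
    })
    cursor <- if (rightward) anchor$end + ps$edge_gap else anchor$start - ps$edge_gap
    for (m in seq_along(orfs)) {
      o <- orfs[[m]]
      len <- nchar(o$orf)
      if (rightward) { start <- cursor; end <- cursor + len; cursor <- end + spacing }
      else { end <- cursor; start <- cursor - len; cursor <- start - spacing }
      fid <- sprintf("sys%d_m%d", s, m)
      claim(ri, start, end, fid)
      put(ri, start, if (ps$strand == "-") reverse_complement(o$orf) else o$orf)
      add_feature(fid, ri, start, end, ps$strand,
                  paste0("planted marker ", o$marker_id), o$prot)
      gap_m <- if (rightward) start - anchor$end else anchor$start - end
      marker_truth[[length(marker_truth) + 1L]] <- data.frame(
        feature_id = fid, system_idx = s, system_name = ps$system_name,
        system_class = o$system_class, source_marker = o$marker_id,
        replicon_id = reps$replicon_id[ri], start = start, end = end,
        strand = ps$strand, anchor_feature = anchor$feature_id,
        planted_direction = ps$direction, edge_gap = gap_m,
        stringsAsFactors = FALSE)
    }
    sys_truth[[s]] <- data.frame(
      system_idx = s, system_name = ps$system_name,
      system_class = orfs[[1]]$system_class,
      anchor_feature = anchor$feature_id, direction = ps$direction,
      edge_gap = ps$edge_gap, n_markers = length(orfs),
      strand = ps$strand, stringsAsFactors = FALSE)
  }

  # --- decoys (shuffled panel composition: same residues, no homology) ---
  decoy_truth <- list()
  n_dec <- spec$decoys$count %||% 0L
  if (n_dec > 0) {
    assert_that(!is.null(panel), "generate_genome: panel required to draw decoys")
    with_seed(child_seed(spec$seed, "decoys"), {
      for (d in seq_len(n_dec)) {
        srcp <- panel$protein_seq[sample(nrow(panel), 1L)]
        v <- strsplit(srcp, "")[[1]]
        prot <- paste0("M", paste(sample(v[-1]), collapse = ""))
        orf <- paste0(paste(vapply(strsplit(prot, "")[[1]], function(a) {
          cs <- codon_choices()[[a]]
          if (length(cs) == 1L) cs else sample(cs, 1L)
        }, ""), collapse = ""), "TAA")
        len <- nchar(orf)
        placed <- FALSE
        for (try in 1:500) {
          ri <- sample(nrow(reps), 1L)
          if (reps$length[ri] < len + 200L) next
          start <- sample.int(reps$length[ri] - len - 100L, 1L) + 50L
          cl <- claimed[[ri]]
          if (any(cl$start < start + len + 50L & start - 50L < cl$end)) next
          fid <- sprintf("decoy%d", d)
          claim(ri, start, start + len, fid)
          strand <- sample(c("+", "-"), 1L)
          put(ri, start, if (strand == "-") reverse_complement(orf) else orf)
          add_feature(fid, ri, start, start + len, strand, "decoy", prot)
          decoy_truth[[d]] <- data.frame(
            feature_id = fid, replicon_id = reps$replicon_id[ri],
            start = start, end = start + len, stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        assert_that(placed, sprintf("infeasible placement for decoy%d", d))
      }
    })
  }

  # --- planted upstream inverted repeats ---
  ir_truth <- list()
  for (q in seq_along(spec$planted_irs)) {
    pi <- spec$planted_irs[[q]]
    anchor <- reg_truth[pi$anchor, , drop = FALSE]
    ri <- match(anchor$replicon_id, reps$replicon_id)
    k <- pi$arm_len; g <- pi$spacer_len; mm <- pi$mismatches
    off <- pi$offset %||% 20L
    foot <- 2L * k + g
    ir <- with_seed(child_seed(spec$seed, paste0("ir", q)), {
      arm1 <- random_dna(k, 0.5)
      spacer <- if (g > 0) random_dna(g, 0.5) else ""
      arm2v <- strsplit(reverse_complement(arm1), "")[[1]]
      if (mm > 0) {
        pos <- sample(k, mm)
        for (p in pos) arm2v[p] <- sample(setdiff(c("A", "C", "G", "T"), arm2v[p]), 1L)
      }
      paste0(arm1, spacer, paste(arm2v, collapse = ""))
    })
    if (anchor$strand == "+") {
      start <- anchor$start - off - foot          # [start, start+foot)
      claim(ri, start, start + foot, sprintf("ir%d", q))
      put(ri, start, ir)
      # flank guards: force the outward base pairs to mismatch so the
      # maximal repeat cannot extend beyond the planted arms
      for (ext in 1:3) {
        lo <- start - ext; hi <- start + foot + ext - 1L
        if (lo >= 0 && hi < reps$length[ri]) {
          seqs[[ri]][hi + 1L] <- NON_COMP[[seqs[[ri]][lo + 1L]]]
        }
      }
    } else {
      start <- anchor$end + off                   # revcomp orientation
      claim(ri, start, start + foot, sprintf("ir%d", q))
      put(ri, start, reverse_complement(ir))
      for (ext in 1:3) {
        lo <- start - ext; hi <- start + foot + ext - 1L
        if (lo >= 0 && hi < reps$length[ri]) {
          seqs[[ri]][hi + 1L] <- NON_COMP[[seqs[[ri]][lo + 1L]]]
        }
      }
    }
    ir_truth[[q]] <- data.frame(
      anchor_feature = anchor$feature_id, arm_len = k, spacer_len = g,
      mismatches = mm, offset = off,
      arm1_seq = substr(ir, 1, k),
      arm2_seq = substr(ir, k + g + 1, foot), stringsAsFactors = FALSE)
  }

  g <- genome(spec$assembly_id,
              data.frame(replicon_id = reps$replicon_id,
                         sequence = vapply(seqs, paste, "", collapse = ""),
                         replicon_type = reps$replicon_type,
                         topology = reps$topology, stringsAsFactors = FALSE),
              if (length(feats)) do.call(rbind, feats) else NULL)
  truth <- list(
    assembly_id = spec$assembly_id, seed = spec$seed,
    regulators = reg_truth,
    systems = if (length(sys_truth)) do.call(rbind, sys_truth) else NULL,
    markers = if (length(marker_truth)) do.call(rbind, marker_truth) else NULL,
    decoys = if (length(decoy_truth)) do.call(rbind, decoy_truth) else NULL,
    irs = if (length(ir_truth)) do.call(rbind, ir_truth) else NULL)
  list(genome = g, truth = truth)
}

#' Expected association results from plan coordinates
#'
#' Computes, directly from the truth-table coordinates (never from the
#' generated sequences), the association verdict every regulator locus
#' should receive and the system instances every window scan should
#' recover: per-marker strand-aware edge gaps, the `<= W` window filter,
#' and single-linkage grouping by system name within `cluster_gap`.  This
#' is the independent oracle the pipeline is checked against.
#'
#' @param truths list of truth tables from [generate_genome()].
#' @param W window size (default 50000).
#' @param cluster_gap grouping gap (default 20000).
#' @return list with `records` (locus_id, verdict) and `instances`
#'   (locus_id, direction, system_name, system_class, n_markers,
#'   marker_feature_ids, distance).
#' @export
truth_associations <- function(truths, W = 50000L, cluster_gap = 20000L) {
  recs <- list(); insts <- list()
  for (tr in truths) {
    mk <- tr$markers
    for (i in seq_len(nrow(tr$regulators))) {
      rg <- tr$regulators[i, , drop = FALSE]
      locus_id <- sprintf("%s:%s", tr$assembly_id, rg$feature_id)
      found <- list(downstream = NULL, upstream = NULL)
      if (!is.null(mk)) {
        same <- mk[mk$replicon_id == rg$replicon_id, , drop = FALSE]
        if (nrow(same)) {
          right <- same$start >= rg$end
          left <- same$end <= rg$start
          gap <- ifelse(right, same$start - rg$end,
                        ifelse(left, rg$start - same$end, 0L))
          dir <- ifelse(right, if (rg$strand == "+") "downstream" else "upstream",
                        ifelse(left, if (rg$strand == "+") "upstream" else "downstream",
                               "overlapping"))
          for (dd in c("downstream", "upstream")) {
            inw <- same[gap <= W & (dir == dd | dir == "overlapping"), , drop = FALSE]
            inw$gap <- gap[gap <= W & (dir == dd | dir == "overlapping")]
            if (!nrow(inw)) next
            for (sn in sort(unique(inw$system_name))) {
              h <- inw[inw$system_name == sn, , drop = FALSE]
              h <- h[order(h$start, h$end), , drop = FALSE]
              cl <- cumsum(c(1L, as.integer(
                h$start[-1] - cummax(h$end)[-nrow(h)] > cluster_gap)))
              for (kk in unique(cl)) {
                hk <- h[cl == kk, , drop = FALSE]
                insts[[length(insts) + 1L]] <- data.frame(
                  locus_id = locus_id, direction = dd, system_name = sn,
                  system_class = hk$system_class[1], n_markers = nrow(hk),
                  marker_feature_ids = paste(hk$feature_id, collapse = ","),
                  distance = min(hk$gap), stringsAsFactors = FALSE)
                found[[dd]] <- c(found[[dd]], sn)
              }
            }
          }
        }
      }
      verdict <- if (!is.null(found$downstream) && !is.null(found$upstream)) "both"
      else if (!is.null(found$downstream)) "downstream_only"
      else if (!is.null(found$upstream)) "upstream_only"
      else "none"
      recs[[length(recs) + 1L]] <- data.frame(
        locus_id = locus_id, verdict = verdict,
        replicon_type = rg$replicon_type, genome_id = tr$assembly_id,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  instances <- if (length(insts)) do.call(rbind, insts) else
    empty_df(locus_id = "character", direction = "character",
             system_name = "character", system_class = "character",
             n_markers = "integer", marker_feature_ids = "character",
             distance = "integer")
  rownames(records) <- NULL; rownames(instances) <- NULL
  list(records = records, instances = instances)
}

#' Write a truth table as JSON
#' @param truth truth list from [generate_genome()] (or a list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Generate a marker panel of mutually dissimilar random proteins
#'
#' Stand-in for a curated defence-system reference panel: `n_systems`
#' system names, `markers_per_system` markers each, random proteins whose
#' pairwise local-alignment identities (matches over the shorter
#' sequence) are checked to stay below `identity_ceiling`.
#'
#' @param n_systems number of defence-system names.
#' @param markers_per_system markers per system.
#' @param seed integer seed.
#' @param len protein length in residues (default 150).
#' @param classes recycled vector of system classes (defaults to a
#'   representative set of defence-system classes).
#' @param identity_ceiling maximum tolerated pairwise identity (checked;
#'   default 0.35).
#' @return a [marker_panel()].
#' @export
generate_panel <- function(n_systems, markers_per_system, seed, len = 150L,
                           classes = c("BREX", "Type I RM", "Type III RM",
                                       "Type IV restriction", "CRISPR-Cas",
                                       "CBASS", "TA type II", "Wadjet",
                                       "Zorya", "Thoeris"),
                           identity_ceiling = 0.35) {
  classes <- rep_len(classes, n_systems)
  entries <- list()
  for (s in seq_len(n_systems)) {
    for (m in seq_len(markers_per_system)) {
      entries[[length(entries) + 1L]] <- data.frame(
        marker_id = sprintf("sys%02d_marker%d", s, m),
        protein_seq = random_protein(len, child_seed(seed, sprintf("panel%d_%d", s, m))),
        system_name = sprintf("system%02d", s),
        system_class = classes[s],
        subtype = sprintf("subtype%d", m),
        stringsAsFactors = FALSE)
    }
  }
  panel <- marker_panel(do.call(rbind, entries))
  scheme <- scoring_scheme()
  n <- nrow(panel)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- local_align(panel$protein_seq[i], panel$protein_seq[j], scheme)
      pid <- a$n_match / min(nchar(panel$protein_seq[i]),
                             nchar(panel$protein_seq[j]))
      assert_that(pid < identity_ceiling, sprintf(
        "generated panel entries %s and %s exceed identity ceiling (%.2f)",
        panel$marker_id[i], panel$marker_id[j], pid))
    }
  }
  panel
}

#' Generate a synthetic EMSA binding curve
#'
#' Fractional saturations are drawn from the single-site isotherm
#' `ymax * c / (kd + c)` plus Gaussian noise of standard deviation
#' `sigma`, then converted to unbound-band intensities with `I_C = 1`
#' (`I_T = 1 - Y`; noisy points may exceed the plateau and are not
#' clipped).
#'
#' @param kd generating dissociation constant (nM).
#' @param ymax plateau (default 1).
#' @param concs protein concentrations (nM).
#' @param sigma Gaussian noise sd on Y (0 for noiseless).
#' @param replicates replicates per concentration.
#' @param seed integer seed.
#' @param probe_id probe identifier.
#' @return a [binding_curve()].
#' @export
generate_binding_data <- function(kd, ymax = 1, concs, sigma = 0.03,
                                  replicates = 3L, seed = 1L,
                                  probe_id = "synthetic") {
  conc <- rep(concs, each = replicates)
  replicate <- rep(seq_len(replicates), times = length(concs))
  mu <- ymax * conc / (kd + conc)
  Y <- with_seed(seed, mu + if (sigma > 0) rnorm(length(mu), 0, sigma) else 0)
  binding_curve(data.frame(conc = conc, I_T = 1 - Y, I_C = 1,
                           replicate = replicate),
                probe_id = probe_id)
}

#' Generate a lineage table from a stated allocation
#'
#' Assigns genomes to taxa according to an allocation table (columns are
#' rank names plus `n`, the number of genomes for that row), in a seeded
#' random order; genomes beyond the allocation are omitted from the
#' table, which downstream summaries bin as "unclassified".
#'
#' @param genome_ids assembly ids to allocate.
#' @param allocation data frame of rank columns plus `n`; `sum(n)` must
#'   not exceed `length(genome_ids)`.  `NULL` or empty gives an empty
#'   lineage table (all unclassified).
#' @param seed integer seed for the assignment order.
#' @return data frame `assembly_id` + rank columns.
#' @export
generate_lineage <- function(genome_ids, allocation = NULL, seed = 1L) {
  if (is.null(allocation) || !nrow(allocation)) {
    return(data.frame(assembly_id = character(0), stringsAsFactors = FALSE))
  }
  assert_that(sum(allocation$n) <= length(genome_ids),
              "allocation exceeds the number of genomes")
  ids <- with_seed(seed, sample(genome_ids))
  ranks <- setdiff(names(allocation), "n")
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(allocation))) {
    take <- ids[(k + 1L):(k + allocation$n[i])]
    k <- k + allocation$n[i]
    r <- data.frame(assembly_id = take, stringsAsFactors = FALSE)
    for (rk in ranks) r[[rk]] <- allocation[[rk]][i]
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
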
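#' Anchor regulator loci from homology hits
#'
#' Turns each passing regulator hit into a locus record: one locus per hit
#' (a genome may therefore carry several), with the replicon type copied
#' from the replicon and up to `upstream_len` bases of 5' sequence
#' attached via [extract_upstream()].
#'
#' @param hits hit data frame from [search()] (regulator query).
#' @param genomes list of `genome` objects (or a single `genome`).
#' @param upstream_len bases of upstream sequence to attach (default 200).
#' @param circular_wrap passed to [extract_upstream()].
#' @return data frame of loci: `locus_id`, `genome_id`, `feature_id`,
#'   `replicon_id`, `start`, `end`, `strand`, `replicon_type`, `evalue`,
#'   `identity_frac`, `upstream_seq`.
#' @export
anchor_regulators <- function(hits, genomes, upstream_len = 200L,
                              circular_wrap = FALSE) {
  genomes <- as_genome_list(genomes)
  if (!nrow(hits)) return(empty_loci())
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    g <- genomes[[hits$genome_id[i]]]
    assert_that(!is.null(g), paste0("hit references unknown genome: ",
                                    hits$genome_id[i]))
    f <- get_feature(g, hits$subject_feature_id[i])
    ri <- match(f$replicon_id, g$replicons$replicon_id)
    data.frame(
      locus_id = sprintf("%s:%s", g$assembly_id, f$feature_id),
      genome_id = g$assembly_id,
      feature_id = f$feature_id,
      replicon_id = f$replicon_id,
      start = f$start, end = f$end, strand = f$strand,
      replicon_type = g$replicons$replicon_type[ri],
      evalue = hits$evalue[i],
      identity_frac = hits$identity_frac[i],
      upstream_seq = extract_upstream(g, f, upstream_len,
                                      circular_wrap = circular_wrap),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$genome_id, out$replicon_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_loci <- function() {
  empty_df(locus_id = "character", genome_id = "character",
           feature_id = "character", replicon_id = "character",
           start = "integer", end = "integer", strand = "character",
           replicon_type = "character", evalue = "double",
           identity_frac = "double", upstream_seq = "character")
}

as_genome_list <- function(genomes) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  setNames(genomes, vapply(genomes, `[[`, "", "assembly_id"))
}

#' Scan a fixed window around a regulator locus for marker hits
#'
#' Returns the marker hits whose subject feature lies on the locus
#' replicon, in the requested direction, with an edge-gap distance of at
#' most `W` bases.  The regulator's own feature is excluded.  Direction is
#' strand-aware by default (downstream = 3' of the regulator on its coding
#' strand); `direction_mode = "coordinate"` instead treats higher
#' coordinates as downstream.  Features overlapping the regulator are
#' within any window and are returned for either direction with
#' distance 0.
#'
#' @param locus one row of the loci table from [anchor_regulators()].
#' @param marker_hits marker hit data frame from [search()].
#' @param genomes list of `genome` objects.
#' @param W window size in bp (default 50000).
#' @param direction `"downstream"` or `"upstream"`.
#' @param direction_mode `"strand"` (default) or `"coordinate"`.
#' @return the qualifying rows of `marker_hits` with added `distance` and
#'   `direction` columns.
#' @export
scan_window <- function(locus, marker_hits, genomes, W = 50000L,
                        direction = c("downstream", "upstream"),
                        direction_mode = c("strand", "coordinate")) {
  direction <- match.arg(direction)
  direction_mode <- match.arg(direction_mode)
  assert_that(W > 0, "scan_window: W must be > 0")
  genomes <- as_genome_list(genomes)
  if (!nrow(marker_hits)) return(cbind(marker_hits,
                                       distance = integer(0),
                                       direction = character(0)))
  g <- genomes[[locus$genome_id]]
  anchor <- get_feature(g, locus$feature_id)
  if (direction_mode == "coordinate") anchor$strand <- "+"
  cand <- marker_hits$genome_id == locus$genome_id &
    marker_hits$replicon_id == locus$replicon_id &
    marker_hits$subject_feature_id != locus$feature_id
  out <- marker_hits[cand, , drop = FALSE]
  if (!nrow(out)) return(cbind(out, distance = integer(0),
                               direction = character(0)))
  dd <- lapply(out$subject_feature_id, function(fid) {
    distance_between(anchor, get_feature(g, fid))
  })
  out$distance <- vapply(dd, function(x) x$distance, 0L)
  out$direction <- vapply(dd, function(x) x$direction, "")
  keep <- out$distance <= W &
    (out$direction == direction | out$direction == "overlapping")
  out <- out[keep, , drop = FALSE]
  out$direction[out$direction == "overlapping"] <- direction
  rownames(out) <- NULL
  out
}

#' Group marker hits in a window into defence-system instances
#'
#' Hits sharing a `system_name` whose features lie within `cluster_gap`
#' of one another (single-linkage on edge gaps along the replicon)
#' collapse into one system instance; a second cluster of the same system
#' beyond `cluster_gap` forms a new instance.  The instance subtype is
#' that of the lowest-E hit in the cluster.
#'
#' @param window_hits output of [scan_window()] for one locus/direction.
#' @param panel a [marker_panel()]; every hit's `query_id` must map to a
#'   panel entry.
#' @param genomes list of `genome` objects (for marker feature spans).
#' @param locus_id,direction identifiers stamped onto the instances.
#' @param cluster_gap maximum edge gap joining markers of one system
#'   instance (default 20000 bp).
#' @return data frame of instances: `instance_id`, `locus_id`,
#'   `direction`, `system_class`, `system_name`, `subtype`, `n_markers`,
#'   `marker_feature_ids`, `span_start`, `span_end`, `distance`.
#' @export
group_systems <- function(window_hits, panel, genomes, locus_id = NA_character_,
                          direction = NA_character_, cluster_gap = 20000L) {
  if (!nrow(window_hits)) return(empty_instances())
  genomes <- as_genome_list(genomes)
  idx <- match(window_hits$query_id, panel$marker_id)
  assert_that(!anyNA(idx), paste0(
    "marker hits lack a panel mapping: ",
    paste(unique(window_hits$query_id[is.na(idx)]), collapse = ", ")))
  wh <- window_hits
  wh$system_name <- panel$system_name[idx]
  wh$system_class <- panel$system_class[idx]
  wh$subtype <- panel$subtype[idx]
  fspan <- t(vapply(seq_len(nrow(wh)), function(i) {
    f <- get_feature(genomes[[wh$genome_id[i]]], wh$subject_feature_id[i])
    c(f$start, f$end)
  }, c(0L, 0L)))
  wh$f_start <- fspan[, 1]; wh$f_end <- fspan[, 2]
  out <- list()
  for (sn in sort(unique(wh$system_name))) {
    h <- wh[wh$system_name == sn, , drop = FALSE]
    h <- h[order(h$f_start, h$f_end), , drop = FALSE]
    cl <- cumsum(c(1L, as.integer(
      h$f_start[-1] - cummax(h$f_end)[-nrow(h)] > cluster_gap)))
    for (k in unique(cl)) {
      hk <- h[cl == k, , drop = FALSE]
      best <- which.min(hk$evalue)
      out[[length(out) + 1L]] <- data.frame(
        instance_id = sprintf("%s|%s|%s|%d", locus_id, direction, sn, k),
        locus_id = locus_id, direction = direction,
        system_class = hk$system_class[1], system_name = sn,
        subtype = hk$subtype[best],
        n_markers = nrow(hk),
        marker_feature_ids = paste(hk$subject_feature_id, collapse = ","),
        span_start = min(hk$f_start), span_end = max(hk$f_end),
        distance = min(hk$distance),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$span_start, res$system_name), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_instances <- function() {
  empty_df(instance_id = "character", locus_id = "character",
           direction = "character", system_class = "character",
           system_name = "character", subtype = "character",
           n_markers = "integer", marker_feature_ids = "character",
           span_start = "integer", span_end = "integer",
           distance = "integer")
}

#' Classify a locus by the emptiness of its two window scans
#'
#' @param locus one row of the loci table.
#' @param downstream_instances,upstream_instances instance data frames
#'   from [group_systems()].
#' @param W window size recorded on the association record.
#' @return one-row data frame: `locus_id`, `W`, `n_downstream`,
#'   `n_upstream`, `verdict` in `{downstream_only, upstream_only, both,
#'   none}`.
#' @export
classify <- function(locus, downstream_instances, upstream_instances,
                     W = 50000L) {
  nd <- nrow(downstream_instances)
  nu <- nrow(upstream_instances)
  verdict <- if (nd > 0 && nu > 0) "both"
  else if (nd > 0) "downstream_only"
  else if (nu > 0) "upstream_only"
  else "none"
  data.frame(locus_id = locus$locus_id, W = as.integer(W),
             n_downstream = nd, n_upstream = nu, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Associate every locus with defence systems in both windows
#'
#' Convenience driver running [scan_window()], [group_systems()] and
#' [classify()] over all loci.
#'
#' @inheritParams scan_window
#' @inheritParams group_systems
#' @param loci loci table from [anchor_regulators()].
#' @return list with `records` (one association row per locus) and
#'   `instances` (all system instances, both directions).
#' @export
associate_loci <- function(loci, marker_hits, genomes, panel, W = 50000L,
                           cluster_gap = 20000L,
                           direction_mode = c("strand", "coordinate")) {
  direction_mode <- match.arg(direction_mode)
  genomes <- as_genome_list(genomes)
  recs <- list(); insts <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, , drop = FALSE]
    down <- group_systems(
      scan_window(locus, marker_hits, genomes, W, "downstream", direction_mode),
      panel, genomes, locus$locus_id, "downstream", cluster_gap)
    up <- group_systems(
      scan_window(locus, marker_hits, genomes, W, "upstream", direction_mode),
      panel, genomes, locus$locus_id, "upstream", cluster_gap)
    recs[[i]] <- classify(locus, down, up, W)
    insts[[length(insts) + 1L]] <- rbind(down, up)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    empty_df(locus_id = "character", W = "integer", n_downstream = "integer",
             n_upstream = "integer", verdict = "character")
  instances <- if (length(insts)) do.call(rbind, insts) else empty_instances()
  rownames(records) <- NULL; rownames(instances) <- NULL
  list(records = records, instances = instances)
}

#' Co-occurrence table of defence-system classes per locus
#'
#' For each locus, the set of distinct system classes among its instances
#' in the chosen direction; the table maps each distinct set (sorted,
#' `+`-joined) to the number of loci carrying exactly that set.  Loci with
#' no instance in the direction do not appear, so the counts sum to the
#' number of associated loci.
#'
#' @param instances instance table from [associate_loci()].
#' @param direction `"downstream"` (default) or `"upstream"`.
#' @return data frame `classes`, `n_loci`, sorted by decreasing count.
#' @export
cooccurrence <- function(instances, direction = "downstream") {
  ins <- instances[instances$direction == direction, , drop = FALSE]
  if (!nrow(ins)) return(empty_df(classes = "character", n_loci = "integer"))
  sets <- vapply(split(ins$system_class, ins$locus_id), function(cl) {
    paste(sort(unique(cl)), collapse = "+")
  }, "")
  tab <- table(sets)
  out <- data.frame(classes = names(tab), n_loci = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_loci, out$classes), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distribution of defence-system classes among instances
#'
#' @param instances instance table.
#' @param direction direction to tally (default `"downstream"`).
#' @return data frame `system_class`, `count`, `percent` (2 dp, of all
#'   instances in the direction), sorted by decreasing count.
#' @export
class_distribution <- function(instances, direction = "downstream") {
  ins <- instances[instances$direction == direction, , drop = FALSE]
  if (!nrow(ins)) return(empty_df(system_class = "character",
                                  count = "integer", percent = "double"))
  tab <- table(ins$system_class)
  out <- data.frame(system_class = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- percent2(out$count, sum(out$count))
  out <- out[order(-out$count, out$system_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Taxonomic summary of regulator loci
#'
#' @param loci loci table.
#' @param lineage data frame with `assembly_id` plus one column per rank
#'   (e.g. `genus`, `class`, `phylum`); may be empty or `NULL`.
#' @param ranks ranks to summarize (defaults to the lineage columns).
#' @return data frame `rank`, `name`, `n_loci`, `n_genomes`, `percent`
#'   (2 dp of all loci); loci without lineage are binned as
#'   `"unclassified"`.
#' @export
taxonomy_summary <- function(loci, lineage = NULL,
                             ranks = NULL) {
  if (is.null(lineage) || !nrow(lineage)) {
    lineage <- data.frame(assembly_id = character(0),
                          stringsAsFactors = FALSE)
  }
  if (is.null(ranks)) ranks <- setdiff(names(lineage), "assembly_id")
  if (!length(ranks)) ranks <- "genus"
  if (!nrow(loci)) {
    return(empty_df(rank = "character", name = "character",
                    n_loci = "integer", n_genomes = "integer",
                    percent = "double"))
  }
  out <- list()
  for (rk in ranks) {
    nm <- if (rk %in% names(lineage)) {
      lineage[[rk]][match(loci$genome_id, lineage$assembly_id)]
    } else rep(NA_character_, nrow(loci))
    nm[is.na(nm) | !nzchar(nm)] <- "unclassified"
    sp <- split(seq_len(nrow(loci)), nm)
    out[[rk]] <- data.frame(
      rank = rk, name = names(sp),
      n_loci = vapply(sp, length, 0L),
      n_genomes = vapply(sp, function(i) length(unique(loci$genome_id[i])), 0L),
      stringsAsFactors = FALSE)
    out[[rk]]$percent <- percent2(out[[rk]]$n_loci, nrow(loci))
    out[[rk]] <- out[[rk]][order(-out[[rk]]$n_loci, out[[rk]]$name), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Locus counts by replicon type
#'
#' @param loci loci table.
#' @return data frame `replicon_type`, `count` over
#'   chromosome/plasmid/unknown (zeros included).
#' @export
replicon_summary <- function(loci) {
  lv <- c("chromosome", "plasmid", "unknown")
  tab <- table(factor(loci$replicon_type, levels = lv))
  data.frame(replicon_type = lv, count = as.integer(tab),
             stringsAsFactors = FALSE)
}
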
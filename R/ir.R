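#' Parameters for the inverted-repeat scan
#'
#' Defaults are the genome-scan settings used on regulator upstream
#' regions: minimum repeat length 20 (per arm), spacer ("gap") strictly
#' below 8 bp, and at most two mismatches between an arm and the reverse
#' complement of its partner.  `length_semantics` selects whether
#' `min_arm` constrains the arm (`"per_arm"`, the EMBOSS-style reading and
#' the default) or the whole repeat footprint arm+gap+arm (`"total"`);
#' the 11-bp R-BOX arms would be invisible to a 20-bp per-arm scan, which
#' is why both are available.
#'
#' @param min_arm minimum repeat length in bp (>= 2); interpreted per
#'   `length_semantics`.
#' @param max_gap maximum spacer length in bp (default 7, i.e. "< 8").
#' @param max_mismatch maximum mismatches per repeat (default 2).
#' @param length_semantics `"per_arm"` or `"total"`.
#' @return object of class `ir_params`.
#' @export
ir_params <- function(min_arm = 20L, max_gap = 7L, max_mismatch = 2L,
                      length_semantics = c("per_arm", "total")) {
  length_semantics <- match.arg(length_semantics)
  assert_that(min_arm >= 2, "min_arm must be >= 2")
  assert_that(max_gap >= 0 && max_mismatch >= 0,
              "max_gap and max_mismatch must be >= 0")
  structure(list(min_arm = as.integer(min_arm), max_gap = as.integer(max_gap),
                 max_mismatch = as.integer(max_mismatch),
                 length_semantics = length_semantics),
            class = "ir_params")
}

#' Find mismatch-tolerant inverted repeats in a DNA sequence
#'
#' Reports all maximal inverted repeats: two equal-length arms separated
#' by a spacer of at most `max_gap` bases, where the Hamming distance
#' between arm 1 and the reverse complement of arm 2 is at most
#' `max_mismatch`.  Maximal means neither arm can be extended outward (one
#' base each, spacer unchanged) without exceeding the mismatch budget or
#' the sequence bounds; repeats wholly contained (both arms) in a reported
#' longer repeat with equal spacer are suppressed.  `N` counts as a
#' mismatch against everything, including `N`.  The scan is substitution
#' only -- no bulges or indels between arms.  Input case is ignored.
#'
#' @param seq DNA string; a sequence shorter than the minimum footprint
#'   yields an empty result.
#' @param params an [ir_params()].
#' @param seq_id identifier stamped on the result rows.
#' @return data frame (`seq_id`, `arm1_start`, `arm1_end`, `arm2_start`,
#'   `arm2_end`, `arm_len`, `spacer_len`, `mismatches`, `arm1_seq`,
#'   `arm2_seq`), 0-based half-open coordinates, sorted by
#'   `(arm1_start, -arm_len)`.
#' @export
find_inverted_repeats <- function(seq, params = ir_params(), seq_id = "seq") {
  seq <- toupper(seq)
  assert_that(!grepl("[^ACGTN]", seq),
              "find_inverted_repeats: invalid character in sequence")
  min_footprint <- if (params$length_semantics == "per_arm")
    2L * params$min_arm else params$min_arm
  if (nchar(seq) < min_footprint) {
    message(sprintf("sequence '%s' shorter than minimum repeat footprint (%d < %d); skipped",
                    seq_id, nchar(seq), min_footprint))
    return(empty_ir(seq_id))
  }
  d <- .find_ir(seq, params$min_arm, params$max_gap, params$max_mismatch,
                params$length_semantics == "total")
  if (!nrow(d)) return(empty_ir(seq_id))
  d$seq_id <- seq_id
  d$arm1_seq <- substring(seq, d$arm1_start + 1L, d$arm1_end)
  d$arm2_seq <- substring(seq, d$arm2_start + 1L, d$arm2_end)
  d[, c("seq_id", "arm1_start", "arm1_end", "arm2_start", "arm2_end",
        "arm_len", "spacer_len", "mismatches", "arm1_seq", "arm2_seq")]
}

empty_ir <- function(seq_id = character(0)) {
  d <- empty_df(seq_id = "character", arm1_start = "integer",
                arm1_end = "integer", arm2_start = "integer",
                arm2_end = "integer", arm_len = "integer",
                spacer_len = "integer", mismatches = "integer",
                arm1_seq = "character", arm2_seq = "character")
  d
}

#' Scan the upstream regions of all regulator loci for inverted repeats
#'
#' @param loci loci table from [anchor_regulators()] (uses
#'   `upstream_seq`).
#' @param params an [ir_params()].
#' @return list with `repeats` (per-locus IR table, `seq_id` = locus id)
#'   and `summary` (`n_ir` total repeats, `n_loci_with_ir` loci carrying
#'   at least one).
#' @export
scan_upstream_all <- function(loci, params = ir_params()) {
  min_footprint <- if (params$length_semantics == "per_arm")
    2L * params$min_arm else params$min_arm
  n_short <- sum(nchar(loci$upstream_seq) < min_footprint)
  if (n_short > 0) {
    message(sprintf(
      "%d of %d upstream sequences shorter than the minimum repeat footprint (%d bp); skipped",
      n_short, nrow(loci), min_footprint))
  }
  reps <- lapply(seq_len(nrow(loci)), function(i) {
    suppressMessages(
      find_inverted_repeats(loci$upstream_seq[i], params,
                            seq_id = loci$locus_id[i]))
  })
  repeats <- if (length(reps)) do.call(rbind, reps) else empty_ir()
  rownames(repeats) <- NULL
  list(repeats = repeats,
       summary = list(n_ir = nrow(repeats),
                      n_loci_with_ir = length(unique(repeats$seq_id))))
}

#' Positional comparison of two operator boxes
#'
#' Aligns two inverted-repeat boxes of identical geometry position by
#' position and counts differences separately for the first arms (IR1),
#' the spacers, and the second arms (IR2).
#'
#' @param box_a,box_b lists with elements `arm1_seq`, `spacer_seq`,
#'   `arm2_seq`; arm and spacer lengths must match between boxes.
#' @return list with per-component difference counts (`ir1_diff`,
#'   `spacer_diff`, `ir2_diff`) and per-position logical match vectors.
#' @export
score_rbox_pair <- function(box_a, box_b) {
  cmp <- function(a, b, what) {
    assert_that(nchar(a) == nchar(b),
                paste0("score_rbox_pair: unequal ", what, " lengths"))
    va <- strsplit(toupper(a), "")[[1]]
    vb <- strsplit(toupper(b), "")[[1]]
    va == vb
  }
  m1 <- cmp(box_a$arm1_seq, box_b$arm1_seq, "arm1")
  ms <- cmp(box_a$spacer_seq, box_b$spacer_seq, "spacer")
  m2 <- cmp(box_a$arm2_seq, box_b$arm2_seq, "arm2")
  list(ir1_diff = sum(!m1), spacer_diff = sum(!ms), ir2_diff = sum(!m2),
       ir1_match = m1, spacer_match = ms, ir2_match = m2)
}

#' Write an inverted-repeat table as TSV (1-based inclusive coordinates)
#'
#' @param repeats IR table from [find_inverted_repeats()] /
#'   [scan_upstream_all()].
#' @param path output file.
#' @param bed also write a BED-like 0-based export alongside (`.bed`).
#' @return `path`, invisibly.
#' @export
write_ir_tsv <- function(repeats, path, bed = FALSE) {
  out <- repeats
  out$arm1_start <- out$arm1_start + 1L   # 1-based inclusive on output
  out$arm2_start <- out$arm2_start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (bed) {
    bedpath <- paste0(sub("\\.tsv$", "", path), ".bed")
    b <- data.frame(chrom = repeats$seq_id, start = repeats$arm1_start,
                    end = repeats$arm2_end,
                    name = sprintf("IR_arm%d_gap%d_mm%d", repeats$arm_len,
                                   repeats$spacer_len, repeats$mismatches))
    write.table(b, bedpath, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}
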